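---
title: "Modelling transposable element load under sexual and asexual reproduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transposable element load under sexual and asexual reproduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tedyn)
```

## The question

Transposable elements (TEs) are genomic parasites that replicate by
copying themselves into new chromosomal locations. In *Saccharomyces
cerevisiae* all TEs are LTR retrotransposons (families Ty1-Ty5): a
full-length copy carries protein-coding internal sequence flanked by two
long terminal repeats (LTRs), and intra-chromosomal recombination
between the two LTRs excises the internal sequence, leaving a diagnostic
solo LTR. Whether sex helps or hinders TE proliferation is a classic
population-genetics question: recombination lets a TE colonise new
genetic backgrounds, but it also generates variance in copy number among
individuals, which makes purifying selection against TEs more
efficient.

`tedyn` packages two things:

1. a forward-time, individual-based simulator of TE copy-number
   evolution in a constant-size haploid population with periodic sexual
   episodes and an unlinked excision-rate *modifier allele*, and
2. the table-level statistical machinery used when measuring TE loads in
   pooled-sequencing experimental-evolution data: multi-detector
   insertion-call deduplication, length-based insertion classification,
   read-fraction load, coverage residualisation, permutation ANOVA with
   a coverage nuisance covariate, and regression-based loss estimates —
   together with synthetic-data generators that emulate the
   experimental design (four sexual and four asexual strains sampled
   every 90 generations over 990 generations) so the entire pipeline is
   testable without sequencing data.

## The simulation model

Each of `N` haploid individuals is a presence/absence vector over
16 chromosomes x 200 insertion loci (3200 sites) plus one unlinked
biallelic modifier locus. Relative fitness with `n` TE copies is

$$ w_n = \exp\!\left(-a\,n - \tfrac{1}{2}\,b\,n^2\right), $$

with `a` the linear selection strength per copy and `b` a synergistic
epistasis term (the marginal cost of a copy grows with load when
`b > 0`).

A run starts from a single founder carrying `founder_copies = 50` TEs at
uniformly chosen sites — the approximate number of full-length, active
Ty copies in the yeast strain this design mirrors — which populates the
deme clonally. Twenty burn-in generations of per-individual
transposition-then-excision cycles follow, without selection or
resampling. Each subsequent generation is:

1. **Selection + reproduction.** `N` parents are drawn with replacement
   with probability proportional to `w_n` (Wright-Fisher with
   selection). In an ordinary generation each offspring is a clonal copy
   of its parent; in a sexual generation (every `sex_interval`
   generations, 90 in the yeast regime) each offspring is produced by
   fusion of two *distinct* fitness-sampled parents followed by
   recombination with a Poisson (mean 1) number of crossovers per
   chromosome at uniform positions, the starting parent of each
   chromosome chosen fairly. The modifier locus is unlinked: it is
   inherited from either parent with probability 1/2.
2. **Transposition.** Each copy spawns a new copy with probability `u`
   (`u_meiotic` in sexual generations), placed uniformly among empty
   sites. With ~50 copies in 3200 sites, saturation is never
   approached; should no empty site remain, the pending insertion is
   skipped.
3. **Excision.** Each copy is removed with probability `v`, or
   `v + modifier_delta_v` in modifier carriers. The modifier has no
   direct fitness effect and no recurrent mutation; it changes frequency
   only through inheritance and hitchhiking.

Mean load, load variance and modifier frequency are recorded every
`sample_every = 10` generations. Replicates derive their seeds
sequentially from the master seed (`seed + replicate`), so experiments
are bit-for-bit reproducible.

Deliberate simplifications: no diploid life stage beyond the transient
fusion, no mating-type loci, no per-family TE classes inside the
simulator, no ectopic-recombination fitness model, no spatial
structure.

## The yeast preset and how it was calibrated

Transposition and excision rates for Ty elements are small and
uncertain — literature estimates put per-element transposition around
$10^{-5}$ to $10^{-7}$ per generation and LTR-LTR excision one to two
orders below that — and per-copy fitness costs are similarly diffuse.
`yeast_params()` therefore ships one named, fixed parameterisation
rather than pretending to measured values:

| parameter | value | meaning |
|---|---|---|
| `u` | $10^{-5}$ | transposition per copy per reproduction |
| `v` | $10^{-6}$ | baseline excision per copy per generation |
| `a` | $3\times10^{-3}$ | selection per copy |
| `b` | 0 | no epistasis in the preset |
| `modifier_delta_v` | $10^{-4}$ | excision-rate increase in carriers |
| `modifier_init_freq` | 0.02 | standing frequency of the modifier |
| `pop_size` | 10,000 | workstation-scale deme (100,000 at full scale) |

The calibration targets are the qualitative and quantitative behaviours
the scenario is meant to reproduce: asexual populations should fix the
modifier by hitchhiking well within 990 generations and end up roughly
nine full-length copies below their ancestor (about 50 down to about
41), while populations having sex every 90 generations should keep
near-constant loads because recombination keeps separating the modifier
from the low-load backgrounds it creates. Once the modifier is fixed,
the deterministic expectation
$n(t) = 50\,e^{-(v + \Delta v - u)t}$ gives ~4-5 copies of direct loss
over 990 generations at $\Delta v = 10^{-4}$; selection amplifies this
(it preferentially propagates the individuals that happened to lose
copies) by roughly the same amount again at $a = 3\times10^{-3}$, which
is what lands the total near nine. Raising `a` or `modifier_delta_v`
makes asexuals overshoot and lets the modifier invade sexual
populations; lowering them leaves the modifier stranded by drift at
`N = 10{,}000`. The initial frequency 0.02 (200 carriers) is the
smallest standing frequency at which hitchhiking reliably rescues the
allele from early drift loss at this deme size while staying low enough
that sexual populations rarely see it spread. These couplings were
mapped with short pilot runs of this same simulator before the values
were frozen; they are a package design choice, not literature
measurements, and a user with measured rates should override the preset
field by field.

At full scale (`pop_size = 1e5`) drift is ten times weaker and the same
qualitative behaviour holds over a wider parameter neighbourhood; the
workstation default keeps a ten-replicate, two-scenario experiment in
the minutes range on one CPU.

Two open modelling choices are resolved as follows: burn-in cycles are
one transposition-plus-excision pass per generation, and in sexual
generations transposition (at `u_meiotic`, default `u`) acts on the
recombinant offspring genome after fusion.

## The no-modifier contrast

Without activity-rate evolution the model predicts the opposite
ordering: sexual populations purge TEs *faster* than asexual ones,
because recombination regenerates among-individual load variance that
selection consumes. At the yeast-preset rates this purge is real but
minuscule — with $u = 10^{-5}$ essentially no load polymorphism arises
within 990 generations, and both regimes drift by well under one copy —
so the package demonstrates the ordering in an elevated-activity corner
of the explored parameter space (`u = v = 2x10^{-4}`, balanced
activity, deme 6000), where segregating insertions accumulate fast
enough for the variance mechanism to be visible above drift noise
within the experiment's horizon (both regimes decline; the sexual one
several copies further). This is a visibility choice, not a change of
mechanism: the ordering holds throughout the parameter space, but only
its magnitude differs.

## The empirical-analysis machinery

**Coverage filtering.** Samples under one-fold mean per-base coverage
are excluded (strictly below; exactly 1.0 is kept), mirroring standard
practice for pooled sequencing.

**Residualisation.** Detection of insertions rises with coverage, so
counts are regressed on coverage by OLS and residuals carry the
corrected signal; with (numerically) constant coverage the fallback is
mean-centring. The slope of residuals against generation, times 1000,
is the loss over 1000 generations, reported with the implied final
count below the 50 ancestral full-length copies.

**Permutation ANOVA.** The model family is fixed:
`count ~ coverage + generation + mode + generation:mode`, generation
numeric (consistent with slope-based loss estimates), mode a two-level
factor, term F statistics by sequential type-I sums of squares in
formula order (coverage first, so the nuisance is always absorbed before
the terms of interest). P-values are empirical:
$p = (1 + \#\{F^* \ge F\})/(1 + B)$, with $B = 10{,}000$ by default and
a mandatory seed. The default scheme is sequential Freedman-Lane — for
each term, residuals of the model containing the *preceding* terms are
permuted and added back to that model's fit, and the term's sequential F
is recomputed — which for the generation term is exactly the classical
permutation-of-residuals-after-covariate construction. Raw-response
permutation (Manly) is available via `scheme = "manly"`; both schemes
converge to the classical F test under Gaussian errors, and the
sequential Freedman-Lane holds its level better when the nuisance
covariate carries real signal. Rows are sorted internally so p-values
are exactly invariant to input row order; a rank-deficient design fails
with the offending term named. No multiple-testing correction is
applied across terms — the three raw term p-values are the result.

**Insertion deduplication.** Calls from different detectors for the
same strain, generation, chromosome and family are merged by
single-linkage chaining along the chromosome with a 100 bp default
tolerance — typical split-read versus discordant-pair breakpoint
scatter — keeping the median position and the union of detectors, so an
insertion with evidence from several programs is counted once.
Deduplication is idempotent. Coordinates are 0-based throughout.

**Classification.** An insertion is `full_length` if its length is
within 500 bp of its family's canonical size (internal sequence plus
two LTRs), `solo_LTR` between 220 and 420 bp regardless of family,
`truncated` between those windows, `other` otherwise (including
unknown-family records that are too long to be solo LTRs, which warn).
The "within 500 bp" window is read as
$|\mathrm{length} - \mathrm{canonical}| \le 500$; canonical family
lengths (Ty1 5918/334, Ty2 5959/332, Ty3 5351/340, Ty4 6223/371,
Ty5 5375/251 bp full/LTR) ship as an editable table compiled from the
yeast TE literature.

**Read-fraction load.** Genome-wide TE load without distinguishing
active from inactive copies: TE-mapped reads over total mappable reads.

## Synthetic data: what it does and does not emulate

`gen_count_table()` draws a latent full-length count per strain and
time point from a mode-specific linear trend plus Gaussian noise
(defaults: asexual slope -0.009 copies/generation from 50 ancestral
copies, sexual slope 0, noise SD 2 — the nine-copies-per-1000-
generations scenario), then thins it binomially with detection
probability $p_{det} = 1 - e^{-k\,c}$ at coverage $c$. The rate $k$ is
calibrated so that $p_{det}(1\times) = 24/50$: at one-fold coverage
about 24 of the 50 ancestral full-length insertions are detectable,
matching the saturating, coverage-limited behaviour of insertion
callers; coverage is drawn uniformly from 2-20x by default, where
detection is nearly saturated. Twelve time points (0 through 990 in
steps of 90) are generated per strain, including generation 0.
`gen_insertion_records()` builds multi-detector call tables with
class-consistent lengths, 1-6 detectors per insertion and bounded
breakpoint jitter, spaced so generator truth is exactly recoverable;
`gen_read_count_table()` programs a proportional read-fraction decline
(23.5% by default) into integer read counts.

Passing tests on these generators shows the *estimators* are correct at
the design's scale and noise structure. It does not validate caller
behaviour on real reads: real detector errors are correlated across
samples, detection bias depends on insertion context and not only
coverage, strains share polymorphisms through common descent, and
residual counts are autocorrelated along time courses. Those effects
are out of scope; the pipeline consumes caller outputs, it does not
re-implement callers.

## Numerical and testing choices

Degenerate inputs have defined behaviour: loss fits require two
distinct sampled generations; a constant response makes every
permutation F degenerate and returns p = 1; saturation during
transposition silently skips insertions (unreachable at yeast-like
loads); `v + modifier_delta_v` is validated at parameter construction,
not per event. Fixation is frequency exactly 1.0 (allele counts are
discrete); trajectories that never fix report `NA`, which summaries
censor at the horizon. The test suite runs the simulator at deme sizes
400-10,000 and the full 990-generation horizon only where a check
needs it, and asserts distributional agreement (3 standard errors, or
total-variation distance against exhaustive enumeration on a 2-individual,
4-locus toy) rather than pointwise equality; Monte Carlo sizes are
chosen so each check resolves its target within minutes on one CPU.

## Limitations

- The preset is a calibrated stand-in in a weakly identified parameter
  region, not a set of measurements; conclusions should be read as
  "the mechanism suffices", never as rate estimates.
- At `N = 10,000` the modifier's early fate is strongly stochastic:
  in a minority of asexual replicates it is lost to drift before
  hitchhiking rescues it, and occasionally it invades a sexual
  replicate. Scenario means over ten replicates inherit that
  variability.
- Sequential type-I tests are order-dependent by construction; the
  coverage-first order is part of the method's definition here.
- The classifier trusts called lengths; it does not inspect sequence.
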