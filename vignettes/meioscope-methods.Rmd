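---
title: "Crossover maps, interference and aneuploidy in F2 populations: models and methods"
author: "meioscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meioscope methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioscope)
```

meioscope analyses meiotic recombination in two-parent F2 populations
genotyped by low-coverage sequencing. This vignette explains the models the
package implements, the choices behind them, and what the built-in simulator
does and does not emulate.

## The meiosis simulator

Every downstream stage is testable against a generative model with known
ground truth. One F2 individual is the union of two independent gametes;
per meiosis and chromosome the simulator:

1. places **class I (interfering) crossovers** on the bivalent by a
   stationary gamma renewal process: inter-event distances are
   gamma(shape $\nu$, rate $\nu m / L$), so the expected count over a
   chromosome of length $L$ is the configured mean $m$. The first event is
   drawn from the equilibrium delay distribution — a uniform fraction of a
   length-biased gamma($\nu + 1$) interval — so the process is stationary
   and position 0 shows no artificial interference. $\nu = 1$ reduces
   exactly to a homogeneous Poisson process (no interference); larger $\nu$
   spaces crossovers more evenly, which is the textbook reading of
   crossover interference at the Mb scale;
2. adds **class II crossovers** as a homogeneous Poisson process with its
   own mean — the interference-insensitive pathway;
3. assigns each bivalent crossover to a random chromatid pair (no chromatid
   interference), so the single inherited chromatid carries each crossover
   independently with probability 1/2 — observable crossovers per gamete
   are half the bivalent count;
4. lets bivalents without any crossover missegregate with probability
   `obligateEscapeP`, producing monosomic or trisomic chromosomes with
   equal odds. At most one missegregation is applied per individual and
   chromosome, so copy number stays in {1, 2, 3}; a trisomic chromosome
   carries the missegregated chromatid twice. This is deliberately the
   simplest model that turns an "obligate crossover failure" into the
   aneuploidy the ploidy caller must detect;
5. flips each genotype call to a random wrong state with probability
   `genoErrorP` (i.i.d. per marker; correlated error tracts are out of
   scope).

Interference is modelled at the bivalent level in physical base pairs, not
genetic distance, because all downstream statistics (cis-DCO distances, CoC
bins, landscapes) are computed in Mb. No generative interference model is
observable in real F2 data directly; the gamma renewal process is the
package's stand-in, chosen because its shape parameter is exactly the
quantity the interference statistics estimate.

**Marker map.** Markers sit on a jittered regular grid (gap =
`markerSpacing` ± 20%). A memoryless random marker set would leave 13% of
gaps longer than twice the mean spacing, and the midpoint of such a gap is
more than two mean spacings from a uniformly placed crossover — an
irreducible localisation error that says nothing about the caller. The
bounded-gap grid models a curated, evenly informative SNP list, which is
what genotyping pipelines use in practice.

**Defaults** (`simConfig()`): 1.8 class I crossovers per bivalent with
$\nu = 5$, 0.3 class II crossovers, 2% genotyping error, 50 kb marker
spacing, 200,000 informative reads per library, mean marker coverage 5x —
a wild-type-like plant F2 sequenced at low coverage. The bundled
`syntheticGenomeModel()` has five 20–30 Mb chromosomes with asymmetric
centromeres and ±2 Mb pericentromere annotations; coordinates are
synthetic.

What the simulator does **not** emulate: read-level artifacts, alignment
bias, structural variants, recombination hotspots or any non-uniform
landscape (a `positionTransform` hook lets tests construct, e.g.,
telomere-clustered scenarios, but there is no hotspot model), and
correlated genotyping errors. Tests passing on simulated data therefore
validate the statistical machinery, not robustness to real-data artifacts.

## Genotype filtering

`filterSnps()` keeps calls with mapping quality strictly above 100 and
coverage strictly above 2.5x; `filterLibraries()` drops libraries with
fewer than 50,000 SNP-associated reads. All three thresholds are strict
inequalities, implemented exactly as printed in the protocols this package
codifies. Masked calls become missing and are skipped (never imputed) by
segmentation.

## The crossover caller

Real GBS pipelines segment genotypes with an HMM; meioscope uses a
deterministic stand-in that is transparent and exactly reproducible:

1. **plurality vote**: each marker takes the most common non-missing call
   in the `windowMarkers = 15` markers centred on it (ties and all-missing
   windows inherit the previous marker's state);
2. **absorption**: provisional runs shorter than `minSegmentMarkers = 5`
   are merged into the flanking run with more markers (shortest first,
   ties to the left), and runs whose supporting-call fraction falls below
   `purity = 0.8` likewise;
3. **boundary refinement**: each segment boundary is re-placed at the
   maximum-likelihood changepoint of the raw calls between its two
   segments (the cut maximising left-state matches plus right-state
   matches; ties resolve towards the provisional boundary). Under i.i.d.
   mis-calls this is the exact ML breakpoint for a two-state segment pair
   and localises boundaries to about one marker;
4. **rescue**: uninterrupted raw runs of a different state of at least
   `max(3, minSegmentMarkers - 2)` markers are restored as segments. Three
   consecutive identical mis-calls of the same wrong state occur with
   probability $\sim 10^{-6}$ per marker at a 2% error rate, so rescued
   segments are almost surely real. Without this pass the vote erases any
   segment shorter than about half the window — exactly the short
   double-crossover tracts the interference analysis needs.

A crossover event is the boundary between adjacent segments; its position
is the midpoint of the flanking-marker interval. Direct
parental-to-parental transitions (two crossovers inside one marker gap)
are flagged and excluded from cis-DCO analysis, never silently emitted.
Individuals with any non-disomic ploidy call are excluded genome-wide by
`excludeAneuploids()`.

At the defaults (2% error, 50 kb spacing) the caller recovers at least
95% of true crossovers, every recovered midpoint within 100 kb (two mean
marker gaps) of truth, with fewer than 0.05 false calls per individual and
chromosome; the remaining misses are crossover pairs or terminal segments
spanning fewer than three markers, which no marker-level method can
resolve.

## Ploidy calling

Window depths (100 kb by default, mosdepth-style) are normalised per
individual to a disomic baseline $D$: the length-weighted mean depth over
chromosomes, re-estimated up to five times with chromosomes whose
provisional ratio leaves [0.8, 1.2] excluded, so a trisomic chromosome
does not inflate its own baseline. If every chromosome is excluded the
plain mean is used with a warning. Classification uses the printed strict
thresholds — ratio above 1.2x is trisomy, below 0.8x monosomy — and the
same thresholds applied per arm (windows assigned by midpoint, arms split
at the centromere) report partial (single-arm) trisomy. Ratios are
invariant to rescaling all depths, so sequencing throughput cancels.
The codified normalisation replaces a visual-inspection step; it is a
reproducibility device, not a claim about how any particular study was
eyeballed.

## Interference statistics

A **cis-DCO** is a maximal parental–heterozygous–parental run of segments
with *matching* parental states (P1–H–P1 or P2–H–P2) in one individual;
its distance is between the midpoints of the two flanking transitions.
P1–H–P2 triples are excluded: non-matching flanks do not imply two
crossovers on the same homolog. The **expected null** draws, per
chromosome, two sets of 400 midpoints with replacement from all identified
crossovers of the genotype, pairs each first-set midpoint with a uniformly
drawn second-set midpoint, and keeps zero distances. Sampling is with
replacement because a population can carry fewer than 400 crossovers per
chromosome. Distances are pooled across chromosomes (per-chromosome use is
possible by subsetting the inputs).

Both distance sets get a two-parameter **gamma fit** by maximum
likelihood: the shape equation $\log k - \psi(k) = \log \bar x -
\overline{\log x}$ is solved by Newton iteration from Minka's closed-form
initialiser, and the rate is $k / \bar x$. This matches `fitdist`-style
MLE fitting (a unit test cross-checks against fitdistrplus to three
decimals) and is fast enough for the 1000-iteration bootstrap of the shape
parameter run on both sets. Zero distances are replaced by half the
smallest positive distance (logged); near-constant samples cap the shape
at $10^6$ with a warning. The bootstrap shape distributions are compared
with a two-sided Mann–Whitney U test.

Two caveats the package states plainly rather than hides:

- **The CoC of this procedure is not calibrated to 1 under independence.**
  The coefficient-of-coincidence profile bins observed cis-DCO distances
  and null distances at 3.5 Mb, rescales the null to the observed total,
  and reports the per-bin ratio. Because a cis-DCO additionally requires
  the whole tract to remain parental-bounded — no transition from the
  other homolog inside the span — long observed distances are suppressed
  by roughly the probability that no interfering transition falls inside
  the span, and only adjacent same-chromatid pairs are counted. Under a
  purely Poisson simulation (no interference, ~2 crossovers per
  individual and chromosome) the profile therefore starts near 1.3–1.5 in
  the first bin and decays with distance; its mean over well-populated
  bins is ~0.75 rather than 1 (the acceptance script computes this number
  from scratch; a truth-level re-derivation that bypasses the caller gives
  the same profile). Within-genotype comparisons of CoC profiles remain
  meaningful because the bias is shared; the absolute level is not a
  calibrated independence test.
- **The Mann–Whitney comparison of bootstrap shape vectors is
  anti-conservative.** Two bootstrap clouds around two point estimates
  will separate "significantly" whenever the estimates differ by a
  fraction of their sampling error. The package keeps the procedure as
  specified, and the acceptance suite evaluates it as a *directional
  declaration* (p < 0.01 and observed median shape above expected): at 500
  individuals per population the false-declaration rate under no
  interference is at or near zero while strong interference ($\nu = 5$) is
  declared essentially always.

`compareDistanceSets()` defaults to the unpaired two-sample rank test; the
paired signed-rank variant is available for equal-length binned inputs,
but an unpaired comparison is the defensible default when the two distance
sets have unrelated sizes. Tests are two-sided and unadjusted throughout.

## Landscapes

`windowFrequency()` bins crossover midpoints into fixed-origin 300 kb
windows (last partial window retained; edge handling is a convention, not
a result) and divides by the population size, so window counts sum to the
event count exactly. `scaleArms()` maps each arm onto [0, 1] from telomere
to centromere and averages window frequencies in proportional bins;
`correlationMatrix()` uses Spearman correlation on identical windows
(constant profiles give `NA`); `regionalReduction()` forms per-window
mutant/wild-type ratios grouped by the pericentromere annotation and
summarises the groups with a rank test (a deliberate simplification of
parametric multi-group testing, which is out of scope). Pericentromere
intervals are an external annotation (methylation-defined in real
genomes); the shipped ones are synthetic.

## Recombination frequency from seed counts

For a fluorescent two-reporter interval,
$RF = 100\,(1 - \sqrt{1 - 2(N_G + N_R)/N_T})$ cM, with green-only and
red-only counts entering the numerator and double-fluorescent seeds only
through $N_T$. The estimator's domain ends at a single-fluorescent
fraction of 1/2 (RF = 50 cM); beyond it the package raises an error rather
than clamping, because such counts are evidence of scoring problems, not
of 50+ cM intervals. The bootstrap CI resamples the three seed classes
multinomially. The simulator inverts the closed form exactly, and the
round trip is unbiased to well under 0.1 cM at realistic seed counts.

## Problem sizes and numerical conventions

The test suite exercises the pipeline at sizes chosen to make every
statistical claim stable: 10,000 draws for renewal-process properties,
150–500 individuals for caller fidelity and interference runs (50 seeds
per arm for the declaration-rate study), 1000 individuals for the CoC
profile, 200 individuals for ploidy accuracy, and 400–600 replicates for
estimator coverage and bias. Randomised steps take explicit seeds
(`SimConfig` requires one; `interferenceAnalysis()` accepts one), ties in
segmentation resolve deterministically to the left, and all file formats
round-trip integers exactly and floats to six significant digits.

## Known limitations

- The caller cannot resolve crossover pairs inside ~3 marker gaps; at
  50 kb spacing this censors cis-DCOs below ~150 kb (far below the 3.5 Mb
  analysis bin).
- Trisomic genotypes are simplified: the duplicated chromatid is carried
  twice, and sister-chromatid differences after meiosis II nondisjunction
  are ignored (such individuals are excluded from crossover analyses
  anyway).
- The ploidy caller assumes at least one well-behaved chromosome per
  individual and no GC or mappability bias; sub-arm CNVs and mosaicism are
  out of scope.
- Absolute CoC levels inherit the adjacency/conditioning bias described
  above; compare profiles, not levels.
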