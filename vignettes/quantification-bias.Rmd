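---
title: "How template evenness and dominance bias degenerate-primer qPCR: the model behind ampliq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How template evenness and dominance bias degenerate-primer qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliq)
```

## The problem

Quantitative real-time PCR of functional marker genes — here the
dissimilatory sulfite reductase beta subunit (*dsrB*), the workhorse marker
for sulfate-reducing microorganisms — is routinely used to estimate absolute
gene copy numbers in environmental DNA. Degenerate primer mixes broaden
taxonomic coverage, but each constituent oligo matches different template
variants with different numbers of mismatches, so a diverse template pool is
amplified unevenly. How badly a quantification is biased then depends not
only on the primers but on the *structure* of the template pool: its
evenness (how abundance is spread across sequence variants) and its
dominance (whether the abundant variants happen to be the ones the primers
cover well).

ampliq packages an in-silico version of the entire measurement chain so
these effects can be studied under controlled conditions: degenerate-primer
coverage analysis, artificial template-mixture design, a fluorescence-curve
simulator, Cy0-based absolute quantification, and the comparison statistics.

## The assay and template panel

Three *dsrB* assays with forward/reverse degeneracies 4/1
(DSRp2060F/DSR4R, target-specific), 77/10 (DSR1728Fmix/DSR4Rmix) and 98/29
(DSR1762Fmix/DSR2107Rmix) are evaluated against a panel of twelve 390 bp
synthetic template fragments (gBlocks) spanning the five *dsrAB*
phylogenetic superclusters. The oligo and gBlock sequences shipped with the
package are *synthetic stand-ins*: seeded random backbones with implanted
binding sites, constructed so that the panel reproduces the published
coverage geometry of the real assays — mix degeneracies of 4/1, 77/10 and
98/29; 7, 8 and 9 amplifiable gBlocks per assay at the conventional
one-mismatch tolerance; four gBlocks amplifiable by all three assays
("common"), four by exactly two ("less common") and four by one ("rare");
and single-mismatch binders (gBlock 3 under the 98/29 assay, gBlock 7 under
the 77/10 assay) so the 1-MM code path is exercised. Any real primer/template
FASTA can be substituted via `read_primer_fasta()` / `read_template_fasta()`.

Mismatch semantics are the standard in-silico PCR convention: a primer
position matches when the template base lies in the position's IUPAC set
(primer-side ambiguity is permissiveness, never a penalty); a mix binds
through its best member; the search is ungapped and counts every position equally, 3' terminus
included, since coverage criteria in this field are stated as total
mismatch counts.
A template is amplifiable when a forward and a reverse hit co-occur in
convergent orientation, each within the tolerance.

```{r}
ref <- dsrb_reference()
print(ref$amplifiability)
```

## Mixture design: evenness and dominance as dials

Relative abundances follow a log-normal distribution (natural-log
parameterization) with location mu = 1 and scale sigma in {1, 2, 5}; larger
sigma means a more uneven, dominated community. Rather than drawing random
variates, the profile takes the distribution's midpoint quantiles
(probabilities (i − 0.5)/n), which makes designs exactly reproducible and
sigma a strictly monotone control of Pielou evenness — the property the
study grid depends on. A seeded random-draw mode remains available for
sensitivity analyses.

```{r}
sapply(c(0, 1, 2, 5), function(s)
  pielou_evenness(lognormal_abundance_profile(12, 1, s)))
```

Dominance is a permutation: the same fraction multiset is assigned either
common-group-first or rare-group-first. Because a fixed mixture table is
emulated, the within-group order is pinned (`dsrb_dominance_priority()`):
rare-dominated mixtures put the top fractions on gBlocks 3, 6 and 7 — the
rare templates covered only by the degenerate assays — which is precisely
the configuration in which a specific assay's theoretical coverage collapses.
The full grid is 2 dominance modes x 3 sigma x 2 total concentrations
(high 1e8, low 1e5 copies/uL), i.e. 12 gBTM conditions.

## The theoretical model

The theoretical template amplification percentage is deliberately binary:
every template within one mismatch of both primers amplifies at 100%
efficiency, everything beyond one mismatch not at all, so the percentage is
just the summed abundance of covered members. It ignores concentration and
all kinetics; its role is to be the null expectation that empirical
quantifications are compared against. Ratios between assays (and later
theory/empirical ratios) use an inclusive four-fold boundary (ratio >= 4 or
<= 1/4), with raw ratios always reported so either reading of "more than
four-fold" is auditable.

## The curve simulator

No public instrument data accompany the study design, so the package
generates fluorescence curves from a minimal kinetic model chosen to have
exactly the two properties the downstream analysis needs — Richards-shaped
curves and a log-linear Cy0 calibration:

* shared-capacity logistic growth: each cycle, template t grows
  `N_t <- N_t * (1 + E_t * s)` with saturation
  `s = max(0, 1 - sum(N)/K)`, all templates drawing on one product
  capacity K;
* fluorescence `= scale * sum(N) + baseline(c) + Gaussian noise`.

Defaults (fixed once as the study conditions): 35 cycles; K = 1e11
molecules and scale = 3e-8 RFU/molecule, giving a plateau near 3000 RFU
with visible exponential and plateau phases within 35 cycles across the
whole 2.34e2–2.34e8 copies/uL standard range; baseline 100 RFU with a
0.2 RFU/cycle drift; read noise SD 15 RFU (0.5% of amplitude); 1 uL of
template per reaction. Per-cycle efficiency comes from the mismatch
category — 0.95 for perfect matches, 0.6 for one mismatch, 0 beyond — plus
an override table per (template, assay), because measured single-template
performance is not always predicted by mismatch count. The packaged
override scenario (`dsrb_efficiency_overrides()`) gives the rare dominants
gBlocks 3, 6, 7 efficiencies of 0.50–0.60 under the degenerate assays; over
a ~14-cycle quantification window that corresponds to recovering roughly
2–8% of input, the single-template recovery range the study design targets.
Optional Poisson sampling of loaded copies models low-concentration
stochasticity.

What the simulator does *not* emulate: enzyme and probe chemistry, melt
behaviour, efficiency drift across cycles, inhibition at high template
loads, pipetting error. Passing tests therefore demonstrate the internal
consistency of the analysis chain under a plausible instrument model, not
the behaviour of any particular real instrument.

## Cy0 quantification

Each curve is fitted with the 5-parameter Richards function
`F(x) = Fb + Fmax / (1 + exp((c - x)/b))^d` by bounded Levenberg–Marquardt
least squares (data-driven starts: baseline from early cycles, amplitude
from the range, location from the steepest cycle, d = 1; a deterministic
ladder of restarts; convergence tolerance 1e-10, max 10,000 evaluations).
Flat or merely drifting curves are reported as no-fit, not errors: a curve
must rise at least tenfold above the differenced-noise floor and
concentrate at least half its rise in a ten-cycle window.

Cy0 is the abscissa intercept of the tangent at the inflection of the
baseline-subtracted curve. The geometry gives a closed form — inflection at
`x* = c + b log d`, hence `Cy0 = c + b log d - b (1 + 1/d)` — which the
tests verify to 1e-6 cycles against a numeric tangent construction; the
quantity is parameterization-independent by construction. The tangent is
intersected with the baseline (y = Fb) rather than absolute zero because
raw baselines are instrument offsets.

Standard curves regress Cy0 on log10 copies (Eq-1 mass-to-copy conversion:
`copies = ng x 6.022e23 / (bp x 660 x 1e9)`); the detection limit is the
lowest dilution level from which upward all replicate wells converge and
mean Cy0 stays strictly monotone. Sample copies are `10^((Cy0 - a)/m)`,
replicates averaged as geometric means (multiplicative error), and
extrapolations beyond the calibrated range flagged.

## Comparison statistics

Empirical amplification percentage = quantified copies / input copies.
t-tests run on log10 copy numbers (multiplicative error structure):
one-sample tests against the theoretically expected copies, paired tests
(by replicate index) between assays. BH adjustment is applied within one
family per report panel and concentration label — the most conservative
partition consistent with per-figure adjustment; re-partitioning changes
only adjusted values, never raw ones. A difference is called significant
only when the adjusted p is below 0.05 *and* the fold change reaches the
inclusive four-fold boundary.

## Problem sizes and numerical choices

The default study grid — 12 gBTM conditions x 3 assays x 3 replicates plus
three 21-well standard series, 171 Richards fits in all — runs in well
under a minute on a laptop core and is the size used throughout the tests
and the analysis scripts. Ties in binding-site pairing resolve to the
minimal-mismatch, outermost convergent pair; amplicon-length bounds are off
by default (assay metadata, not a coverage criterion); degenerate
statistical cases (zero-variance replicates) return limiting p-values
rather than errors.

## Known limitations

* The shipped panel is a structural stand-in; sequence-specific findings do
  not transfer to the real oligos, only the coverage geometry does.
* The binary theoretical model and the three-level efficiency model bracket,
  but do not span, real per-template kinetics; the override table is the
  escape hatch.
* Quantification of a mixed-efficiency pool reports an *effective* copy
  number dominated by the fastest-amplifying members — which is the bias
  under study, so it is a feature, but it means "empirical percentage" is
  assay-relative, not a physical titer.
* Detection-limit behaviour at the lowest level (2.34e2 copies/uL) depends
  on the noise draw; the pipeline tracks it but the tests assert it only
  loosely, mirroring the 1e2-vs-1e3 copies/uL spread such experiments show.
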