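# ampliq

In-silico machinery for studying how target-gene sequence **evenness** and
**dominance** bias absolute qPCR quantification with degenerate primers,
built around the *dsrB* gene (the functional marker for sulfate-reducing
microorganisms) as the model system. It is aimed at microbial ecologists
who quantify marker genes in environmental DNA and want to know, before
running assays, how much a primer set's coverage geometry can distort copy
numbers for a given community structure.

The package implements the full measurement chain:

1. **Primer coverage** — IUPAC-aware expansion of degenerate primer mixes
   (degeneracy = number of distinct concrete oligos), ungapped
   mismatch-tolerant binding-site search (a position matches when the
   template base is in the primer position's IUPAC set; a mix binds through
   its best member), and amplifiability classification: a template is
   covered by an assay when forward and reverse sites co-occur convergently
   with at most 1 mismatch each.
2. **Mixture design** — artificial template mixtures whose fractions follow
   a log-normal distribution, p_i ∝ F⁻¹((i−0.5)/n) with F = LogN(μ, σ);
   σ ∈ {1, 2, 5} controls unevenness (Pielou J = H/ln n falls
   monotonically), and dominance assigns the top fractions to either the
   broadly covered ("common") or narrowly covered ("rare") templates.
3. **Theory** — theoretical amplification percentage of a mixture under an
   assay: 100 × Σ fractions of templates within 1 mismatch (binary
   amplify/not model).
4. **Simulation** — shared-capacity logistic amplification curves with
   mismatch-dependent per-template efficiencies and Gaussian read noise,
   standing in for instrument data.
5. **Cy0 quantification** — 5-parameter Richards fits
   F(x) = F_b + F_max/(1+e^{(c−x)/b})^d, Cy0 = c + b·ln d − b(1+1/d)
   (tangent-at-inflection x-intercept), standard curves of Cy0 vs log₁₀
   copies, and the mass↔copies conversion
   copies = ng·N_A/(bp·660·10⁹).
6. **Comparison statistics** — empirical amplification percentages,
   one-sample/paired t-tests on log₁₀ copies, Benjamini–Hochberg
   adjustment, and a significance rule requiring adjusted p < 0.05 *and* a
   four-fold difference.

The shipped assay/template panel (three assays with forward/reverse
degeneracies 4/1, 77/10, 98/29 against twelve 390 bp gBlocks) is
**synthetic**: seeded backbones with implanted binding sites that reproduce
the real panel's coverage geometry (7/8/9 covered templates, four common /
four less-common / four rare). Real FASTA input drops in via
`read_primer_fasta()` / `read_template_fasta()`.

## Worked example

```r
library(ampliq)

ref <- dsrb_reference()
print(ref$amplifiability)
#> <amplifiability_matrix> 12 templates x 3 primer sets (max 1 MM)
#> amplifiable per set: DSRp2060F/DSR4R=7, DSR1728Fmix/DSR4Rmix=8, DSR1762Fmix/DSR2107Rmix=9
#> groups: common=4, less common=4, rare=4

# a standard dilution series, fitted and calibrated
series <- simulate_dilution_series(replicates = 3, seed = 42)
fits   <- fit_curves(series)
build_standard_curve(fits$cy0, fits$copies_per_ul)
#> <standard_curve> Cy0 = 35.452 -3.449 log10(copies); R2 = 1.0000; LOD = 234 copies/uL
```

The slope of −3.45 cycles per decade is what a per-cycle efficiency of 0.95
implies (−ln 10 / ln 1.95), and R² > 0.99 is the calibration quality such
assays require. The full study (12 mixture conditions × 3 assays ×
triplicates) runs with `run_study(seed = 1)`; its report shows the headline
pattern — common-dominated mixtures quantify within four-fold of theory for
every assay, while rare-dominated mixtures at σ ∈ {2, 5} are significantly
(> four-fold) under-quantified by the two degenerate assays only:

```r
st <- run_study(seed = 1)
print(subset(st$report$theory_vs_empirical, grepl("rare_s5", gbtm_name),
             c(gbtm_name, primer_set, theoretical_pct, empirical_pct,
               significant)), digits = 3, row.names = FALSE)
#>     gbtm_name              primer_set theoretical_pct empirical_pct significant
#>  rare_s5_high    DSR1728Fmix/DSR4Rmix          6.1666        0.2148        TRUE
#>  rare_s5_high DSR1762Fmix/DSR2107Rmix         93.9148       12.5779        TRUE
#>  rare_s5_high         DSRp2060F/DSR4R          0.0417        0.0420       FALSE
#>   rare_s5_low    DSR1728Fmix/DSR4Rmix          6.1666        0.1173        TRUE
#>   rare_s5_low DSR1762Fmix/DSR2107Rmix         93.9148        1.0486        TRUE
#>   rare_s5_low         DSRp2060F/DSR4R          0.0417        0.0423       FALSE
```

## Analysis workflow

The study is organised as numbered drivers over the package functions, each
writing tab-separated tables under `results/`:

| script | step | outputs |
|---|---|---|
| `analysis/01_coverage.R` | primer degeneracy + amplifiability Venn | `primer_degeneracy.tsv`, `amplifiability.tsv` |
| `analysis/02_design_mixtures.R` | gBTM grid, evenness ladder | `designs.tsv`, `evenness.tsv` |
| `analysis/03_theory.R` | theoretical percentages + four-fold ratios | `theory.tsv`, `theory_ratios.tsv` |
| `analysis/04_simulate_qpcr.R` | standards + sample curves (long CSV) | `curves_*.csv` |
| `analysis/05_quantify.R` | Richards fits, Cy0, standard curves | `standard_curves.tsv`, `quantification.tsv` |
| `analysis/06_compare.R` | theory-vs-empirical and assay-vs-assay panels | `theory_vs_empirical.tsv`, `assay_vs_assay.tsv` |

## Documentation

The methods vignette (`vignettes/quantification-bias.Rmd`) documents the
model assumptions, simulator defaults, numerical choices and limitations.
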