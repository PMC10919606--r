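#' Empirical template amplification percentage
#'
#' The ratio of the qPCR quantification result to the total template
#' abundance loaded into the reaction, as a percentage. Replicates are kept
#' for downstream testing.
#'
#' @param quants Replicate quantified copy numbers (copies/uL).
#' @param input_total Total template concentration added (copies/uL, > 0).
#' @return An `empirical_result`: list with `replicate_quants`,
#'   `replicate_pcts`, `empirical_pct` (mean-based), `input_total`.
#' @export
empirical_amp_pct <- function(quants, input_total) {
  if (length(quants) == 0L) stop("no replicate quantifications", call. = FALSE)
  stopifnot(input_total > 0)
  pcts <- 100 * quants / input_total
  structure(
    list(replicate_quants = quants, replicate_pcts = pcts,
         empirical_pct = 100 * mean(quants, na.rm = TRUE) / input_total,
         input_total = input_total),
    class = "empirical_result")
}

.log10_safe <- function(x) {
  if (any(!is.na(x) & x <= 0)) {
    stop("copy numbers must be positive for log-scale testing", call. = FALSE)
  }
  log10(x)
}

#' One-sample t-test of replicate quantifications against a reference
#'
#' Tested on the log10 scale (qPCR error is multiplicative). Degenerate
#' zero-variance replicates return p = 1 when they equal the reference and
#' 0 (the limiting value) when they do not.
#'
#' @param replicate_quants Replicate copy numbers (>= 2).
#' @param reference_value Reference copy number (> 0).
#' @return Two-sided p-value.
#' @export
one_sample_test <- function(replicate_quants, reference_value) {
  x <- .log10_safe(replicate_quants[is.finite(replicate_quants)])
  if (length(x) < 2L) return(NA_real_)
  mu0 <- .log10_safe(reference_value)
  if (stats::sd(x) == 0) return(if (isTRUE(all.equal(mean(x), mu0))) 1 else 0)
  stats::t.test(x, mu = mu0)$p.value
}

#' Paired t-test between two replicate series
#'
#' Pairing is by replicate index; testing is on the log10 scale, so this
#' equals a one-sample test of the log-ratios against zero.
#'
#' @param quants_a,quants_b Equal-length replicate copy numbers (>= 2).
#' @return Two-sided p-value.
#' @export
paired_test <- function(quants_a, quants_b) {
  if (length(quants_a) != length(quants_b)) {
    stop("paired series must have equal length", call. = FALSE)
  }
  d <- .log10_safe(quants_a) - .log10_safe(quants_b)
  d <- d[is.finite(d)]
  if (length(d) < 2L) return(NA_real_)
  if (stats::sd(d) == 0) return(if (isTRUE(all.equal(mean(d), 0))) 1 else 0)
  stats::t.test(d, mu = 0)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (returned in input order, capped at 1); NA
#' entries are preserved.
#'
#' @param p_values p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Combined significance rule
#'
#' A comparison is called significant only when the BH-adjusted p-value is
#' below 0.05 AND the two quantities differ at least four-fold
#' (ratio >= 4 or <= 1/4, boundary inclusive).
#'
#' @param fold_ratio Ratio of the two compared quantities (> 0); vectorized.
#' @param p_adj Adjusted p-value(s).
#' @return Logical significance call(s); NA propagates.
#' @export
significance_call <- function(fold_ratio, p_adj) {
  ifelse(is.na(fold_ratio) | is.na(p_adj), NA,
         p_adj < 0.05 & (fold_ratio >= 4 | fold_ratio <= 0.25))
}

#' Theory-vs-empirical and assay-vs-assay comparison report
#'
#' Builds the two study report tables. Panel one compares, per mixture and
#' assay, the theoretical template amplification percentage with the
#' empirical one: fold ratio theory/empirical plus a one-sample t-test of
#' the replicate quantifications against the theoretically expected copy
#' number. Panel two compares the replicate quantifications of every assay
#' pair per mixture with paired t-tests. BH adjustment is applied within
#' each panel family: all conditions of one comparison type at one
#' concentration label (the per-panel reading of the adjustment).
#'
#' @param theory data.frame from [theory_table()].
#' @param empirical data.frame with one row per (gbtm_name, primer_set)
#'   containing `empirical_pct`, `input_total`, a `concentration` label,
#'   and replicate quantifications in the list column `replicate_quants`.
#' @return List of data.frames `theory_vs_empirical` and `assay_vs_assay`,
#'   each with `ratio`, `p_raw`, `p_adj`, `significant`.
#' @export
study_report <- function(theory, empirical) {
  merged <- merge(empirical, theory, by = c("gbtm_name", "primer_set"))
  if (nrow(merged) < nrow(empirical)) {
    warning("conditions without matching theory were skipped", call. = FALSE)
  }
  # panel 1: theory vs empirical
  t_rows <- lapply(seq_len(nrow(merged)), function(i) {
    row <- merged[i, ]
    expected <- row$theoretical_pct / 100 * row$input_total
    quants <- row$replicate_quants[[1]]
    p <- if (expected > 0) one_sample_test(quants, expected) else NA_real_
    emp <- row$empirical_pct
    data.frame(gbtm_name = row$gbtm_name, primer_set = row$primer_set,
               concentration = row$concentration,
               theoretical_pct = row$theoretical_pct, empirical_pct = emp,
               ratio = if (!is.na(emp) && emp > 0) row$theoretical_pct / emp
                       else NA_real_,
               p_raw = p, stringsAsFactors = FALSE)
  })
  tve <- do.call(rbind, t_rows)
  tve$p_adj <- stats::ave(tve$p_raw, tve$concentration,
                          FUN = function(p) bh_adjust(p))
  tve$significant <- significance_call(tve$ratio, tve$p_adj)

  # panel 2: assay vs assay on matched replicates
  a_rows <- list()
  for (g in unique(merged$gbtm_name)) {
    sub <- merged[merged$gbtm_name == g, , drop = FALSE]
    sets <- sub$primer_set
    if (length(sets) < 2L) next
    cmb <- utils::combn(seq_along(sets), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      qa <- sub$replicate_quants[[i]]
      qb <- sub$replicate_quants[[j]]
      ma <- mean(qa, na.rm = TRUE); mb <- mean(qb, na.rm = TRUE)
      a_rows[[length(a_rows) + 1L]] <- data.frame(
        gbtm_name = g, set_a = sets[i], set_b = sets[j],
        concentration = sub$concentration[i],
        ratio = if (is.finite(mb) && mb > 0) ma / mb else NA_real_,
        p_raw = tryCatch(paired_test(qa, qb), error = function(e) NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  ava <- do.call(rbind, a_rows)
  if (!is.null(ava)) {
    ava$p_adj <- stats::ave(ava$p_raw, ava$concentration,
                            FUN = function(p) bh_adjust(p))
    ava$significant <- significance_call(ava$ratio, ava$p_adj)
  }
  list(theory_vs_empirical = tve, assay_vs_assay = ava)
}
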