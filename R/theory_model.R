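#' Theoretical template amplification percentage
#'
#' The binary amplifiability model: templates with at most one mismatch to
#' both primers of a set amplify at full efficiency, templates with more
#' than one mismatch do not amplify at all. The theoretical template
#' amplification percentage of a mixture under an assay is therefore 100
#' times the summed relative abundances of its amplifiable members; it is
#' independent of total concentration.
#'
#' @param design A `mixture_design`.
#' @param amat An [amplifiability_matrix()] covering the design's templates.
#' @param set_name Primer-set (assay) name, a column of the matrix.
#' @return A `theoretical_result`: list with `gbtm_name`, `primer_set`,
#'   `theoretical_pct`, `amplifiable_ids`.
#' @export
theoretical_amp_pct <- function(design, amat, set_name) {
  stopifnot(inherits(design, "mixture_design"),
            inherits(amat, "amplifiability_matrix"))
  if (!set_name %in% colnames(amat$matrix)) {
    stop("unknown primer set '", set_name, "'", call. = FALSE)
  }
  ids <- names(design$abundances)
  missing <- setdiff(ids, rownames(amat$matrix))
  if (length(missing) > 0L) {
    stop("design templates absent from amplifiability matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  amp_ids <- ids[amat$matrix[ids, set_name]]
  structure(
    list(gbtm_name = design$name, primer_set = set_name,
         theoretical_pct = 100 * sum(design$abundances[amp_ids]),
         amplifiable_ids = amp_ids),
    class = "theoretical_result"
  )
}

#' Theory table over a design grid
#'
#' @param designs Named list of `mixture_design`s (see [gbtm_grid()]).
#' @param amat An [amplifiability_matrix()].
#' @param set_names Assay names (default: all matrix columns).
#' @return data.frame `gbtm_name`, `primer_set`, `theoretical_pct`.
#' @export
theory_table <- function(designs, amat, set_names = colnames(amat$matrix)) {
  rows <- list()
  for (d in designs) {
    for (s in set_names) {
      r <- theoretical_amp_pct(d, amat, s)
      rows[[length(rows) + 1L]] <- data.frame(
        gbtm_name = r$gbtm_name, primer_set = r$primer_set,
        theoretical_pct = r$theoretical_pct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise assay comparison ratios with the four-fold rule
#'
#' For every ordered pair of assays within each mixture, the ratio of
#' theoretical template amplification percentages, flagged when it reaches
#' a four-fold difference in either direction (ratio >= 4 or <= 0.25,
#' boundary inclusive). A zero-percentage denominator yields an undefined
#' (NA) ratio rather than infinity.
#'
#' @param results data.frame as from [theory_table()] (or any table with
#'   `gbtm_name`, `primer_set` and a value column named by `value_col`).
#' @param value_col Column holding the compared percentage.
#' @return data.frame `gbtm_name`, `numerator_set`, `denominator_set`,
#'   `ratio`, `exceeds_fourfold`.
#' @export
ratio_table <- function(results, value_col = "theoretical_pct") {
  rows <- list()
  for (g in unique(results$gbtm_name)) {
    sub <- results[results$gbtm_name == g, , drop = FALSE]
    sets <- unique(sub$primer_set)
    if (length(sets) < 2L) next
    for (a in sets) for (b in sets) {
      if (a == b) next
      num <- sub[[value_col]][sub$primer_set == a][1]
      den <- sub[[value_col]][sub$primer_set == b][1]
      ratio <- if (!is.na(den) && den > 0) num / den else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        gbtm_name = g, numerator_set = a, denominator_set = b,
        ratio = ratio,
        exceeds_fourfold = !is.na(ratio) && (ratio >= 4 || ratio <= 0.25),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
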