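#' Construct a degenerate primer
#'
#' @param name Primer name.
#' @param sequence IUPAC nucleotide string, written 5'->3'.
#' @param orientation `"forward"` or `"reverse"`.
#' @return A `degenerate_primer` object.
#' @export
degenerate_primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  .check_iupac(sequence, sprintf("primer '%s'", name))
  structure(
    list(name = name, sequence = toupper(sequence), orientation = orientation),
    class = "degenerate_primer"
  )
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s) 5'-%s-3' degeneracy %d\n",
              x$name, x$orientation, x$sequence, primer_degeneracy(x)))
  invisible(x)
}

#' Construct a primer set (an assay)
#'
#' A qPCR assay: a forward primer mix and a reverse primer mix, optionally
#' with expected amplicon-length bounds.
#'
#' @param name Assay name.
#' @param forward_mix List of forward [degenerate_primer()]s.
#' @param reverse_mix List of reverse [degenerate_primer()]s.
#' @param amplicon_min,amplicon_max Optional amplicon length bounds (bp).
#' @return A `primer_set` object.
#' @export
primer_set <- function(name, forward_mix, reverse_mix,
                       amplicon_min = NULL, amplicon_max = NULL) {
  if (length(forward_mix) == 0L || length(reverse_mix) == 0L) {
    stop("both primer mixes must be non-empty", call. = FALSE)
  }
  if (inherits(forward_mix, "degenerate_primer")) forward_mix <- list(forward_mix)
  if (inherits(reverse_mix, "degenerate_primer")) reverse_mix <- list(reverse_mix)
  for (p in forward_mix) {
    if (!identical(p$orientation, "forward"))
      stop("forward_mix member '", p$name, "' is not a forward primer", call. = FALSE)
  }
  for (p in reverse_mix) {
    if (!identical(p$orientation, "reverse"))
      stop("reverse_mix member '", p$name, "' is not a reverse primer", call. = FALSE)
  }
  structure(
    list(name = name, forward_mix = forward_mix, reverse_mix = reverse_mix,
         amplicon_min = amplicon_min, amplicon_max = amplicon_max),
    class = "primer_set"
  )
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("<primer_set> %s: %d forward / %d reverse primers, degeneracy %d/%d\n",
              x$name, length(x$forward_mix), length(x$reverse_mix),
              mix_degeneracy(x$forward_mix), mix_degeneracy(x$reverse_mix)))
  invisible(x)
}

#' Construct a template sequence
#'
#' @param id Template identifier.
#' @param sequence Unambiguous A/C/G/T nucleotide string.
#' @param group_label Optional label (`"common"`, `"less common"`, `"rare"`).
#' @param supercluster_label Optional phylogenetic supercluster label.
#' @return A `template_seq` object.
#' @export
template_seq <- function(id, sequence, group_label = NA_character_,
                         supercluster_label = NA_character_) {
  chars <- .check_iupac(sequence, sprintf("template '%s'", id))
  if (any(!chars %in% c("A", "C", "G", "T"))) {
    stop("template '", id, "' contains ambiguity codes; templates must be unambiguous",
         call. = FALSE)
  }
  structure(
    list(id = id, sequence = toupper(sequence), group_label = group_label,
         supercluster_label = supercluster_label),
    class = "template_seq"
  )
}

#' Count primer-template mismatches for aligned windows
#'
#' A position matches when the template base is a member of the primer
#' position's IUPAC ambiguity set (primer-side ambiguity is permissiveness,
#' never a mismatch). For a primer mix, use the minimum over member oligos
#' via [find_binding_sites()].
#'
#' @param primer_window IUPAC primer string (or concrete oligo).
#' @param template_window Unambiguous template window of the same length.
#' @return Integer mismatch count.
#' @examples
#' count_mismatches("Y", "C")  # 0: Y = {C, T}
#' count_mismatches("Y", "G")  # 1
#' @export
count_mismatches <- function(primer_window, template_window) {
  p <- .check_iupac(primer_window, "primer window")
  t <- .check_iupac(template_window, "template window")
  if (length(p) != length(t)) {
    stop("primer and template windows must have equal length", call. = FALSE)
  }
  sum(vapply(seq_along(p), function(i) !t[i] %in% IUPAC_CODES[[p[i]]], logical(1)))
}

# Mismatch counts of one IUPAC primer against every window of a template,
# vectorized over windows. Returns integer vector of length T - L + 1
# (zero-length when the template is shorter than the primer).
.window_mismatches <- function(primer_chars, template_chars) {
  L <- length(primer_chars)
  Tn <- length(template_chars)
  n_win <- Tn - L + 1L
  if (n_win < 1L) return(integer(0))
  # ok[j, i]: template position i matches primer position j
  mm <- integer(n_win)
  for (j in seq_len(L)) {
    allowed <- IUPAC_CODES[[primer_chars[j]]]
    mm <- mm + !(template_chars[seq.int(j, j + n_win - 1L)] %in% allowed)
  }
  mm
}

#' Find binding sites of a degenerate primer on a template
#'
#' Forward primers are scanned against the plus strand; reverse primers
#' against the reverse complement, with hit coordinates reported on the plus
#' strand (0-based, half-open). Searching is ungapped; a window is a hit
#' when its mismatch count (see [count_mismatches()]) is at most `max_mm`.
#'
#' @param template A [template_seq()] object.
#' @param primer A [degenerate_primer()] object.
#' @param max_mm Maximum tolerated mismatches (non-negative integer).
#' @return data.frame with columns `template_id`, `primer_name`, `strand`
#'   (`"plus"`/`"minus"`), `start`, `end`, `mismatches`, sorted by position
#'   then mismatches. Zero rows when no window qualifies or the template is
#'   shorter than the primer.
#' @export
find_binding_sites <- function(template, primer, max_mm = 1L) {
  stopifnot(inherits(template, "template_seq"), inherits(primer, "degenerate_primer"))
  if (max_mm < 0) stop("max_mm must be >= 0", call. = FALSE)
  tmpl <- strsplit(template$sequence, "")[[1]]
  L <- nchar(primer$sequence)
  Tn <- length(tmpl)
  query <- if (identical(primer$orientation, "forward")) {
    primer$sequence
  } else {
    reverse_complement(primer$sequence)
  }
  mm <- .window_mismatches(strsplit(query, "")[[1]], tmpl)
  hit <- which(mm <= max_mm)
  out <- data.frame(
    template_id = rep(template$id, length(hit)),
    primer_name = rep(primer$name, length(hit)),
    strand = rep(if (identical(primer$orientation, "forward")) "plus" else "minus",
                 length(hit)),
    start = hit - 1L,
    end = hit - 1L + L,
    mismatches = mm[hit],
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$mismatches), , drop = FALSE]
}

# All hits of a primer mix on a template: per window, the mismatch count is
# the minimum over mix members (any constituent oligo in the tube can prime).
.mix_binding_sites <- function(template, mix, max_mm) {
  hits <- do.call(rbind, lapply(mix, find_binding_sites,
                                template = template, max_mm = max_mm))
  if (is.null(hits) || nrow(hits) == 0L) return(hits)
  # collapse to best (minimum-mismatch) hit per window position
  best <- stats::aggregate(mismatches ~ start + end + strand + template_id,
                           data = hits, FUN = min)
  best[order(best$start, best$mismatches), , drop = FALSE]
}

#' Decide whether a primer set amplifies a template
#'
#' A template is amplifiable when a forward-mix hit and a reverse-mix hit
#' exist in convergent orientation (forward site upstream of the reverse
#' site on the plus strand, non-overlapping) with each mismatch count at
#' most `max_mm`. Among qualifying pairs the minimal-mismatch, outermost
#' pair defines the predicted amplicon. Optional amplicon-length bounds on
#' the primer set are enforced when present.
#'
#' @param template A [template_seq()].
#' @param pset A [primer_set()].
#' @param max_mm Mismatch tolerance per primer (default 1, the conventional
#'   in-silico coverage criterion).
#' @return List with `amplifiable` (logical), `forward_mm`, `reverse_mm`
#'   (best per-primer mismatch counts over qualifying pairs; `NA` when not
#'   amplifiable), `amplicon_start`, `amplicon_end`, `amplicon_length`.
#' @export
is_amplifiable <- function(template, pset, max_mm = 1L) {
  stopifnot(inherits(template, "template_seq"), inherits(pset, "primer_set"))
  fwd <- .mix_binding_sites(template, pset$forward_mix, max_mm)
  rev <- .mix_binding_sites(template, pset$reverse_mix, max_mm)
  not_amp <- list(amplifiable = FALSE, forward_mm = NA_integer_,
                  reverse_mm = NA_integer_, amplicon_start = NA_integer_,
                  amplicon_end = NA_integer_, amplicon_length = NA_integer_)
  if (is.null(fwd) || is.null(rev) || nrow(fwd) == 0L || nrow(rev) == 0L) {
    return(not_amp)
  }
  pairs <- merge(fwd, rev, by = "template_id", suffixes = c("_f", "_r"))
  pairs <- pairs[pairs$start_f < pairs$start_r & pairs$end_f <= pairs$start_r, ,
                 drop = FALSE]
  if (!is.null(pset$amplicon_min)) {
    pairs <- pairs[pairs$end_r - pairs$start_f >= pset$amplicon_min, , drop = FALSE]
  }
  if (!is.null(pset$amplicon_max)) {
    pairs <- pairs[pairs$end_r - pairs$start_f <= pset$amplicon_max, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) return(not_amp)
  total_mm <- pairs$mismatches_f + pairs$mismatches_r
  pairs <- pairs[total_mm == min(total_mm), , drop = FALSE]
  span <- pairs$end_r - pairs$start_f
  best <- pairs[which.max(span), , drop = FALSE]
  list(amplifiable = TRUE,
       forward_mm = as.integer(best$mismatches_f),
       reverse_mm = as.integer(best$mismatches_r),
       amplicon_start = as.integer(best$start_f),
       amplicon_end = as.integer(best$end_r),
       amplicon_length = as.integer(best$end_r - best$start_f))
}

#' Amplifiability matrix over templates and primer sets
#'
#' Evaluates [is_amplifiable()] for every (template, primer set) pair and
#' derives each template's Venn membership across assays plus its group
#' label: `"common"` (amplifiable by all sets), `"less common"` (exactly
#' two), `"rare"` (exactly one). Templates amplified by no set are labelled
#' `"none"` and flagged, since a designed template panel should contain at
#' least one binding site per template.
#'
#' @param templates List of [template_seq()] objects.
#' @param primer_sets List of [primer_set()] objects.
#' @param max_mm Mismatch tolerance per primer (default 1).
#' @return An `amplifiability_matrix`: list with `table` (long data.frame:
#'   template_id, set, forward_mm, reverse_mm, amplifiable, group_label),
#'   `matrix` (logical templates x sets), `groups` (named character vector
#'   of per-template labels), and `unamplifiable` (ids hit by no set).
#' @export
amplifiability_matrix <- function(templates, primer_sets, max_mm = 1L) {
  stopifnot(length(templates) > 0L, length(primer_sets) > 0L)
  set_names <- vapply(primer_sets, `[[`, character(1), "name")
  tmpl_ids <- vapply(templates, `[[`, character(1), "id")
  rows <- list()
  amp <- matrix(FALSE, nrow = length(templates), ncol = length(primer_sets),
                dimnames = list(tmpl_ids, set_names))
  for (i in seq_along(templates)) {
    for (j in seq_along(primer_sets)) {
      res <- is_amplifiable(templates[[i]], primer_sets[[j]], max_mm)
      amp[i, j] <- res$amplifiable
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = tmpl_ids[i], set = set_names[j],
        forward_mm = res$forward_mm, reverse_mm = res$reverse_mm,
        amplifiable = res$amplifiable, stringsAsFactors = FALSE
      )
    }
  }
  n_sets <- rowSums(amp)
  groups <- ifelse(n_sets == ncol(amp), "common",
                   ifelse(n_sets == 2L, "less common",
                          ifelse(n_sets == 1L, "rare", "none")))
  # with two assays "common" (all) takes precedence over "less common"
  names(groups) <- tmpl_ids
  table <- do.call(rbind, rows)
  table$group_label <- groups[table$template_id]
  unamp <- tmpl_ids[n_sets == 0L]
  if (length(unamp) > 0L) {
    warning("templates amplifiable by no primer set: ",
            paste(unamp, collapse = ", "), call. = FALSE)
  }
  structure(
    list(table = table, matrix = amp, groups = groups, unamplifiable = unamp,
         max_mm = max_mm),
    class = "amplifiability_matrix"
  )
}

#' @export
print.amplifiability_matrix <- function(x, ...) {
  cat(sprintf("<amplifiability_matrix> %d templates x %d primer sets (max %d MM)\n",
              nrow(x$matrix), ncol(x$matrix), x$max_mm))
  cat("amplifiable per set:",
      paste(sprintf("%s=%d", colnames(x$matrix), colSums(x$matrix)), collapse = ", "),
      "\n")
  cat("groups:", paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Write the tab-separated amplifiability report
#'
#' @param amat An [amplifiability_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_amplifiability_report <- function(amat, path) {
  utils::write.table(amat$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
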