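#' IUPAC nucleotide ambiguity sets
#'
#' Named list mapping each IUPAC nucleotide code to the set of unambiguous
#' bases it stands for.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

.check_iupac <- function(sequence, what = "sequence") {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0L) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad) > 0L) {
    stop(sprintf("non-IUPAC character '%s' in %s at position %d",
                 chars[bad[1]], what, bad[1]), call. = FALSE)
  }
  chars
}

#' Reverse-complement an IUPAC nucleotide string
#'
#' Ambiguity codes are complemented onto their mirror codes (R <-> Y,
#' B <-> V, ...), so degenerate primers can be mapped between strands.
#'
#' @param sequence IUPAC nucleotide string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(sequence) {
  chars <- .check_iupac(sequence)
  paste(rev(unname(.iupac_complement[chars])), collapse = "")
}

#' Expand a degenerate primer into its unambiguous oligonucleotides
#'
#' Every IUPAC ambiguity code is expanded into the bases it encodes; the
#' result enumerates all concrete A/C/G/T oligos the primer mix contains.
#'
#' @param primer A [degenerate_primer()] object or an IUPAC string.
#' @return Character vector of unambiguous oligos; its length equals the
#'   product of per-position ambiguity-set sizes.
#' @examples
#' expand_iupac("RY")   # "AC" "AT" "GC" "GT"
#' @export
expand_iupac <- function(primer) {
  seq <- if (inherits(primer, "degenerate_primer")) primer$sequence else primer
  chars <- .check_iupac(seq, "primer")
  sets <- IUPAC_CODES[chars]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  oligos <- do.call(paste0, rev(grid))
  sort(unique(oligos))
}

#' Degeneracy of a single primer
#'
#' The number of distinct unambiguous oligos a primer encodes, computed as
#' the product of per-position ambiguity-set sizes.
#'
#' @inheritParams expand_iupac
#' @return Integer degeneracy.
#' @export
primer_degeneracy <- function(primer) {
  seq <- if (inherits(primer, "degenerate_primer")) primer$sequence else primer
  chars <- .check_iupac(seq, "primer")
  prod(lengths(IUPAC_CODES[chars]))
}

#' Degeneracy of a primer mix
#'
#' Counts the distinct unambiguous oligos in the union of the expansions of
#' all mix members (shared oligos between members are counted once).
#'
#' @param mix List of [degenerate_primer()] objects or IUPAC strings.
#' @return Integer: size of the deduplicated oligo union.
#' @export
mix_degeneracy <- function(mix) {
  if (length(mix) == 0L) stop("primer mix must be non-empty", call. = FALSE)
  length(unique(unlist(lapply(mix, expand_iupac))))
}
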