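# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL runs expr unseeded.
with_preserved_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

geometric_mean <- function(x, na.rm = FALSE) {
  exp(mean(log(x), na.rm = na.rm))
}

#' Pielou evenness of an abundance profile
#'
#' Shannon entropy of the normalized fractions divided by its maximum
#' (`ln n`); 1 means perfectly even. Defined for n >= 2.
#'
#' @param fractions Positive abundances (normalized internally).
#' @return Evenness J in (0, 1].
#' @export
pielou_evenness <- function(fractions) {
  stopifnot(length(fractions) >= 2L, all(fractions > 0))
  p <- fractions / sum(fractions)
  h <- -sum(p * log(p))
  h / log(length(p))
}
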