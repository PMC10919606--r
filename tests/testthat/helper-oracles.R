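# Independent oracles used across the suite. These deliberately re-derive
# the quantities with their own tables and numerics, so they never share
# code with the implementation they check.

.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_mismatches <- function(primer, window) {
  p <- strsplit(primer, "")[[1]]
  w <- strsplit(window, "")[[1]]
  sum(mapply(function(pc, wc) !wc %in% .oracle_iupac[[pc]], p, w))
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# Exhaustive all-window scan for one primer on one template, both the
# plus-strand query (forward primers) and the reverse-complement query
# (reverse primers), mirroring the hit contract of find_binding_sites().
oracle_binding_sites <- function(template_seq_str, primer_seq, orientation,
                                 max_mm) {
  query <- if (orientation == "forward") primer_seq else oracle_revcomp(primer_seq)
  L <- nchar(query)
  Tn <- nchar(template_seq_str)
  hits <- list()
  if (Tn >= L) {
    for (s in seq_len(Tn - L + 1L)) {
      win <- substr(template_seq_str, s, s + L - 1L)
      mm <- oracle_mismatches(query, win)
      if (mm <= max_mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = s - 1L, end = s - 1L + L, mismatches = mm)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$mismatches), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_iupac <- function(n, codes = names(.oracle_iupac)) {
  paste(sample(codes, n, replace = TRUE,
               prob = c(rep(10, 4), rep(1, 11))), collapse = "")
}

# Numeric tangent construction for the Cy0 geometry: locate the inflection
# of the baseline-subtracted Richards curve by maximizing the central-
# difference slope, then intersect the tangent with the abscissa.
oracle_cy0_numeric <- function(b, c, d, Fmax = 1000) {
  f <- function(x) Fmax * (1 + exp((c - x) / b))^(-d)
  h <- 1e-5 * b
  slope <- function(x) (f(x + h) - f(x - h)) / (2 * h)
  opt <- stats::optimize(slope, interval = c(c - 30 * b, c + 30 * b),
                         maximum = TRUE, tol = 1e-12)
  x_star <- opt$maximum
  x_star - f(x_star) / slope(x_star)
}

# Step-up FDR adjustment applied literally from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Cached study runs shared between expensive tests.
.study_cache <- new.env(parent = emptyenv())
cached_study <- function(key, expr) {
  if (!exists(key, envir = .study_cache)) {
    assign(key, force(expr), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

make_richards_curve <- function(Fb, Fmax, b, c, d, cycles = 35) {
  x <- seq_len(cycles)
  data.frame(cycle = x,
             fluorescence = Fb + Fmax / (1 + exp((c - x) / b))^d)
}
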