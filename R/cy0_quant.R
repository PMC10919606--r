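#' Convert a dsDNA mass concentration to gene copies
#'
#' copies = mass_ng * N_A / (length_bp * 660 g/mol * 1e9 ng/g), with
#' Avogadro's number N_A = 6.022e23 and 660 g/mol per base pair of
#' double-stranded DNA. For the 390 bp standard fragment, 0.1 ng converts
#' to 2.34e8 copies.
#'
#' @param mass_ng DNA mass (ng); vectorized.
#' @param length_bp Fragment length (bp, > 0).
#' @return Copy number(s).
#' @examples
#' copies_from_mass(0.1, 390)    # 2.34e8
#' copies_from_mass(1e-7, 390)   # 2.34e2
#' @export
copies_from_mass <- function(mass_ng, length_bp = 390L) {
  stopifnot(all(mass_ng >= 0))
  if (any(length_bp <= 0)) stop("length_bp must be > 0", call. = FALSE)
  mass_ng * 6.022e23 / (length_bp * 660 * 1e9)
}

# Model function used throughout: 5-parameter Richards sigmoid.
richards_f <- function(x, Fb, Fmax, b, c, d) {
  Fb + Fmax / (1 + exp((c - x) / b))^d
}

#' Fit a 5-parameter Richards function to an amplification curve
#'
#' Model: `F(x) = Fb + Fmax / (1 + exp((c - x)/b))^d`, fitted to raw
#' fluorescence by bounded nonlinear least squares (Levenberg-Marquardt)
#' with data-driven initialization (baseline from early cycles, amplitude
#' from the range, location from the steepest cycle) and a deterministic
#' ladder of jittered restarts on failure. Non-amplifying curves — flat or
#' with no concentrated rise above the noise floor — are reported as no-fit
#' rather than an error.
#'
#' @param curve An `amplification_curve` (or data.frame with `cycle` and
#'   `fluorescence`).
#' @return A `richards_fit`: list with `Fb`, `Fmax`, `b`, `c`, `d`, `rss`,
#'   `converged`, `cy0`, and `reason` when not converged.
#' @export
fit_richards <- function(curve) {
  x <- curve$cycle
  y <- curve$fluorescence
  if (length(x) < 10L) stop("need at least 10 cycles to fit", call. = FALSE)
  no_fit <- function(reason) {
    structure(list(Fb = NA_real_, Fmax = NA_real_, b = NA_real_,
                   c = NA_real_, d = NA_real_, rss = NA_real_,
                   converged = FALSE, cy0 = NA_real_, reason = reason),
              class = "richards_fit")
  }
  rng <- max(y) - min(y)
  sigma_hat <- stats::mad(diff(y)) / sqrt(2)
  if (rng < max(10 * sigma_hat, 1e-8)) return(no_fit("amplitude below noise floor"))
  # a sigmoid concentrates its rise; a drifting baseline does not
  win <- min(10L, length(x) - 1L)
  rises <- vapply(seq_len(length(y) - win), function(i) y[i + win] - y[i],
                  numeric(1))
  if (max(rises) < 0.5 * rng) return(no_fit("no concentrated rise (flat/linear curve)"))

  fb0 <- stats::median(y[seq_len(min(5L, length(y)))])
  dy <- diff(y)
  sm <- stats::filter(dy, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- dy[is.na(sm)]
  c0 <- x[which.max(sm)]
  starts <- list(Fb = fb0, Fmax = rng, b = 1.5, c = c0, d = 1)
  lower <- c(Fb = min(y) - 2 * rng, Fmax = rng * 0.05, b = 0.05,
             c = min(x) - 5, d = 0.05)
  upper <- c(Fb = max(y), Fmax = 10 * rng, b = 15,
             c = max(x) + 15, d = 20)
  jitter_grid <- list(
    c(1, 1, 1), c(1, 0.5, 1), c(1, 2, 1), c(1, 1, 0.5), c(1, 1, 2),
    c(0.9, 1, 1), c(1.1, 2, 0.5))
  best <- NULL
  for (j in jitter_grid) {
    st <- starts
    st$c <- starts$c * j[1]
    st$b <- starts$b * j[2]
    st$d <- starts$d * j[3]
    st$b <- min(max(st$b, lower["b"]), upper["b"])
    st$c <- min(max(st$c, lower["c"]), upper["c"])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ Fb + Fmax / (1 + exp((c - x) / b))^d,
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 10000,
                                             ftol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(fit = fit, rss = rss)
      }
      # accept early when the fit explains the curve well
      if (rss < 1e-4 * sum((y - mean(y))^2)) break
    }
  }
  if (is.null(best)) return(no_fit("optimizer failed"))
  p <- as.list(stats::coef(best$fit))
  out <- structure(
    list(Fb = p$Fb, Fmax = p$Fmax, b = p$b, c = p$c, d = p$d,
         rss = best$rss, converged = TRUE, cy0 = NA_real_, reason = NULL),
    class = "richards_fit")
  out$cy0 <- compute_cy0(out)
  out
}

#' @export
print.richards_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<richards_fit> no fit:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<richards_fit> Fb=%.2f Fmax=%.2f b=%.3f c=%.3f d=%.3f rss=%.3g Cy0=%.3f\n",
      x$Fb, x$Fmax, x$b, x$c, x$d, x$rss, x$cy0))
  }
  invisible(x)
}

#' Cy0 of a Richards fit (tangent-at-inflection x-intercept)
#'
#' The Cy0 quantification cycle is the abscissa intercept of the tangent
#' drawn at the inflection point of the baseline-subtracted Richards curve.
#' For `F(x) - Fb = Fmax (1 + exp((c - x)/b))^(-d)` the inflection sits at
#' `x* = c + b log(d)` and the closed form is
#' `Cy0 = c + b log(d) - b (1 + 1/d)`.
#'
#' @param fit A converged `richards_fit`, or any list with `b`, `c`, `d`.
#' @return Cy0 in cycles.
#' @export
compute_cy0 <- function(fit) {
  b <- fit$b; c <- fit$c; d <- fit$d
  if (is.na(d) || d <= 0 || is.na(b) || b <= 0) {
    stop("Cy0 undefined: requires b > 0 and d > 0", call. = FALSE)
  }
  c + b * log(d) - b * (1 + 1 / d)
}

#' Fit a list of curves and tabulate per-well results
#'
#' @param curves List of `amplification_curve`s.
#' @return data.frame: per-well `Fb`, `Fmax`, `b`, `c`, `d`, `rss`, `cy0`,
#'   `converged`, plus any scalar metadata fields the curves carry.
#' @export
fit_curves <- function(curves) {
  rows <- lapply(seq_along(curves), function(i) {
    f <- fit_richards(curves[[i]])
    md <- attr(curves[[i]], "metadata")
    base <- data.frame(Fb = f$Fb, Fmax = f$Fmax, b = f$b, c = f$c, d = f$d,
                       rss = f$rss, cy0 = f$cy0, converged = f$converged,
                       stringsAsFactors = FALSE)
    for (nm in names(md)) {
      if (length(md[[nm]]) == 1L && is.atomic(md[[nm]])) base[[nm]] <- md[[nm]]
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a qPCR standard curve from Cy0 values
#'
#' Ordinary least-squares regression of Cy0 on log10(copies). The detection
#' limit is the lowest concentration level from which upward every level
#' has all replicate wells converged and the mean Cy0 ordering is strictly
#' monotone (decreasing with copies).
#'
#' @param cy0s Per-well Cy0 values (NA for non-converged wells).
#' @param copies Per-well copy numbers (copies/uL), same length.
#' @return A `standard_curve`: `slope` (cycles per decade), `intercept`,
#'   `r_squared`, `level_range`, `detection_limit`, `fit` (the `lm`), and
#'   the per-well data.
#' @export
build_standard_curve <- function(cy0s, copies) {
  stopifnot(length(cy0s) == length(copies), all(copies > 0))
  levels <- sort(unique(copies))
  if (length(levels) < 3L) {
    stop("need at least 3 distinct concentration levels", call. = FALSE)
  }
  ok <- is.finite(cy0s)
  if (sum(ok) < 3L) stop("too few converged wells for a calibration", call. = FALSE)
  fit <- stats::lm(cy0s[ok] ~ log10(copies[ok]))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= 0) {
    stop("calibration invalid: Cy0 must decrease with copy number", call. = FALSE)
  }
  level_ok <- vapply(levels, function(l) all(is.finite(cy0s[copies == l])),
                     logical(1))
  level_mean <- vapply(levels, function(l) mean(cy0s[copies == l]), numeric(1))
  detection_limit <- NA_real_
  for (i in seq_along(levels)) {
    if (all(level_ok[i:length(levels)]) &&
        all(diff(level_mean[i:length(levels)]) < 0)) {
      detection_limit <- levels[i]
      break
    }
  }
  structure(
    list(slope = slope, intercept = intercept,
         # collinear input triggers lm's "essentially perfect fit" warning
         r_squared = suppressWarnings(summary(fit)$r.squared),
         level_range = range(copies[ok]),
         detection_limit = detection_limit, fit = fit,
         data = data.frame(cy0 = cy0s, copies = copies)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Cy0 = %.3f %+.3f log10(copies); R2 = %.4f; LOD = %g copies/uL\n",
    x$intercept, x$slope, x$r_squared, x$detection_limit))
  invisible(x)
}

#' Quantify a sample from its Cy0
#'
#' copies = 10^((Cy0 - intercept) / slope); estimates outside the
#' calibration's level range are flagged as extrapolations.
#'
#' @param cy0 Cy0 of the sample well (cycles); vectorized.
#' @param sc A [build_standard_curve()] result.
#' @param sample_id Optional id(s) recorded in the result.
#' @return data.frame `sample_id`, `cy0`, `estimated_copies_per_ul`,
#'   `in_calibration_range`.
#' @export
quantify_sample <- function(cy0, sc, sample_id = NA_character_) {
  stopifnot(inherits(sc, "standard_curve"))
  est <- 10^((cy0 - sc$intercept) / sc$slope)
  data.frame(
    sample_id = sample_id, cy0 = cy0, estimated_copies_per_ul = est,
    in_calibration_range = is.finite(est) &
      est >= sc$level_range[1] & est <= sc$level_range[2],
    stringsAsFactors = FALSE)
}

#' Aggregate replicate quantifications on the log scale
#'
#' qPCR error is multiplicative, so replicate copy estimates are averaged
#' as a geometric mean.
#'
#' @param estimates Positive replicate copy estimates (NA dropped).
#' @return Geometric-mean copy number (NA when no finite estimate).
#' @export
aggregate_replicates <- function(estimates) {
  est <- estimates[is.finite(estimates) & estimates > 0]
  if (length(est) == 0L) return(NA_real_)
  geometric_mean(est)
}
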