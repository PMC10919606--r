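#' Mismatch-dependent amplification-efficiency model
#'
#' Maps each (template, assay) mismatch category to a per-cycle
#' amplification efficiency E (fractional increase per cycle; E = 1 is
#' perfect doubling): `e_perfect` for perfectly matched templates,
#' `e_one_mm` for one mismatch, `e_blocked` (normally 0) for more than one
#' mismatch. An overrides table (columns `template_id`, `primer_set`,
#' `efficiency`) takes precedence over the category value, because single
#' templates can amplify idiosyncratically regardless of mismatch count.
#'
#' @param e_perfect Efficiency for 0-mismatch templates (default 0.95).
#' @param e_one_mm Efficiency for 1-mismatch templates (default 0.6).
#' @param e_blocked Efficiency for >1-mismatch templates (default 0).
#' @param overrides Optional overrides data.frame.
#' @return An `efficiency_model` object.
#' @export
efficiency_model <- function(e_perfect = 0.95, e_one_mm = 0.6,
                             e_blocked = 0, overrides = NULL) {
  vals <- c(e_perfect, e_one_mm, e_blocked)
  if (any(vals < 0 | vals > 1)) {
    stop("efficiencies must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(overrides)) {
    stopifnot(all(c("template_id", "primer_set", "efficiency") %in%
                    colnames(overrides)),
              all(overrides$efficiency >= 0 & overrides$efficiency <= 1))
  }
  structure(list(e_perfect = e_perfect, e_one_mm = e_one_mm,
                 e_blocked = e_blocked, overrides = overrides),
            class = "efficiency_model")
}

#' Per-template efficiencies for one assay from an amplifiability matrix
#'
#' The mismatch category of a template under an assay is the larger of its
#' best forward and reverse mismatch counts (both primers must sit down for
#' amplification); non-amplifiable templates are blocked. Overrides in the
#' model take precedence.
#'
#' @param amat An [amplifiability_matrix()].
#' @param set_name Assay name.
#' @param model An [efficiency_model()].
#' @return Named numeric vector: per-template per-cycle efficiency.
#' @export
efficiency_from_matrix <- function(amat, set_name, model = efficiency_model()) {
  stopifnot(inherits(amat, "amplifiability_matrix"),
            inherits(model, "efficiency_model"))
  tab <- amat$table[amat$table$set == set_name, , drop = FALSE]
  if (nrow(tab) == 0L) stop("unknown primer set '", set_name, "'", call. = FALSE)
  mm <- pmax(tab$forward_mm, tab$reverse_mm)
  e <- ifelse(!tab$amplifiable | is.na(mm), model$e_blocked,
              ifelse(mm == 0L, model$e_perfect,
                     ifelse(mm == 1L, model$e_one_mm, model$e_blocked)))
  e <- stats::setNames(e, tab$template_id)
  ov <- model$overrides
  if (!is.null(ov)) {
    ov <- ov[ov$primer_set == set_name & ov$template_id %in% names(e), ,
             drop = FALSE]
    e[ov$template_id] <- ov$efficiency
  }
  e
}

#' Reaction specification for the curve simulator
#'
#' @param template_copies Named numeric vector: initial copies per template.
#' @param efficiency Named per-cycle efficiencies (same names), each in
#'   `[0, 1]`.
#' @param cycles Number of PCR cycles (default 35).
#' @param plateau_capacity Shared molecule ceiling of the reaction
#'   (default 1e11 molecules; sets where the plateau occurs).
#' @param fluorescence_scale Fluorescence units per molecule (default 3e-8,
#'   i.e. a plateau near 3000 RFU).
#' @param baseline_intercept,baseline_slope Constant and per-cycle linear
#'   drift of the background fluorescence (default 100 and 0.2 RFU).
#' @param noise_sd SD of additive Gaussian readout noise (default 15 RFU,
#'   0.5 percent of the plateau amplitude).
#' @param seed Optional seed for the noise draws.
#' @return A `reaction_spec` object.
#' @export
reaction_spec <- function(template_copies, efficiency, cycles = 35L,
                          plateau_capacity = 1e11, fluorescence_scale = 3e-8,
                          baseline_intercept = 100, baseline_slope = 0.2,
                          noise_sd = 15, seed = NULL) {
  stopifnot(all(template_copies >= 0), cycles >= 1L, plateau_capacity > 0,
            all(efficiency >= 0 & efficiency <= 1))
  if (!is.null(names(template_copies)) && !is.null(names(efficiency))) {
    efficiency <- efficiency[names(template_copies)]
    if (anyNA(efficiency)) {
      stop("efficiency missing for some templates", call. = FALSE)
    }
  } else if (length(efficiency) != length(template_copies)) {
    stop("template_copies and efficiency lengths differ", call. = FALSE)
  }
  structure(list(template_copies = template_copies, efficiency = efficiency,
                 cycles = as.integer(cycles),
                 plateau_capacity = plateau_capacity,
                 fluorescence_scale = fluorescence_scale,
                 baseline_intercept = baseline_intercept,
                 baseline_slope = baseline_slope, noise_sd = noise_sd,
                 seed = seed),
            class = "reaction_spec")
}

#' Simulate one amplification curve
#'
#' Shared-capacity logistic kinetics: each cycle, template t grows
#' `N_t <- N_t * (1 + E_t * s)` with the common saturation factor
#' `s = max(0, 1 - sum(N) / plateau_capacity)`, so all templates amplify
#' near-exponentially at their own efficiency until the pooled product
#' approaches the reaction's capacity, producing a sigmoid of Richards
#' shape. Fluorescence is `scale * sum(N) + baseline(c) + N(0, noise_sd)`.
#'
#' @param spec A [reaction_spec()].
#' @param metadata Optional named list attached to the curve.
#' @return An `amplification_curve`: data.frame `cycle`, `fluorescence`,
#'   with the per-cycle total molecule counts in `attr(, "molecules")` and
#'   `metadata` attached.
#' @export
simulate_reaction <- function(spec, metadata = list()) {
  stopifnot(inherits(spec, "reaction_spec"))
  n <- as.numeric(spec$template_copies)
  e <- as.numeric(spec$efficiency)
  total <- numeric(spec$cycles)
  for (cyc in seq_len(spec$cycles)) {
    s <- max(0, 1 - sum(n) / spec$plateau_capacity)
    n <- n * (1 + e * s)
    total[cyc] <- sum(n)
  }
  noise <- if (spec$noise_sd > 0) {
    with_preserved_rng(spec$seed, stats::rnorm(spec$cycles, 0, spec$noise_sd))
  } else {
    numeric(spec$cycles)
  }
  cycle <- seq_len(spec$cycles)
  fl <- spec$fluorescence_scale * total + spec$baseline_intercept +
    spec$baseline_slope * cycle + noise
  out <- data.frame(cycle = cycle, fluorescence = fl)
  attr(out, "molecules") <- total
  attr(out, "metadata") <- metadata
  class(out) <- c("amplification_curve", "data.frame")
  out
}

#' Simulate a 10-fold standard dilution series
#'
#' One single-template reaction per concentration level and replicate,
#' mirroring a qPCR standard series. Default levels span 2.34e2 to 2.34e8
#' copies/uL in 10-fold steps (the copy numbers of a 1e-7 to 0.1 ng/uL
#' series of a 390 bp fragment); the template volume converts
#' concentration to reaction copies.
#'
#' @param copies_levels Concentrations (copies/uL) of the series.
#' @param replicates Replicates per level (default 3).
#' @param efficiency Per-cycle efficiency of the standard template
#'   (default 0.95).
#' @param reaction_volume_ul Template volume per reaction (default 1).
#' @param seed Base seed; each well gets a distinct derived seed.
#' @param ... Further arguments passed to [reaction_spec()].
#' @return List of `amplification_curve`s; each carries metadata
#'   `copies_per_ul`, `level`, `replicate`, `well`.
#' @export
simulate_dilution_series <- function(copies_levels = 2.34 * 10^(2:8),
                                     replicates = 3L, efficiency = 0.95,
                                     reaction_volume_ul = 1, seed = NULL,
                                     ...) {
  stopifnot(all(copies_levels > 0), replicates >= 1L)
  curves <- list()
  well <- 0L
  for (li in seq_along(copies_levels)) {
    for (rep in seq_len(replicates)) {
      well <- well + 1L
      well_seed <- if (is.null(seed)) NULL else seed + 1000L * li + rep
      spec <- reaction_spec(
        template_copies = c(standard = copies_levels[li] * reaction_volume_ul),
        efficiency = c(standard = efficiency),
        seed = well_seed, ...)
      curves[[well]] <- simulate_reaction(spec, metadata = list(
        copies_per_ul = copies_levels[li], level = li, replicate = rep,
        well = well))
    }
  }
  curves
}

#' Simulate replicate reactions of a template mixture
#'
#' @param design A `mixture_design`.
#' @param efficiency Named per-template efficiencies (e.g. from
#'   [efficiency_from_matrix()]).
#' @param replicates Number of replicate reactions.
#' @param reaction_volume_ul Template volume per reaction.
#' @param poisson Poisson-sample the loaded copies per replicate.
#' @param seed Base seed; each replicate derives its own.
#' @param ... Further arguments passed to [reaction_spec()].
#' @return List of `amplification_curve`s with metadata `design`,
#'   `replicate`, `input_total` (copies/uL).
#' @export
simulate_mixture <- function(design, efficiency, replicates = 3L,
                             reaction_volume_ul = 1, poisson = FALSE,
                             seed = NULL, ...) {
  curves <- vector("list", replicates)
  for (rep in seq_len(replicates)) {
    rep_seed <- if (is.null(seed)) NULL else seed + rep
    copies <- copies_per_template(design, reaction_volume_ul,
                                  poisson = poisson, seed = rep_seed)
    spec <- reaction_spec(template_copies = copies, efficiency = efficiency,
                          seed = if (is.null(rep_seed)) NULL else rep_seed + 500000L,
                          ...)
    curves[[rep]] <- simulate_reaction(spec, metadata = list(
      design = design$name, replicate = rep,
      input_total = design$total_concentration * reaction_volume_ul))
  }
  curves
}

#' Convert curves to/from the long instrument-export format
#'
#' The long format (`condition`, `well`, `replicate`, `cycle`,
#' `fluorescence`) matches a melted real-time instrument export, so real
#' data can be substituted for simulated curves.
#'
#' @param curves List of `amplification_curve`s.
#' @return data.frame in long format.
#' @export
curves_to_long <- function(curves) {
  rows <- lapply(seq_along(curves), function(i) {
    md <- attr(curves[[i]], "metadata")
    cond <- md$design
    if (is.null(cond)) cond <- as.character(md$copies_per_ul)
    if (is.null(cond)) cond <- NA_character_
    data.frame(condition = cond,
               well = if (!is.null(md$well)) md$well else i,
               replicate = if (!is.null(md$replicate)) md$replicate else 1L,
               cycle = curves[[i]]$cycle,
               fluorescence = curves[[i]]$fluorescence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname curves_to_long
#' @param long Long-format data.frame with at least `well`, `cycle`,
#'   `fluorescence`.
#' @export
long_to_curves <- function(long) {
  stopifnot(all(c("well", "cycle", "fluorescence") %in% colnames(long)))
  lapply(split(long, long$well), function(d) {
    d <- d[order(d$cycle), , drop = FALSE]
    out <- data.frame(cycle = d$cycle, fluorescence = d$fluorescence)
    attr(out, "metadata") <- list(
      condition = d$condition[1], well = d$well[1], replicate = d$replicate[1])
    class(out) <- c("amplification_curve", "data.frame")
    out
  })
}
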