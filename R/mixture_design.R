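#' Log-normal relative-abundance profile
#'
#' Deterministic evenness-controlled profile: the n fractions are taken at
#' the midpoint quantiles (i - 0.5)/n of LogNormal(mu, sigma), normalized
#' to sum one and sorted in descending order. sigma = 0 degenerates to a
#' perfectly even profile; larger sigma gives a more uneven (dominated)
#' profile. A seeded random-draw mode is available for sensitivity
#' analyses.
#'
#' @param n Number of community members (>= 1).
#' @param mu Log-normal location parameter (natural-log scale).
#' @param sigma Log-normal scale parameter (natural-log scale, >= 0).
#' @param random Draw from the distribution instead of using quantiles.
#' @param seed Seed for the random mode.
#' @return Numeric vector of n fractions, descending, summing to 1.
#' @export
lognormal_abundance_profile <- function(n, mu = 1, sigma = 1,
                                        random = FALSE, seed = NULL) {
  stopifnot(n >= 1)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  vals <- if (random) {
    with_preserved_rng(seed, stats::rlnorm(n, meanlog = mu, sdlog = sigma))
  } else if (sigma == 0) {
    rep(exp(mu), n)
  } else {
    stats::qlnorm((seq_len(n) - 0.5) / n, meanlog = mu, sdlog = sigma)
  }
  sort(vals / sum(vals), decreasing = TRUE)
}

#' Assign an abundance profile to templates by dominance mode
#'
#' The largest fractions go to the members of the dominant group ("common"
#' or "rare" amplifiability group), the next ranks to the "less common"
#' group, and the smallest to the remaining group. Within-group order comes
#' from `priority` when given, otherwise from template order (optionally
#' shuffled under `seed`). The full assignment is recorded in the returned
#' design.
#'
#' @param profile Descending fractions from [lognormal_abundance_profile()].
#' @param templates Named list of [template_seq()] objects carrying
#'   `group_label`s (e.g. from [dsrb_reference()]).
#' @param mode `"common"` or `"rare"`: which group dominates.
#' @param total_concentration Total template concentration (copies/uL).
#' @param mu,sigma Profile parameters, recorded for provenance.
#' @param priority Optional named list of within-group id orderings (as
#'   [dsrb_dominance_priority()]).
#' @param seed Optional seed for within-group shuffling.
#' @param name Design name; default is derived from mode and sigma.
#' @return A `mixture_design` object.
#' @export
assign_dominance <- function(profile, templates, mode = c("common", "rare"),
                             total_concentration = 1e8, mu = NA_real_,
                             sigma = NA_real_, priority = NULL, seed = NULL,
                             name = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(profile) == length(templates))
  ids <- vapply(templates, `[[`, character(1), "id")
  groups <- vapply(templates, function(t) t$group_label, character(1))
  names(groups) <- ids
  if (anyNA(groups)) {
    stop("templates must carry group labels (run amplifiability_matrix first)",
         call. = FALSE)
  }
  dominant <- mode
  tail_group <- setdiff(c("common", "rare"), mode)
  if (!any(groups == dominant)) {
    stop("dominant group '", dominant, "' has no members", call. = FALSE)
  }
  order_within <- function(group) {
    members <- ids[groups == group]
    if (!is.null(priority) && !is.null(priority[[group]])) {
      pri <- priority[[group]]
      if (!setequal(pri, members)) {
        stop("priority for group '", group, "' does not match its members",
             call. = FALSE)
      }
      pri
    } else if (!is.null(seed)) {
      with_preserved_rng(seed, sample(members))
    } else {
      members
    }
  }
  ranked_ids <- c(order_within(dominant),
                  order_within("less common"),
                  order_within(tail_group))
  ranked_ids <- c(ranked_ids, setdiff(ids, ranked_ids))  # any "none" last
  abundances <- stats::setNames(sort(profile, decreasing = TRUE), ranked_ids)
  abundances <- abundances[ids]  # template order
  if (is.null(name)) {
    name <- sprintf("%s_mu%g_sigma%g", mode, mu, sigma)
  }
  structure(
    list(name = name, abundances = abundances, dominance_mode = mode,
         mu = mu, sigma = sigma, total_concentration = total_concentration,
         seed = seed,
         assignment = data.frame(template_id = ranked_ids,
                                 rank = seq_along(ranked_ids),
                                 fraction = sort(profile, decreasing = TRUE),
                                 group_label = unname(groups[ranked_ids]),
                                 stringsAsFactors = FALSE)),
    class = "mixture_design"
  )
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design> %s: %d templates, %s-dominated, sigma=%g, %g copies/uL\n",
              x$name, length(x$abundances), x$dominance_mode, x$sigma,
              x$total_concentration))
  invisible(x)
}

#' Absolute template copies loaded into a reaction
#'
#' copies_i = abundance_i x total_concentration x template volume. With
#' `poisson = TRUE` the (possibly fractional) expectations are replaced by
#' seeded Poisson draws, modelling the loading stochasticity that matters
#' at low template concentration.
#'
#' @param design A `mixture_design`.
#' @param reaction_volume_ul Template volume added to the reaction (uL).
#' @param poisson Poisson-sample the copy numbers.
#' @param seed Seed for the Poisson draws.
#' @return Named numeric vector of per-template copies.
#' @export
copies_per_template <- function(design, reaction_volume_ul = 1,
                                poisson = FALSE, seed = NULL) {
  stopifnot(inherits(design, "mixture_design"), reaction_volume_ul > 0)
  expected <- design$abundances * design$total_concentration * reaction_volume_ul
  if (!poisson) return(expected)
  with_preserved_rng(seed, {
    draws <- stats::rpois(length(expected), expected)
    stats::setNames(as.numeric(draws), names(expected))
  })
}

#' Full study grid of mixture designs
#'
#' Builds the 2 dominance x length(sigmas) x 2 concentration grid of gBTM
#' designs used by the study: common- and rare-dominated mixtures at each
#' unevenness level, each at a high and a low total template concentration.
#'
#' @param templates Labelled templates (see [assign_dominance()]).
#' @param sigmas Log-normal scale values (default `c(1, 2, 5)`).
#' @param mu Log-normal location (default 1).
#' @param concentrations Named vector of total concentrations (copies/uL),
#'   default `c(high = 1e8, low = 1e5)`.
#' @param priority Optional within-group priorities.
#' @param seed Optional shuffling seed (unused when priority is given).
#' @return Named list of `mixture_design` objects; names are
#'   `<mode>_s<sigma>_<conc>`.
#' @export
gbtm_grid <- function(templates, sigmas = c(1, 2, 5), mu = 1,
                      concentrations = c(high = 1e8, low = 1e5),
                      priority = NULL, seed = NULL) {
  out <- list()
  n <- length(templates)
  for (mode in c("common", "rare")) {
    for (sigma in sigmas) {
      profile <- lognormal_abundance_profile(n, mu, sigma)
      for (ci in seq_along(concentrations)) {
        label <- sprintf("%s_s%g_%s", mode, sigma, names(concentrations)[ci])
        out[[label]] <- assign_dominance(
          profile, templates, mode,
          total_concentration = unname(concentrations[ci]),
          mu = mu, sigma = sigma, priority = priority, seed = seed,
          name = label
        )
      }
    }
  }
  out
}

#' Write a tab-separated design table
#'
#' @param design A `mixture_design`.
#' @param path Output TSV path.
#' @param reaction_volume_ul Template volume used for the copies column.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path, reaction_volume_ul = 1) {
  tab <- design$assignment
  tab$copies_in_reaction <- tab$fraction * design$total_concentration *
    reaction_volume_ul
  tab$design <- design$name
  tab$dominance_mode <- design$dominance_mode
  tab$sigma <- design$sigma
  tab$total_concentration <- design$total_concentration
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
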