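# Synthetic red-cell populations: per-cell physical state sampled from a
# declared distribution spec. Every downstream assay (osmotic fragility,
# microfluidics, cytometry) consumes these cells.

#' Declare a synthetic RBC population
#'
#' Builds a validated specification from which [sample_population()] draws
#' per-cell physical parameters. Each scalar field is described by a
#' mean/SD pair (SD 0 gives a degenerate, constant field); the transit
#' velocity is described as a three-component mixture (main peak near
#' 1 a.u., optional slow tail below the occlusion-prone regime, optional
#' fast tail).
#'
#' Defaults describe a healthy control population: isotonic volume
#' 90 +/- 5 fL with an osmotically inactive (nonsolvent) volume of about
#' 55% of the isotonic volume, lysis threshold 142 +/- 8 mOsmol, oblate
#' axis ratio 0.30 +/- 0.03 (flattened discocyte), a single velocity
#' component at 1.0 +/- 0.15 a.u. and no adhesion.
#'
#' @param group_label Treatment group name (e.g. "Control", "TAX").
#' @param n_cells Number of cells to draw; must be positive.
#' @param v300 List with `mean` and `sd` (fL): isotonic cell volume.
#' @param vs List with `mean` and `sd` (fL): osmotically inactive volume.
#'   Draws are clamped into (0, 0.99 * v300) to keep cells physical.
#' @param lysis_osm List with `mean` and `sd` (mOsmol): osmolality at
#'   which the cell lyses.
#' @param axis_ratio List with `mean` and `sd`: oblate-spheroid axis
#'   ratio q in (0, 1]; 1 is a sphere.
#' @param velocity Named list of mixture components `main`, `slow`,
#'   `fast`, each a list with `weight`, `mean`, `sd` and optional
#'   truncation bounds `lower`/`upper` (normalized velocity, a.u.).
#'   Weights must be nonnegative and sum to 1.
#' @param adhesion_propensity Per-transit probability of arresting in a
#'   microchannel, in \[0, 1\] (scalar applied to all cells, or a list
#'   with `mean`/`sd`).
#' @param esterase_activity List with `mean` and `sd`: relative
#'   enzymatic vitality, clamped to \[0, 1\].
#' @param ps_exposed_prob Probability that a cell externalizes
#'   phosphatidylserine.
#' @param seed Optional RNG seed recorded in the spec and used by
#'   [sample_population()].
#' @return An object of class `population_spec`.
#' @seealso [sample_population()]
#' @export
population_spec <- function(group_label = "Control",
                            n_cells = 5000L,
                            v300 = list(mean = 90, sd = 5),
                            vs = list(mean = 49.5, sd = 3),
                            lysis_osm = list(mean = 142, sd = 8),
                            axis_ratio = list(mean = 0.30, sd = 0.03),
                            velocity = list(
                              main = list(weight = 1, mean = 1.0, sd = 0.15,
                                          lower = 0, upper = Inf),
                              slow = list(weight = 0, mean = 0.10, sd = 0.03,
                                          lower = 0, upper = 0.175),
                              fast = list(weight = 0, mean = 1.6, sd = 0.10,
                                          lower = 0, upper = Inf)),
                            adhesion_propensity = 0,
                            esterase_activity = list(mean = 1, sd = 0),
                            ps_exposed_prob = 0,
                            seed = NULL) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("`n_cells` must be a positive count", call. = FALSE)
  n_cells <- as.integer(n_cells)

  check_ms <- function(x, name) {
    if (!is.list(x) || is.null(x$mean) || is.null(x$sd))
      stop(sprintf("`%s` must be a list with `mean` and `sd`", name),
           call. = FALSE)
    if (x$sd < 0)
      stop(sprintf("`%s$sd` must be nonnegative", name), call. = FALSE)
    x
  }
  v300 <- check_ms(v300, "v300")
  vs <- check_ms(vs, "vs")
  lysis_osm <- check_ms(lysis_osm, "lysis_osm")
  axis_ratio <- check_ms(axis_ratio, "axis_ratio")
  esterase_activity <- check_ms(esterase_activity, "esterase_activity")
  if (is.numeric(adhesion_propensity))
    adhesion_propensity <- list(mean = adhesion_propensity, sd = 0)
  adhesion_propensity <- check_ms(adhesion_propensity, "adhesion_propensity")
  if (adhesion_propensity$mean < 0 || adhesion_propensity$mean > 1)
    stop("`adhesion_propensity` mean must lie in [0, 1]", call. = FALSE)
  if (ps_exposed_prob < 0 || ps_exposed_prob > 1)
    stop("`ps_exposed_prob` must lie in [0, 1]", call. = FALSE)

  comp_names <- c("main", "slow", "fast")
  if (!all(names(velocity) %in% comp_names) || is.null(velocity$main))
    stop("`velocity` must name components among main/slow/fast", call. = FALSE)
  for (nm in comp_names) {
    if (is.null(velocity[[nm]]))
      velocity[[nm]] <- list(weight = 0, mean = 1, sd = 0)
    comp <- velocity[[nm]]
    if (is.null(comp$lower)) comp$lower <- 0
    if (is.null(comp$upper)) comp$upper <- Inf
    if (is.null(comp$weight) || comp$weight < 0)
      stop(sprintf("velocity component `%s` needs a nonnegative weight", nm),
           call. = FALSE)
    if (comp$sd < 0)
      stop(sprintf("velocity component `%s` has negative sd", nm),
           call. = FALSE)
    velocity[[nm]] <- comp
  }
  w <- vapply(velocity, function(c) c$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8)
    stop("velocity mixture weights must sum to 1 (got ",
         format(sum(w)), ")", call. = FALSE)

  structure(list(group_label = group_label,
                 n_cells = n_cells,
                 v300 = v300, vs = vs,
                 lysis_osm = lysis_osm,
                 axis_ratio = axis_ratio,
                 velocity = velocity[comp_names],
                 adhesion_propensity = adhesion_propensity,
                 esterase_activity = esterase_activity,
                 ps_exposed_prob = ps_exposed_prob,
                 seed = seed),
            class = "population_spec")
}

# Truncated-normal draw by inverse-CDF; degenerate sd collapses to the mean
# (clamped into the truncation interval).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Draw a synthetic RBC population
#'
#' Samples `spec$n_cells` cells, one row per cell, with every field drawn
#' independently from the distributions declared in the spec. Draws are
#' reproducible: the same spec and seed give bit-identical populations.
#'
#' @param spec A [population_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A `data.frame` with columns `v300`, `vs`, `lysis_osm`,
#'   `axis_ratio`, `velocity_factor`, `velocity_component`,
#'   `adhesion_propensity`, `esterase_activity`, `ps_exposed`, and the
#'   group label as attribute `group_label`.
#' @examples
#' cells <- sample_population(population_spec(n_cells = 100, seed = 1))
#' summary(cells$lysis_osm)
#' @export
sample_population <- function(spec, seed = NULL) {
  if (!inherits(spec, "population_spec"))
    stop("`spec` must be a population_spec", call. = FALSE)
  seed <- if (!is.null(seed)) seed else spec$seed
  if (!is.null(seed)) withr::local_seed(seed)
  n <- spec$n_cells

  v300 <- rnorm_trunc(n, spec$v300$mean, spec$v300$sd, lower = 1)
  vs <- rnorm_trunc(n, spec$vs$mean, spec$vs$sd, lower = 1e-3)
  vs <- pmin(vs, 0.99 * v300)
  lysis <- rnorm_trunc(n, spec$lysis_osm$mean, spec$lysis_osm$sd,
                       lower = 1e-3)
  q <- rnorm_trunc(n, spec$axis_ratio$mean, spec$axis_ratio$sd,
                   lower = 1e-3, upper = 1)

  w <- vapply(spec$velocity, function(c) c$weight, numeric(1))
  comp <- sample(names(spec$velocity), n, replace = TRUE, prob = w)
  vel <- numeric(n)
  for (nm in names(spec$velocity)) {
    idx <- which(comp == nm)
    c <- spec$velocity[[nm]]
    vel[idx] <- rnorm_trunc(length(idx), c$mean, c$sd, c$lower, c$upper)
  }
  vel <- pmax(vel, 0)

  adh <- rnorm_trunc(n, spec$adhesion_propensity$mean,
                     spec$adhesion_propensity$sd, lower = 0, upper = 1)
  est <- rnorm_trunc(n, spec$esterase_activity$mean,
                     spec$esterase_activity$sd, lower = 0, upper = 1)
  ps <- stats::runif(n) < spec$ps_exposed_prob

  cells <- data.frame(v300 = v300, vs = vs, lysis_osm = lysis,
                      axis_ratio = q, velocity_factor = vel,
                      velocity_component = comp,
                      adhesion_propensity = adh,
                      esterase_activity = est,
                      ps_exposed = ps)
  attr(cells, "group_label") <- spec$group_label
  cells
}
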