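#' Functional-type richness
#'
#' Number of types with a strictly positive total population.
#'
#' @param per_ft_totals Numeric vector of per-type landscape totals.
#' @return Integer count.
#' @export
ft_richness <- function(per_ft_totals) {
  if (any(per_ft_totals < 0)) stop("totals must be nonnegative")
  sum(per_ft_totals > 0)
}

#' Shannon diversity of the community
#'
#' `H = -sum(p_i * log(p_i))` in nats over the positive totals, with
#' `p_i = n_i / sum(n)`. All-zero input is an error (diversity undefined).
#'
#' @param per_ft_totals Numeric vector of per-type landscape totals.
#' @return Shannon index in nats; 0 for a monoculture, `log(S)` for `S`
#'   equal totals.
#' @export
shannon <- function(per_ft_totals) {
  if (any(per_ft_totals < 0)) stop("totals must be nonnegative")
  if (sum(per_ft_totals) == 0)
    stop("undefined diversity: all totals are zero")
  unname(vegan::diversity(per_ft_totals, index = "shannon"))
}

#' Quasi-extinction threshold for a landscape
#'
#' The reference threshold is 10,000 individuals on a 9 km^2 landscape,
#' i.e. a density of 10,000/9e6 individuals per m^2; other landscape sizes
#' scale by area so that scaled-down runs stay comparable.
#'
#' @param area_m2 Landscape area in m^2 (or a `bee_landscape`).
#' @return Threshold in individuals.
#' @export
quasi_extinction_threshold <- function(area_m2) {
  if (inherits(area_m2, "bee_landscape")) area_m2 <- landscape_area_m2(area_m2)
  10000 * area_m2 / 9e6
}

#' Quasi-extinction risk
#'
#' Fraction of repetitions in which the trajectory falls below the
#' threshold at least once within the evaluation window (default: the last
#' 10 simulated years). Risks take values on the grid `{0, 1/R, ..., 1}`.
#'
#' @param trajectories Matrix `repetitions x years` of abundance series;
#'   columns named by year ("0", "1", ...). A vector is treated as one
#'   repetition.
#' @param threshold Quasi-extinction threshold in individuals.
#' @param window Length-2 numeric `c(from, to)` in year units, both
#'   inclusive; default the last 10 years of the series.
#' @return Risk in `[0, 1]`.
#' @export
quasi_extinction_risk <- function(trajectories, threshold, window = NULL) {
  if (is.vector(trajectories)) trajectories <- matrix(trajectories, 1)
  yrs <- as.numeric(colnames(trajectories))
  if (is.null(colnames(trajectories))) yrs <- seq_len(ncol(trajectories)) - 1
  if (is.null(window)) window <- c(max(min(yrs), max(yrs) - 10), max(yrs))
  if (window[1] < min(yrs) || window[2] > max(yrs))
    stop("window lies outside the simulated years")
  sel <- yrs >= window[1] & yrs <= window[2]
  mean(apply(trajectories[, sel, drop = FALSE], 1,
             function(x) any(x < threshold)))
}

#' Per-type quasi-extinction risks of a run
#'
#' @param run A `bee_run` from [run_simulation()].
#' @param threshold Defaults to the area-scaled landscape threshold.
#' @param window Passed to [quasi_extinction_risk()].
#' @return Named numeric vector of per-type risks.
#' @export
run_qe_risk <- function(run, threshold = NULL, window = NULL) {
  if (is.null(threshold))
    threshold <- quasi_extinction_threshold(run$landscape_area_m2)
  S <- dim(run$totals)[3]
  vapply(seq_len(S), function(s)
    quasi_extinction_risk(run$totals[, , s, drop = TRUE], threshold, window),
    numeric(1)) |> setNames(dimnames(run$totals)[[3]])
}

#' Trait codings for community-weighted means
#'
#' Flying period codes 1 (first half), 2 (second half), 3 (both);
#' foraging/dispersal range codes 1/2/3 for short/medium/long (ordinal,
#' default) or the kernel mean in meters; disturbance susceptibility is the
#' type's `dist_eff`.
#'
#' @param community A `bee_community`.
#' @param foraging One of `"ordinal"`, `"meters"`.
#' @return Data frame of coded trait values per type.
#' @export
trait_coding <- function(community, foraging = c("ordinal", "meters")) {
  foraging <- match.arg(foraging)
  data.frame(
    ft_id = community$ft_id,
    foraging = if (foraging == "ordinal")
      match(community$foraging_distance, c("short", "medium", "long"))
    else community$disp_mean,
    flying_period = match(community$flying_period,
                          c("first", "second", "both")),
    disturbance_susceptibility = community$dist_eff)
}

#' Community-weighted trait means
#'
#' Abundance-weighted averages `sum(n_i * x_i) / sum(n_i)` of the coded
#' traits ([trait_coding()]).
#'
#' @param per_ft_totals Numeric vector of per-type totals (positive sum).
#' @param community A `bee_community`.
#' @param foraging Passed to [trait_coding()].
#' @return Named numeric vector with elements `foraging`, `flying_period`,
#'   `disturbance_susceptibility`.
#' @export
community_weighted_mean <- function(per_ft_totals, community,
                                    foraging = c("ordinal", "meters")) {
  if (sum(per_ft_totals) <= 0)
    stop("community-weighted means need a positive total abundance")
  coding <- trait_coding(community, foraging)
  w <- per_ft_totals / sum(per_ft_totals)
  c(foraging = sum(w * coding$foraging),
    flying_period = sum(w * coding$flying_period),
    disturbance_susceptibility = sum(w * coding$disturbance_susceptibility))
}

#' Feeding-intensity map
#'
#' Per cell, the sum over all foraging populations of population size times
#' their competition-dependent resource uptake in that cell -- exactly the
#' uptake entering the growth function. Around ABZ cells this visualizes the
#' spill-over of foraging activity into adjacent patches.
#'
#' @param state A `bee_state` (typically a final-year state).
#' @param ls A `bee_landscape`.
#' @param community A `bee_community`.
#' @param config A [sim_config()].
#' @return Numeric matrix `n_rows x n_cols`; water cells carry 0.
#' @export
feeding_intensity_map <- function(state, ls, community,
                                  config = sim_config()) {
  occ <- occupancy_grids(state, ls, community, config)
  fi <- rowSums(occ$F * occ$uptake)
  matrix(fi, ls$n_rows, ls$n_cols)
}

#' Land-use-scale summary of a run
#'
#' Summaries per land-use class under the patch filter used for class-scale
#' analyses: all arable patches, and only forest/grassland patches adjacent
#' to an arable cell or an ABZ. Reports mean final-year abundance, density
#' per m^2, and the mean per-type quasi-extinction risk at the class-scale
#' density threshold (0.001 individuals per m^2 by default).
#'
#' @param run A `bee_run` recorded with `record_landuse = TRUE`.
#' @param threshold_density Class-scale quasi-extinction density threshold
#'   (individuals per m^2).
#' @param window Passed to [quasi_extinction_risk()].
#' @return Data frame with one row per class: `class`, `cells`,
#'   `abundance` (mean over repetitions, final year, all types),
#'   `density_m2`, `qe_risk` (mean over types).
#' @export
landuse_scale_summary <- function(run, threshold_density = 0.001,
                                  window = NULL) {
  if (is.null(run$landuse_totals))
    stop("run was not recorded with record_landuse = TRUE")
  classes <- dimnames(run$landuse_totals)[[3]]
  S <- dim(run$landuse_totals)[4]
  out <- lapply(seq_along(classes), function(m) {
    cells <- sum(run$landuse_masks[[m]])
    area <- cells * run$cell_size_m^2
    tot <- run$landuse_totals[, , m, , drop = FALSE]
    dn <- dimnames(run$landuse_totals)
    final <- tot[, dim(tot)[2], 1, , drop = TRUE]
    if (is.null(dim(final))) final <- matrix(final, ncol = S)
    abundance <- mean(rowSums(final))
    risks <- vapply(seq_len(S), function(s) {
      traj <- matrix(tot[, , 1, s], nrow = dim(tot)[1],
                     dimnames = list(NULL, dn[[2]]))
      if (area == 0) return(1)
      quasi_extinction_risk(traj, threshold_density * area, window)
    }, numeric(1))
    data.frame(class = classes[m], cells = cells, abundance = abundance,
               density_m2 = if (area > 0) abundance / area else 0,
               qe_risk = mean(risks))
  })
  do.call(rbind, out)
}
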