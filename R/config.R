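#' Simulation configuration
#'
#' Bundles the engine-level parameters with the module configurations.
#' Defaults reproduce the standard study conditions: 50 simulated years,
#' 10 repetitions, 1000 initial individuals per functional type, weather
#' standard deviation 0.15, per-cell capacity scale `k_max = 50`,
#' extinction threshold 1 individual, the printed resource-uptake form,
#' 10 dispersal search attempts, and land-use disturbance probabilities
#' arable 1.0, grassland 0.8, bare 0.7, urban 0.7, forest 0.3, water 0.
#'
#' @param years Simulated years (default 50).
#' @param repetitions Independent repetitions (default 10).
#' @param base_seed Integer; repetition `r` runs under seed
#'   `base_seed + r`.
#' @param initial_individuals_per_ft Individuals placed per type at year 0
#'   (default 1000).
#' @param weather_std Weather standard deviation (default 0.15).
#' @param k_max Per-cell nesting capacity scale (default 50).
#' @param extinction_threshold Populations below this size are removed
#'   after growth (default 1).
#' @param uptake_form `"printed"` (default) or `"inverted"`, see
#'   [cell_resource_uptake()].
#' @param dispersal_tries Maximal settlement search attempts (default 10).
#' @param disturbance_prob Named probabilities per land-use class.
#' @param abz_order Arable-patch order for ABZ conversion,
#'   `"descending"` (default) or `"ascending"`.
#' @param record_landuse Record per-land-use-class abundance series
#'   (needed by [landuse_scale_summary()]; default `FALSE`).
#' @param record_final_state Keep the final-year per-cell state of each
#'   repetition (default `FALSE`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(years = 50, repetitions = 10, base_seed = 0,
                       initial_individuals_per_ft = 1000,
                       weather_std = 0.15, k_max = 50,
                       extinction_threshold = 1,
                       uptake_form = c("printed", "inverted"),
                       dispersal_tries = 10,
                       disturbance_prob = NULL,
                       abz_order = c("descending", "ascending"),
                       record_landuse = FALSE,
                       record_final_state = FALSE) {
  uptake_form <- match.arg(uptake_form)
  abz_order <- match.arg(abz_order)
  if (years < 1 || repetitions < 1)
    stop("years and repetitions must be >= 1")
  if (is.null(disturbance_prob))
    disturbance_prob <- c(bare = 0.7, arable = 1.0, forest = 0.3,
                          grassland = 0.8, urban = 0.7, water = 0.0)
  disturbance_prob <- disturbance_prob[lu_names()]
  if (any(is.na(disturbance_prob)))
    stop("disturbance_prob must name all land-use classes")
  if (any(disturbance_prob < 0 | disturbance_prob > 1))
    stop("disturbance probabilities must lie in [0, 1]")
  if (dispersal_tries < 1) stop("dispersal_tries must be >= 1")
  structure(list(years = as.integer(years),
                 repetitions = as.integer(repetitions),
                 base_seed = as.integer(base_seed),
                 initial_individuals_per_ft = initial_individuals_per_ft,
                 weather_std = weather_std, k_max = k_max,
                 extinction_threshold = extinction_threshold,
                 uptake_form = uptake_form,
                 dispersal_tries = as.integer(dispersal_tries),
                 disturbance_prob = disturbance_prob,
                 abz_order = abz_order,
                 record_landuse = record_landuse,
                 record_final_state = record_final_state),
            class = "sim_config")
}
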