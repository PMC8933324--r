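#' Population state
#'
#' Per-cell, per-type nesting abundances for one year. Abundances are stored
#' as an `n_cells x S` matrix in column-major cell order (cell index
#' `(col - 1) * n_rows + row`), one column per functional type.
#'
#' @param abundance Nonnegative numeric matrix, `n_cells x S`.
#' @param year Integer simulation year (0 = initial state).
#' @param community The `bee_community` the columns refer to (optional,
#'   used for column names).
#' @return A `bee_state` object.
#' @export
population_state <- function(abundance, year = 0L, community = NULL) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundances must be nonnegative")
  if (!is.null(community)) colnames(abundance) <- community$ft_id
  structure(list(abundance = abundance, year = as.integer(year)),
            class = "bee_state")
}

#' @export
print.bee_state <- function(x, ...) {
  cat("<bee_state> year ", x$year, ": ", nrow(x$abundance), " cells x ",
      ncol(x$abundance), " types, total ",
      format(sum(x$abundance), digits = 6), " individuals\n", sep = "")
  invisible(x)
}

# community columns as matrices/vectors for the C++ core
community_matrices <- function(community) {
  list(r = community$r, cc = community$c,
       forage = as.matrix(community[paste0("forage_", lu_names())]),
       nest = as.matrix(community[paste0("nest_", lu_names())]),
       trans_res = community$trans_effect_res,
       trans_nest = community$trans_effect_nest,
       b = community$b, period = period_code(community$flying_period),
       disp_mean = community$disp_mean, disp_sd = community$disp_sd,
       mu = community$emigration_mu, omega = community$emigration_omega)
}

# foraging radius in cells: radius equals the dispersal-kernel mean (the
# movement scale of the type), converted by the cell size
foraging_radius_cells <- function(community, ls) {
  community$disp_mean / ls$cell_size_m
}

#' Draw the yearly weather factor
#'
#' One global multiplier per landscape-year, drawn from a normal
#' distribution with mean 1 truncated at 0 (negative draws are rejected).
#' With `weather_std = 0` the factor is exactly 1.
#'
#' @param weather_std Standard deviation (default 0.15).
#' @param n Number of draws.
#' @return Numeric vector of nonnegative weather factors.
#' @export
draw_weather <- function(weather_std = 0.15, n = 1) {
  if (weather_std < 0) stop("weather_std must be >= 0")
  if (weather_std == 0) return(rep(1, n))
  vapply(seq_len(n), function(i) {
    repeat {
      x <- rnorm(1, 1, weather_std)
      if (x >= 0) return(x)
    }
  }, numeric(1))
}

#' Cells within a population's foraging range
#'
#' All cells whose center-to-center Euclidean distance to the focal cell is
#' at most `radius_m`, clipped at the landscape boundary; includes the focal
#' cell. Radius 0 returns the focal cell only.
#'
#' @param ls A `bee_landscape`.
#' @param cell Integer vector `c(row, col)` (1-based).
#' @param radius_m Foraging radius in meters (the type's dispersal mean).
#' @return Two-column integer matrix of (row, col) coordinates.
#' @export
foraging_cells <- function(ls, cell, radius_m) {
  r_cells <- radius_m / ls$cell_size_m
  R <- floor(r_cells)
  offs <- expand.grid(dr = -R:R, dc = -R:R)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r_cells^2, , drop = FALSE]
  out <- cbind(cell[1] + offs$dr, cell[2] + offs$dc)
  out[out[, 1] >= 1 & out[, 1] <= ls$n_rows &
      out[, 2] >= 1 & out[, 2] <= ls$n_cols, , drop = FALSE]
}

#' Interspecific competition load
#'
#' The heterospecific load on a focal type in one cell:
#' `beta = sum_i (1 + (c_focal - c_i) / c_total) * n_i` over nonconspecific
#' types `i` with overlapping flying period. When `c_total = 0` the scaled
#' term is dropped; the result is clamped at 0. Stronger competitors carry
#' lower `c`, so a focal type with low `c` discounts its competitors'
#' abundances while a weak competitor feels them amplified.
#'
#' @param c_focal Competition factor of the focal type.
#' @param c_others,n_others Competition factors and abundances of the
#'   nonconspecific types sharing the cell (overlapping periods only).
#' @param c_total Sum of competition factors of all types present in the
#'   cell; defaults to `c_focal + sum(c_others[n_others > 0])`.
#' @return Nonnegative competition load.
#' @export
competition_load <- function(c_focal, c_others, n_others,
                             c_total = c_focal + sum(c_others[n_others > 0])) {
  if (length(c_others) == 0) return(0)
  w <- if (c_total > 0) 1 + (c_focal - c_others) / c_total else
    rep(1, length(c_others))
  max(0, sum(w * n_others))
}

#' Competition-dependent resource uptake in one cell
#'
#' Printed form (default): `uptake = ((beta + n_focal) / n_total) * suit`;
#' the ratio is taken as 1 when `n_total = 0`. The `inverted` form computes
#' `(n_total / (beta + n_focal)) * suit` instead, so that a larger
#' heterospecific load depresses rather than inflates uptake (mechanism
#' switch; see the methods vignette).
#'
#' @param beta Competition load ([competition_load()]).
#' @param n_focal Foraging abundance of the focal type in the cell.
#' @param n_total Total foraging abundance of overlapping-period types.
#' @param suitability Effective foraging suitability of the cell (land-use
#'   value plus `trans_effect_res` on ABZ cells).
#' @param form `"printed"` (default) or `"inverted"`.
#' @return Nonnegative uptake.
#' @export
cell_resource_uptake <- function(beta, n_focal, n_total, suitability,
                                 form = c("printed", "inverted")) {
  form <- match.arg(form)
  ratio <- if (form == "printed") {
    if (n_total > 0) (beta + n_focal) / n_total else 1
  } else {
    if (beta + n_focal > 0) n_total / (beta + n_focal) else 1
  }
  ratio * suitability
}

#' Nesting capacity of a cell
#'
#' `K = k_max * (nest_suitability + trans_effect_nest * abz)`; water cells
#' have suitability 0 and hence capacity 0.
#'
#' @param nest_suit Land-use nesting suitability for the type.
#' @param abz Logical ABZ flag of the cell.
#' @param trans_effect_nest ABZ nesting bonus (default 1).
#' @param k_max Per-cell capacity scale in individuals (default 50).
#' @return Nonnegative capacity (vectorized over inputs).
#' @export
nest_capacity <- function(nest_suit, abz = FALSE, trans_effect_nest = 1,
                          k_max = 50) {
  k_max * (nest_suit + ifelse(abz, trans_effect_nest, 0))
}

# capacity grid for all types: n_cells x S
capacity_grid <- function(ls, community, k_max) {
  cm <- community_matrices(community)
  lu <- as.integer(ls$land_use)
  abz <- as.vector(ls$abz)
  S <- nrow(community)
  K <- matrix(0, length(lu), S)
  for (s in seq_len(S))
    K[, s] <- k_max * (cm$nest[s, lu + 1L] + ifelse(abz, cm$trans_nest[s], 0))
  K
}

#' Maynard Smith-Slatkin population growth
#'
#' `n_next = n * r * weather * mean_uptake /
#'  (1 + (r - 1) * ((n + beta_nest) / k)^b)`. With this parenthesization `k`
#' is the competition-free equilibrium: at `n = k`, `beta = 0`, unit uptake
#' and weather, the population stays put. Capacity 0 forces extinction, and
#' populations below `extinction_threshold` are set to 0 after growth.
#'
#' @param n Current population size (nonnegative).
#' @param r Growth rate.
#' @param k Nesting capacity of the cell.
#' @param beta_nest Nesting-site competition load (from nesting populations
#'   in the cell only).
#' @param mean_uptake Mean resource uptake over the foraging range.
#' @param weather Yearly weather factor.
#' @param b Density-compensation exponent (default 1).
#' @param extinction_threshold Populations below this size die out
#'   (default 1 individual).
#' @return Next-year population size (vectorized over inputs).
#' @export
grow <- function(n, r, k, beta_nest = 0, mean_uptake = 1, weather = 1,
                 b = 1, extinction_threshold = 1) {
  if (any(n < 0) || any(k < 0)) stop("n and k must be nonnegative")
  out <- ifelse(k > 0,
                n * r * weather * mean_uptake /
                  (1 + (r - 1) * ((n + beta_nest) / k)^b),
                0)
  ifelse(out < extinction_threshold, 0, out)
}

# full occupancy/uptake grids for a state (no growth): foraging abundances
# F, per-cell uptake, disk-mean uptake, presence-based C_total
occupancy_grids <- function(state, ls, community, config = sim_config()) {
  cm <- community_matrices(community)
  cpp_growth_core(state$abundance, as.integer(ls$land_use),
                  as.vector(ls$abz), ls$n_rows, ls$n_cols,
                  cm$r, cm$cc, cm$forage, cm$nest, cm$trans_res,
                  cm$trans_nest, cm$b, cm$period,
                  foraging_radius_cells(community, ls),
                  1.0, config$k_max, config$extinction_threshold,
                  config$uptake_form == "inverted", FALSE)
}

#' Mean resource uptake over a population's foraging range
#'
#' Arithmetic mean of [cell_resource_uptake()] over all in-bounds cells of
#' the foraging disk around the nest cell (zero-suitability cells such as
#' water included).
#'
#' @param state A `bee_state`.
#' @param ls A `bee_landscape`.
#' @param community A `bee_community`.
#' @param nest_cell `c(row, col)` of the nesting cell.
#' @param ft Functional-type index (column of the community).
#' @param config A [sim_config()].
#' @return Mean uptake (scalar).
#' @export
mean_resource_uptake <- function(state, ls, community, nest_cell, ft,
                                 config = sim_config()) {
  occ <- occupancy_grids(state, ls, community, config)
  idx <- (nest_cell[2] - 1L) * ls$n_rows + nest_cell[1]
  occ$mean_uptake[idx, ft]
}

#' One synchronous growth step
#'
#' Applies [grow()] to every population using occupancies computed from the
#' pre-step state: foraging abundances are accumulated over each
#' population's foraging disk, per-cell uptake follows the competition
#' rules, the disk mean feeds the growth term, and nesting-site competition
#' uses the nesting populations of the cell only. Results are independent
#' of the order types are processed in.
#'
#' @param state A `bee_state`.
#' @param ls A `bee_landscape`.
#' @param community A `bee_community`.
#' @param weather Yearly weather factor (default 1).
#' @param config A [sim_config()].
#' @return The next `bee_state` (year unchanged; [run_year()] increments).
#' @export
growth_step <- function(state, ls, community, weather = 1,
                        config = sim_config()) {
  cm <- community_matrices(community)
  res <- cpp_growth_core(state$abundance, as.integer(ls$land_use),
                         as.vector(ls$abz), ls$n_rows, ls$n_cols,
                         cm$r, cm$cc, cm$forage, cm$nest, cm$trans_res,
                         cm$trans_nest, cm$b, cm$period,
                         foraging_radius_cells(community, ls),
                         weather, config$k_max, config$extinction_threshold,
                         config$uptake_form == "inverted", TRUE)
  population_state(res$N_next, state$year, community)
}
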