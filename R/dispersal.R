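#' Number of emigrants leaving a population
#'
#' Density-dependent emigration, independent of interspecific competition:
#' the expected emigrant fraction is
#' `f = min(1, emigration_mu * (n / k)^emigration_omega)`; the realized
#' count is `round-half-up(f * n)` capped at `floor(n)`. A population on a
#' cell without capacity (`k = 0`) emigrates completely.
#'
#' @param n Population size.
#' @param k Nesting capacity of the cell.
#' @param emigration_mu Emigration scale in `[0, 1]` (default 0.2).
#' @param emigration_omega Emigration shape, positive (default 2).
#' @return Integer emigrant count.
#' @export
emigrant_count <- function(n, k, emigration_mu = 0.2, emigration_omega = 2) {
  if (n <= 0) return(0L)
  f <- if (k > 0) min(1, emigration_mu * (n / k)^emigration_omega) else 1
  as.integer(min(floor(n), round_half_up(f * n)))
}

#' Sample dispersal displacements
#'
#' Displacement distance is normal with the type's kernel mean and sd,
#' truncated at strictly positive values; direction is uniform on
#' `[0, 2*pi)`. The displacement is converted to cell offsets by rounding
#' each axis to the nearest cell.
#'
#' @param n Number of draws.
#' @param disp_mean,disp_sd Kernel mean and sd in meters.
#' @param cell_size_m Cell edge length in meters (default 20).
#' @return Data frame with columns `distance`, `angle`, `d_row`, `d_col`.
#' @export
sample_displacement <- function(n, disp_mean, disp_sd, cell_size_m = 20) {
  distance <- vapply(seq_len(n), function(i) {
    repeat {
      d <- rnorm(1, disp_mean, disp_sd)
      if (d > 0) return(d)
    }
  }, numeric(1))
  angle <- runif(n, 0, 2 * pi)
  data.frame(distance = distance, angle = angle,
             d_row = round(distance * sin(angle) / cell_size_m),
             d_col = round(distance * cos(angle) / cell_size_m))
}

# suitability of the 7 settlement classes (6 land uses + ABZ pseudo-class)
settlement_suitabilities <- function(community, ft) {
  nest <- as.numeric(community[ft, paste0("nest_", lu_names())])
  c(setNames(nest, lu_names()),
    abz = nest[2] + community$trans_effect_nest[ft])
}

#' Settle one dispersing individual
#'
#' Semidirected random settlement: the land-use classes present within the
#' origin's foraging range (ABZ cells forming their own class) are ranked by
#' the type's nesting suitability (ties by class code). For attempt
#' `k = 1..dispersal_tries` a displacement is drawn; the target cell is
#' accepted iff it is in bounds, its class rank is at most
#' `ceiling(k * n_ranks / dispersal_tries)` (so acceptable suitability
#' relaxes with attempts) and the type's nesting population there is below
#' capacity. Out-of-bounds draws and draws onto classes unseen in the
#' foraging range consume an attempt. Returns `NULL` when all attempts fail
#' (the individual dies or leaves the landscape).
#'
#' @param origin `c(row, col)` of the source cell.
#' @param ft Functional-type index.
#' @param state A `bee_state` (current, mid-step abundances).
#' @param ls A `bee_landscape`.
#' @param community A `bee_community`.
#' @param config A [sim_config()].
#' @return `c(row, col)` of the settlement cell, or `NULL`.
#' @export
settle <- function(origin, ft, state, ls, community, config = sim_config()) {
  suit <- settlement_suitabilities(community, ft)
  range_cells <- foraging_cells(ls, origin, community$disp_mean[ft])
  idx <- (range_cells[, 2] - 1L) * ls$n_rows + range_cells[, 1]
  cls <- ifelse(as.vector(ls$abz)[idx], 7L, as.integer(ls$land_use)[idx] + 1L)
  present <- sort(unique(cls))
  ord <- present[order(-suit[present], present)]
  ranks <- setNames(seq_along(ord), ord)
  n_ranks <- length(ord)
  K <- capacity_grid(ls, community, config$k_max)
  for (k in seq_len(config$dispersal_tries)) {
    d <- sample_displacement(1, community$disp_mean[ft],
                             community$disp_sd[ft], ls$cell_size_m)
    trow <- origin[1] + d$d_row
    tcol <- origin[2] + d$d_col
    if (trow < 1 || trow > ls$n_rows || tcol < 1 || tcol > ls$n_cols) next
    tidx <- (tcol - 1L) * ls$n_rows + trow
    tclass <- if (as.vector(ls$abz)[tidx]) 7L else
      as.integer(ls$land_use)[tidx] + 1L
    trank <- ranks[as.character(tclass)]
    if (is.na(trank)) next
    if (trank > ceiling(k * n_ranks / config$dispersal_tries)) next
    if (state$abundance[tidx, ft] < K[tidx, ft]) return(c(trow, tcol))
  }
  NULL
}

#' One dispersal step for the whole landscape
#'
#' Removes [emigrant_count()] individuals from every population, then
#' settles all emigrants one by one in a seeded random order, each following
#' the [settle()] rules against the mid-step state (settlers already placed
#' count towards capacity). Total abundance never increases; emigrants that
#' fail every attempt are lost.
#'
#' @param state A `bee_state`.
#' @param ls A `bee_landscape`.
#' @param community A `bee_community`.
#' @param config A [sim_config()].
#' @param ctx Optional engine context from [engine_context()] (precomputed
#'   capacity and class-presence grids).
#' @return The next `bee_state`.
#' @export
dispersal_step <- function(state, ls, community, config = sim_config(),
                           ctx = NULL) {
  if (is.null(ctx)) ctx <- engine_context(ls, community, config)
  cm <- community_matrices(community)
  N <- cpp_dispersal_step(state$abundance, ctx$K, as.integer(ls$land_use),
                          as.vector(ls$abz), ls$n_rows, ls$n_cols,
                          ls$cell_size_m, cm$disp_mean, cm$disp_sd,
                          cm$mu, cm$omega, config$dispersal_tries,
                          ctx$presence, ctx$radius_col - 1L,
                          cm$nest, cm$trans_nest)
  population_state(N, state$year, community)
}
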