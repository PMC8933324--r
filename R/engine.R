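#' Precomputed engine context
#'
#' Static per-scenario grids reused across years: capacity per cell and
#' type, class-presence bitmasks per foraging radius, and the radius column
#' each type uses. Landscape and ABZ layout do not change within a run, so
#' this is computed once.
#'
#' @param ls A `bee_landscape`.
#' @param community A `bee_community`.
#' @param config A [sim_config()].
#' @return An `engine_context` list.
#' @export
engine_context <- function(ls, community, config = sim_config()) {
  radii <- foraging_radius_cells(community, ls)
  uradii <- sort(unique(radii))
  structure(list(
    K = capacity_grid(ls, community, config$k_max),
    presence = cpp_presence_masks(as.integer(ls$land_use),
                                  as.vector(ls$abz), ls$n_rows, ls$n_cols,
                                  uradii),
    radius_col = match(radii, uradii)), class = "engine_context")
}

#' Initialize populations in a landscape
#'
#' Places `initial_individuals_per_ft` individuals per functional type, each
#' on a uniformly drawn non-water cell (one draw per individual).
#'
#' @param ls A `bee_landscape`.
#' @param community A `bee_community`.
#' @param config A [sim_config()].
#' @return A year-0 `bee_state`; exact per-type totals equal the configured
#'   count. Uses the current RNG state.
#' @export
initialize_population <- function(ls, community, config = sim_config()) {
  open <- which(as.integer(ls$land_use) != land_use_classes()[["water"]])
  if (length(open) == 0) stop("landscape is all water: nowhere to initialize")
  S <- nrow(community)
  ni <- config$initial_individuals_per_ft
  N <- matrix(0, n_cells(ls), S)
  for (s in seq_len(S)) {
    cells <- open[sample.int(length(open), ni, replace = TRUE)]
    tab <- tabulate(cells, nbins = n_cells(ls))
    N[, s] <- tab
  }
  population_state(N, 0L, community)
}

#' Simulate one year
#'
#' Ordered sub-steps: (1) draw the yearly weather factor, (2) synchronous
#' growth, (3) individual dispersal, (4) draw and apply disturbance; the
#' year counter then increments by one.
#'
#' @param state A `bee_state`.
#' @param ls A `bee_landscape`.
#' @param community A `bee_community`.
#' @param config A [sim_config()].
#' @param ctx Optional [engine_context()].
#' @return The next `bee_state`.
#' @export
run_year <- function(state, ls, community, config = sim_config(),
                     ctx = NULL) {
  if (is.null(ctx)) ctx <- engine_context(ls, community, config)
  weather <- draw_weather(config$weather_std)
  state <- growth_step(state, ls, community, weather, config)
  state <- dispersal_step(state, ls, community, config, ctx)
  mask <- draw_disturbance_mask(ls, config)
  state <- apply_disturbance(state, mask, community)
  state$year <- state$year + 1L
  state
}

# per-class cell masks under the land-use-scale patch filter: all arable
# patches; forest and grassland patches adjacent (4-neighborhood) to an
# arable cell or an ABZ cell
landuse_masks <- function(ls) {
  lu <- ls$land_use
  arable <- lu == land_use_classes()["arable"]
  shift_any <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[-1, ] <- out[-1, ] | m[-nrow(m), ]
    out[-nrow(m), ] <- out[-nrow(m), ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -ncol(m)]
    out[, -ncol(m)] <- out[, -ncol(m)] | m[, -1]
    out
  }
  adj <- shift_any(arable | ls$abz)
  masks <- list(arable = arable)
  for (cls in c("forest", "grassland")) {
    cls_cells <- lu == land_use_classes()[cls]
    pids <- unique(ls$patch_id[cls_cells & adj])
    masks[[cls]] <- cls_cells & (ls$patch_id %in% pids)
  }
  masks
}

#' Run a full simulation
#'
#' Runs `repetitions` independent replicates of `years` yearly steps;
#' replicate `r` is seeded with `base_seed + r`, so a rerun with the same
#' configuration is bit-identical. Records the per-year, per-type landscape
#' abundance totals (years 0..`years`), optionally per-land-use-class
#' totals and the final per-cell state.
#'
#' @param ls A `bee_landscape` (ABZ layer applied beforehand if wanted).
#' @param community A `bee_community`.
#' @param config A [sim_config()].
#' @return A `bee_run` object with fields `totals` (array `repetitions x
#'   (years + 1) x S`, year dimension named "0".."years"), `landuse_totals`
#'   (array `repetitions x (years + 1) x class x S` over the filtered
#'   arable/forest/grassland masks, when recorded), `final_states` (list,
#'   when recorded), `community`, `config`, and landscape metadata.
#' @export
run_simulation <- function(ls, community, config = sim_config()) {
  S <- nrow(community)
  yrs <- config$years
  totals <- array(0, dim = c(config$repetitions, yrs + 1, S),
                  dimnames = list(NULL, as.character(0:yrs), community$ft_id))
  masks <- if (config$record_landuse) landuse_masks(ls) else NULL
  lu_totals <- if (config$record_landuse)
    array(0, dim = c(config$repetitions, yrs + 1, length(masks), S),
          dimnames = list(NULL, as.character(0:yrs), names(masks),
                          community$ft_id)) else NULL
  final_states <- if (config$record_final_state)
    vector("list", config$repetitions) else NULL
  ctx <- engine_context(ls, community, config)
  for (rep in seq_len(config$repetitions)) {
    set.seed(config$base_seed + rep)
    state <- initialize_population(ls, community, config)
    record <- function(state, y) {
      totals[rep, y + 1, ] <<- colSums(state$abundance)
      if (config$record_landuse)
        for (m in seq_along(masks))
          lu_totals[rep, y + 1, m, ] <<-
            colSums(state$abundance[as.vector(masks[[m]]), , drop = FALSE])
    }
    record(state, 0)
    for (y in seq_len(yrs)) {
      state <- run_year(state, ls, community, config, ctx)
      record(state, y)
    }
    if (config$record_final_state) final_states[[rep]] <- state
  }
  structure(list(totals = totals, landuse_totals = lu_totals,
                 landuse_masks = masks, final_states = final_states,
                 community = community, config = config,
                 landscape_area_m2 = landscape_area_m2(ls),
                 cell_size_m = ls$cell_size_m),
            class = "bee_run")
}

#' @export
print.bee_run <- function(x, ...) {
  d <- dim(x$totals)
  cat("<bee_run> ", d[1], " repetitions x ", d[2] - 1, " years x ", d[3],
      " functional types\n", sep = "")
  invisible(x)
}

#' Run an ABZ scenario grid
#'
#' For each landscape and ABZ fraction: converts the fraction of potential
#' ABZ cells once (seeded by base seed, landscape index and fraction, so
#' every repetition of a scenario shares one ABZ layout), then runs a full
#' simulation.
#'
#' @param landscapes A `bee_landscape` or list of them.
#' @param community A `bee_community`.
#' @param config A [sim_config()].
#' @param fractions ABZ fractions (default the standard gradient 0, 0.05,
#'   0.1, 0.15, 0.2, 0.25, 0.5, 0.75, 1).
#' @return A `bee_scenarios` object: list with `runs` (nested list indexed
#'   `[[landscape]][[fraction]]` of `bee_run`), `fractions`, and a
#'   long-format `table` (landscape, fraction, repetition, year, ft,
#'   abundance).
#' @export
run_scenarios <- function(landscapes, community, config = sim_config(),
                          fractions = c(0, 0.05, 0.1, 0.15, 0.2, 0.25,
                                        0.5, 0.75, 1)) {
  if (inherits(landscapes, "bee_landscape")) landscapes <- list(landscapes)
  if (is.unsorted(fractions) || anyDuplicated(fractions))
    stop("fractions must be sorted and unique")
  runs <- vector("list", length(landscapes))
  rows <- list()
  for (li in seq_along(landscapes)) {
    runs[[li]] <- vector("list", length(fractions))
    names(runs[[li]]) <- as.character(fractions)
    for (fi in seq_along(fractions)) {
      f <- fractions[fi]
      abz_seed <- (config$base_seed + 7919L * li +
                     as.integer(round(f * 1000))) %% .Machine$integer.max
      ls_f <- with_local_seed(abz_seed,
                              apply_abz(landscapes[[li]], f,
                                        order = config$abz_order))
      run <- run_simulation(ls_f, community, config)
      runs[[li]][[fi]] <- run
      d <- dim(run$totals)
      rows[[length(rows) + 1]] <- data.frame(
        landscape = li, fraction = f,
        repetition = rep(seq_len(d[1]), times = d[2] * d[3]),
        year = rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]),
        ft = rep(community$ft_id, each = d[1] * d[2]),
        abundance = as.vector(run$totals))
    }
  }
  structure(list(runs = runs, fractions = fractions,
                 table = do.call(rbind, rows), community = community,
                 config = config),
            class = "bee_scenarios")
}
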