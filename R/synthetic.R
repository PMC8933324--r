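#' Configuration for the synthetic landscape generator
#'
#' The generator emulates agricultural mosaics as contiguous patches grown by
#' seeded region growing: patch seeds are placed on random unassigned cells,
#' patch target areas are drawn from a geometric distribution, and patches
#' grow by annexing random unassigned 4-neighbors until the target area or
#' the class quota is reached. Class quotas are enforced exactly (largest
#' remainder rounding), so realized class fractions match the targets to
#' within rounding.
#'
#' @param target_composition Named numeric vector of class fractions over
#'   `names(land_use_classes())`; must be nonnegative and sum to 1 (within
#'   1e-9).
#' @param mean_patch_area_cells Mean of the geometric patch-size
#'   distribution, in cells (default 80, i.e. 3.2 ha at 20 m cells).
#' @param n_rows,n_cols Grid dimensions (default 150 x 150).
#' @param cell_size_m Cell edge length in meters (default 20).
#' @param seed Integer seed making the landscape bit-reproducible.
#' @return A `synthetic_landscape_config` list.
#' @export
synthetic_landscape_config <- function(target_composition = NULL,
                                       mean_patch_area_cells = 80,
                                       n_rows = 150, n_cols = 150,
                                       cell_size_m = 20, seed = 1) {
  if (is.null(target_composition))
    target_composition <- c(bare = 0.06, arable = 0.60, forest = 0.15,
                            grassland = 0.11, urban = 0.03, water = 0.05)
  miss <- setdiff(lu_names(), names(target_composition))
  target_composition[miss] <- 0
  target_composition <- target_composition[lu_names()]
  if (any(target_composition < 0))
    stop("composition fractions must be nonnegative")
  if (abs(sum(target_composition) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  structure(list(target_composition = target_composition,
                 mean_patch_area_cells = mean_patch_area_cells,
                 n_rows = n_rows, n_cols = n_cols,
                 cell_size_m = cell_size_m, seed = seed),
            class = "synthetic_landscape_config")
}

#' Archetype landscape configurations
#'
#' Three documented compositions: `"study_region"` mirrors a north-east
#' German agricultural region (60% arable, 15% forest, 11% grassland,
#' 5% water, 3% urban, 6% bare ground); `"heterogeneous"` a mixed mosaic
#' with low arable and high natural cover (35/30/20 arable/forest/grassland);
#' `"arable_dominated"` a homogeneous landscape of few large arable fields
#' (75% arable, 15% forest+grassland).
#'
#' @param archetype One of `"study_region"`, `"heterogeneous"`,
#'   `"arable_dominated"`.
#' @param ... Overrides passed to [synthetic_landscape_config()].
#' @return A `synthetic_landscape_config`.
#' @export
archetype_config <- function(archetype = c("study_region", "heterogeneous",
                                           "arable_dominated"), ...) {
  archetype <- match.arg(archetype)
  comp <- switch(archetype,
    study_region = c(bare = 0.06, arable = 0.60, forest = 0.15,
                     grassland = 0.11, urban = 0.03, water = 0.05),
    heterogeneous = c(bare = 0.05, arable = 0.35, forest = 0.30,
                      grassland = 0.20, urban = 0.05, water = 0.05),
    arable_dominated = c(bare = 0.04, arable = 0.75, forest = 0.08,
                         grassland = 0.07, urban = 0.03, water = 0.03))
  mean_area <- if (archetype == "arable_dominated") 300 else 80
  args <- list(target_composition = comp,
               mean_patch_area_cells = mean_area, ...)
  do.call(synthetic_landscape_config, args)
}

#' Generate a synthetic landscape
#'
#' Seeded region growing (see [synthetic_landscape_config()]): repeatedly
#' picks a class with remaining quota (probability proportional to the
#' remaining quota), a geometric target patch area, and a random unassigned
#' seed cell, then grows the patch over random unassigned 4-neighbors.
#' Unassignable leftovers become single-cell patches of classes with
#' remaining quota. The patch table is derived by 4-connected component
#' labelling, so patches of one class that touch merge into one patch.
#'
#' @param config A `synthetic_landscape_config`.
#' @return A validated `bee_landscape`; identical configs (including seed)
#'   yield identical landscapes.
#' @export
generate_synthetic_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_landscape_config"))
  nr <- config$n_rows; nc <- config$n_cols
  ncell <- nr * nc
  # exact integer quotas via largest-remainder rounding
  raw <- config$target_composition * ncell
  quota <- floor(raw)
  left <- ncell - sum(quota)
  if (left > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(left)]
    quota[extra] <- quota[extra] + 1
  }
  if (sum(quota > 0) == 0) stop("composition infeasible for grid size")
  with_local_seed(config$seed, {
    lu <- rep(NA_integer_, ncell)
    unassigned <- rep(TRUE, ncell)
    remaining <- quota
    p_geom <- 1 / config$mean_patch_area_cells
    neighbors <- function(i) {
      row <- (i - 1L) %% nr + 1L
      col <- (i - 1L) %/% nr + 1L
      nb <- integer(0)
      if (row > 1L) nb <- c(nb, i - 1L)
      if (row < nr) nb <- c(nb, i + 1L)
      if (col > 1L) nb <- c(nb, i - nr)
      if (col < nc) nb <- c(nb, i + nr)
      nb
    }
    free <- which(unassigned)
    while (length(free) > 0) {
      open <- which(remaining > 0)
      cls <- if (length(open) == 1) open else
        sample(open, 1, prob = remaining[open])
      size <- min(stats::rgeom(1, p_geom) + 1, remaining[cls], length(free))
      seed_cell <- if (length(free) == 1) free else sample(free, 1)
      patch <- seed_cell
      lu[seed_cell] <- cls - 1L
      unassigned[seed_cell] <- FALSE
      frontier <- neighbors(seed_cell)
      frontier <- frontier[unassigned[frontier]]
      while (length(patch) < size && length(frontier) > 0) {
        pick <- if (length(frontier) == 1) frontier else sample(frontier, 1)
        if (!unassigned[pick]) {
          frontier <- setdiff(frontier, pick)
          next
        }
        lu[pick] <- cls - 1L
        unassigned[pick] <- FALSE
        patch <- c(patch, pick)
        frontier <- unique(c(setdiff(frontier, pick),
                             Filter(function(j) unassigned[j],
                                    neighbors(pick))))
      }
      remaining[cls] <- remaining[cls] - length(patch)
      free <- which(unassigned)
    }
    lu_mat <- matrix(lu, nr, nc)
    landscape(lu_mat, cell_size_m = config$cell_size_m)
  })
}
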