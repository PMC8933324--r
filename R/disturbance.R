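#' Draw the yearly disturbance mask
#'
#' Agriculturally managed classes are disturbed at patch scale: one
#' Bernoulli draw per arable or grassland patch (probability 1.0 and 0.8 by
#' default) sets all the patch's cells together. Forest, bare and urban
#' cells draw independently per cell (0.3, 0.7, 0.7). ABZ cells and water
#' are never disturbed. Patch draws run in ascending patch id, then one
#' uniform vector serves the cell-scale classes, so a fixed RNG state gives
#' a fixed mask.
#'
#' @param ls A `bee_landscape`.
#' @param config A [sim_config()] (field `disturbance_prob`).
#' @return Logical matrix (`n_rows x n_cols`) of disturbed cells.
#' @export
draw_disturbance_mask <- function(ls, config = sim_config()) {
  prob <- config$disturbance_prob
  lu <- ls$land_use
  mask <- matrix(FALSE, ls$n_rows, ls$n_cols)
  patch_classes <- c("arable", "grassland")
  pt <- ls$patch_table
  pt <- pt[pt$land_use %in% patch_classes, , drop = FALSE]
  pt <- pt[order(pt$patch_id), , drop = FALSE]
  for (k in seq_len(nrow(pt))) {
    if (runif(1) < prob[[pt$land_use[k]]])
      mask[ls$patch_id == pt$patch_id[k]] <- TRUE
  }
  cell_classes <- c("bare", "forest", "urban")
  u <- matrix(runif(length(lu)), nrow(lu), ncol(lu))
  for (cls in cell_classes) {
    sel <- lu == land_use_classes()[cls]
    mask[sel] <- u[sel] < prob[[cls]]
  }
  mask[ls$abz] <- FALSE
  mask[lu == land_use_classes()["water"]] <- FALSE
  mask
}

#' Apply a disturbance mask to the population state
#'
#' Every population in a masked cell is reduced multiplicatively to
#' `n * (1 - dist_eff)` of its type-specific survival; unmasked cells are
#' untouched. Soil-nesting (endogeic) types lose 90% per event, cavity
#' nesters (hypogean) 30%.
#'
#' @param state A `bee_state`.
#' @param mask Logical matrix from [draw_disturbance_mask()].
#' @param community A `bee_community` (column `dist_eff`).
#' @return The disturbed `bee_state`.
#' @export
apply_disturbance <- function(state, mask, community) {
  if (length(mask) != nrow(state$abundance))
    stop("mask shape does not match the population grid")
  m <- as.vector(mask)
  N <- state$abundance
  surv <- pmax(0, 1 - community$dist_eff)
  N[m, ] <- sweep(N[m, , drop = FALSE], 2, surv, `*`)
  population_state(N, state$year, community)
}
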