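# Literal scalar oracle for the growth equations: plain R loops over cells
# and types, applying the competition load, the competition-dependent
# resource uptake, its average over the foraging range, and the Maynard
# Smith-Slatkin update exactly as written, with no shared code with the
# package's vectorized path.

oracle_overlap <- function(p1, p2) p1 == "both" || p2 == "both" || p1 == p2

oracle_growth_step <- function(state, ls, community, weather = 1,
                               k_max = 50, ext_thresh = 1,
                               form = "printed") {
  nr <- ls$n_rows; nc <- ls$n_cols
  S <- nrow(community)
  N <- state$abundance
  lu_codes <- as.integer(ls$land_use)
  abz <- as.vector(ls$abz)
  forage_suit <- as.matrix(community[paste0("forage_", names(land_use_classes()))])
  nest_suit <- as.matrix(community[paste0("nest_", names(land_use_classes()))])
  radius <- community$disp_mean / ls$cell_size_m
  idx <- function(row, col) (col - 1) * nr + row
  range_of <- function(row, col, rad) {
    cells <- list()
    R <- floor(rad)
    for (dr in -R:R) for (dc in -R:R) {
      if (dr^2 + dc^2 > rad^2) next
      rr <- row + dr; cc2 <- col + dc
      if (rr >= 1 && rr <= nr && cc2 >= 1 && cc2 <= nc)
        cells[[length(cells) + 1]] <- c(rr, cc2)
    }
    do.call(rbind, cells)
  }
  # foraging abundance of type i in cell q: sum of populations of i whose
  # range covers q (symmetry: cells within radius of q)
  Fmat <- matrix(0, nr * nc, S)
  for (s in seq_len(S)) {
    for (col in seq_len(nc)) for (row in seq_len(nr)) {
      cells <- range_of(row, col, radius[s])
      Fmat[idx(row, col), s] <- sum(N[idx(cells[, 1], cells[, 2]), s])
    }
  }
  uptake <- matrix(0, nr * nc, S)
  for (q in seq_len(nr * nc)) {
    C_total <- sum(community$c[Fmat[q, ] > 0])
    for (j in seq_len(S)) {
      beta <- 0; n_total <- Fmat[q, j]
      for (i in seq_len(S)) {
        if (i == j) next
        if (!oracle_overlap(community$flying_period[j],
                            community$flying_period[i])) next
        n_total <- n_total + Fmat[q, i]
        w <- if (C_total > 0)
          1 + (community$c[j] - community$c[i]) / C_total else 1
        beta <- beta + w * Fmat[q, i]
      }
      beta <- max(0, beta)
      suit <- forage_suit[j, lu_codes[q] + 1] +
        if (abz[q]) community$trans_effect_res[j] else 0
      ratio <- if (form == "printed") {
        if (n_total > 0) (beta + Fmat[q, j]) / n_total else 1
      } else {
        if (beta + Fmat[q, j] > 0) n_total / (beta + Fmat[q, j]) else 1
      }
      uptake[q, j] <- ratio * suit
    }
  }
  N_next <- matrix(0, nr * nc, S)
  for (j in seq_len(S)) {
    for (col in seq_len(nc)) for (row in seq_len(nr)) {
      q <- idx(row, col)
      n <- N[q, j]
      if (n <= 0) next
      K <- k_max * (nest_suit[j, lu_codes[q] + 1] +
                      if (abz[q]) community$trans_effect_nest[j] else 0)
      if (K <= 0) next
      cells <- range_of(row, col, radius[j])
      mean_up <- mean(uptake[idx(cells[, 1], cells[, 2]), j])
      C_total <- sum(community$c[Fmat[q, ] > 0])
      beta_nest <- 0
      for (i in seq_len(S)) {
        if (i == j) next
        if (!oracle_overlap(community$flying_period[j],
                            community$flying_period[i])) next
        w <- if (C_total > 0)
          1 + (community$c[j] - community$c[i]) / C_total else 1
        beta_nest <- beta_nest + w * N[q, i]
      }
      beta_nest <- max(0, beta_nest)
      R_j <- community$r[j]
      nn <- n * R_j * weather * mean_up /
        (1 + (R_j - 1) * ((n + beta_nest) / K)^community$b[j])
      N_next[q, j] <- if (nn < ext_thresh) 0 else nn
    }
  }
  population_state(N_next, state$year)
}
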