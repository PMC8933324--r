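# Small programmatic fixtures shared across the suite.

lu <- land_use_classes()

# a tiny landscape from a matrix of class names
toy_landscape <- function(names_mat, cell_size_m = 20) {
  codes <- matrix(lu[names_mat], nrow(names_mat), ncol(names_mat))
  landscape(codes, cell_size_m = cell_size_m)
}

# n x n single-class landscape
uniform_landscape <- function(n, class = "grassland", cell_size_m = 20) {
  toy_landscape(matrix(class, n, n), cell_size_m = cell_size_m)
}

# community of a few hand-picked profiles
small_community <- function(profiles) {
  df <- do.call(rbind, lapply(profiles, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  df$species <- sprintf("sp%02d", seq_len(nrow(df)))
  classify_trait_table(df)
}

profile <- function(foraging_distance = "short", diet = "oligolectic",
                    flying_period = "first", nesting = "endogeic",
                    parasite_host = "no") {
  list(foraging_distance = foraging_distance, diet = diet,
       flying_period = flying_period, nesting = nesting,
       parasite_host = parasite_host)
}

withr_like_tempdir <- function() {
  d <- tempfile("beescape")
  dir.create(d)
  d
}

write_ascii_grid_for_test <- function(m, path) {
  beescape:::write_ascii_grid(m, path)
}

# a random state on a landscape: populations in [lo, hi] on a fraction of
# cells (uses current RNG state)
random_state <- function(ls, S, fill = 0.5, lo = 0.5, hi = 100) {
  n <- n_cells(ls)
  N <- matrix(0, n, S)
  for (s in seq_len(S)) {
    k <- max(1, round(fill * n))
    cells <- sample.int(n, k)
    N[cells, s] <- runif(k, lo, hi)
  }
  population_state(N)
}
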