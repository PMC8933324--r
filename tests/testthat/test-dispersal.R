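test_that("emigrant counts follow the density-dependent fraction", {
  expect_equal(emigrant_count(0, 100), 0L)
  expect_equal(emigrant_count(100, 100, 0.2, 2), 20L)
  # vanishing density: no emigrants
  expect_equal(emigrant_count(100, 1e12, 0.2, 2), 0L)
  # K = 0: complete emigration (capped at whole individuals)
  expect_equal(emigrant_count(7.6, 0), 7L)
  # fraction capped at 1
  expect_equal(emigrant_count(300, 100, 0.9, 2), 300L)
  # count never exceeds the whole individuals present
  expect_equal(emigrant_count(2.9, 1, 1, 1), 2L)
})

test_that("displacement kernel is truncated normal with uniform direction", {
  set.seed(3)
  d <- sample_displacement(10000, 600, 60)
  expect_true(all(d$distance > 0))
  expect_lt(abs(mean(d$distance) - 600), 2)
  expect_lt(abs(sd(d$distance) - 60), 2)
  # direction symmetry: mean offsets near zero
  expect_lt(abs(mean(d$d_row)), 1)
  expect_lt(abs(mean(d$d_col)), 1)
  set.seed(9)
  a <- sample_displacement(20, 100, 10)
  set.seed(9)
  expect_identical(sample_displacement(20, 100, 10), a)
})

test_that("settlement fails when every reachable cell is at capacity", {
  ls <- uniform_landscape(9)
  com <- small_community(list(profile()))  # endogeic, grassland suit 0.7
  cfg <- sim_config(years = 1, repetitions = 1, dispersal_tries = 10)
  K <- 50 * 0.7
  full <- population_state(matrix(K, n_cells(ls), 1))
  set.seed(4)
  expect_null(settle(c(5, 5), 1, full, ls, com, cfg))
  # with free space, settlement succeeds eventually over many tries
  empty <- population_state(matrix(0, n_cells(ls), 1))
  set.seed(4)
  hits <- sum(vapply(1:50, function(i)
    !is.null(settle(c(5, 5), 1, empty, ls, com, cfg)), logical(1)))
  expect_gt(hits, 0)
})

test_that("early search attempts admit only the best-ranked classes", {
  # grassland (endogeic suit 0.7) ranks above arable (0.3); with
  # tries = n_ranks = 2 the acceptance threshold ceil(k * n_ranks / tries)
  # admits rank 1 only at the first attempt, both at the second
  nm <- matrix("arable", 21, 21)
  nm[, 11:21] <- "grassland"
  ls <- toy_landscape(nm)
  com <- small_community(list(profile()))  # short: kernel 100/10 m
  empty <- population_state(matrix(0, n_cells(ls), 1))
  origin <- c(11, 10)  # one cell inside arable, both classes in reach
  classes_hit <- function(tries, n = 400) {
    cfg <- sim_config(dispersal_tries = tries)
    out <- integer(0)
    for (i in seq_len(n)) {
      dest <- settle(origin, 1, empty, ls, com, cfg)
      if (!is.null(dest))
        out <- c(out, ls$land_use[dest[1], dest[2]])
    }
    out
  }
  set.seed(21)
  hits2 <- classes_hit(2)
  # both classes are reachable, but grassland dominates because arable is
  # only admitted at the final attempt
  tab <- table(factor(hits2, levels = land_use_classes()))
  gr <- tab[[as.character(land_use_classes()[["grassland"]])]]
  ar <- tab[[as.character(land_use_classes()[["arable"]])]]
  expect_gt(gr, ar)
  expect_gt(ar, 0)
  # with a single-class range every settlement lands in that class
  nm_g <- matrix("grassland", 15, 15)
  ls_g <- toy_landscape(nm_g)
  empty_g <- population_state(matrix(0, n_cells(ls_g), 1))
  set.seed(22)
  for (i in 1:50) {
    dest <- settle(c(8, 8), 1, empty_g, ls_g, com, sim_config())
    if (!is.null(dest))
      expect_equal(unname(ls_g$land_use[dest[1], dest[2]]),
                   unname(land_use_classes()[["grassland"]]))
  }
})

test_that("dispersal conserves or loses individuals, never creates them", {
  cfg_ls <- synthetic_landscape_config(n_rows = 20, n_cols = 20, seed = 6,
                                       mean_patch_area_cells = 25)
  ls <- generate_synthetic_landscape(cfg_ls)
  com <- default_community(6, seed = 3)
  cfg <- sim_config()
  set.seed(8)
  st <- random_state(ls, 6, fill = 0.4, lo = 1, hi = 60)
  before <- sum(st$abundance)
  out <- dispersal_step(st, ls, com, cfg)
  expect_lte(sum(out$abundance), before + 1e-9)
  expect_true(all(out$abundance >= 0))
  # per-type totals can only shrink
  expect_true(all(colSums(out$abundance) <= colSums(st$abundance) + 1e-9))
})

test_that("no individual ever settles on water", {
  nm <- matrix("water", 15, 15)
  nm[8, 8] <- "grassland"
  ls <- toy_landscape(nm)
  com <- small_community(list(profile()))
  cfg <- sim_config()
  N <- matrix(0, n_cells(ls), 1)
  N[(8 - 1) * 15 + 8] <- 200  # far above K = 35: strong emigration
  st <- population_state(N)
  set.seed(12)
  out <- dispersal_step(st, ls, com, cfg)
  water <- as.vector(ls$land_use) == land_use_classes()[["water"]]
  expect_true(all(out$abundance[water, ] == 0))
})

test_that("dispersal with zero emigration leaves the state unchanged", {
  ls <- uniform_landscape(10)
  com <- small_community(list(profile()))
  com$emigration_mu <- 0
  cfg <- sim_config()
  set.seed(2)
  st <- random_state(ls, 1, fill = 0.5, lo = 1, hi = 30)
  out <- dispersal_step(st, ls, com, cfg)
  expect_equal(unname(out$abundance), st$abundance)
})

test_that("dispersal is bit-reproducible under a fixed seed", {
  cfg_ls <- synthetic_landscape_config(n_rows = 15, n_cols = 15, seed = 2,
                                       mean_patch_area_cells = 15)
  ls <- generate_synthetic_landscape(cfg_ls)
  com <- default_community(4, seed = 5)
  cfg <- sim_config()
  set.seed(31)
  st <- random_state(ls, 4, fill = 0.5, lo = 10, hi = 80)
  set.seed(77)
  a <- dispersal_step(st, ls, com, cfg)
  set.seed(77)
  b <- dispersal_step(st, ls, com, cfg)
  expect_identical(a$abundance, b$abundance)
})

test_that("an empty high-suitability patch gains settlers from a crowded source", {
  # crowded grassland beside empty grassland within the kernel reach
  nm <- matrix("grassland", 11, 21)
  ls <- toy_landscape(nm)
  com <- small_community(list(profile()))  # short, kernel 100 m = 5 cells
  cfg <- sim_config()
  src <- (6 - 1) * 11 + 6  # row 6, col 6
  right_half <- as.vector(col(matrix(0, 11, 21)) > 11)
  gains <- vapply(1:100, function(seed) {
    N <- matrix(0, n_cells(ls), 1)
    N[src] <- 200  # far above K: many emigrants
    st <- population_state(N)
    set.seed(seed)
    out <- dispersal_step(st, ls, com, cfg)
    sum(out$abundance[-src, ])
  }, numeric(1))
  # settlement succeeds in the overwhelming majority of seeds
  expect_gt(mean(gains > 0), 0.95)
})
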