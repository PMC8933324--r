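test_that("weather draws are truncated normal around 1", {
  expect_identical(draw_weather(0, 5), rep(1, 5))
  set.seed(7)
  w <- draw_weather(0.15, 10000)
  expect_true(all(w >= 0))
  expect_lt(abs(mean(w) - 1), 0.01)
  expect_lt(abs(sd(w) - 0.15), 0.01)
  set.seed(11)
  a <- draw_weather(0.15, 50)
  set.seed(11)
  expect_identical(draw_weather(0.15, 50), a)
  expect_error(draw_weather(-0.1), ">= 0")
})

test_that("foraging disk has 81 cells at radius 5 and clips at boundaries", {
  ls <- uniform_landscape(30)
  disk <- foraging_cells(ls, c(15, 15), 100)  # 100 m / 20 m = 5 cells
  expect_equal(nrow(disk), 81)
  d2 <- (disk[, 1] - 15)^2 + (disk[, 2] - 15)^2
  expect_true(all(d2 <= 25))
  # corner clipping: only in-bounds cells
  corner <- foraging_cells(ls, c(1, 1), 100)
  expect_lt(nrow(corner), 81)
  expect_true(all(corner >= 1))
  # radius 0: focal cell only
  expect_equal(foraging_cells(ls, c(3, 4), 0), cbind(3L, 4L))
})

test_that("competition load reproduces the hand-evaluated cases", {
  expect_equal(competition_load(3, numeric(0), numeric(0)), 0)
  # weak focal (c=0) against one strong competitor (c=5): load vanishes
  expect_equal(competition_load(0, 5, 100, c_total = 5), 0)
  # strong focal (c=5) against a weak competitor (c=0): load doubles
  expect_equal(competition_load(5, 0, 100, c_total = 5), 200)
  # c_total = 0 drops the scaled term
  expect_equal(competition_load(0, 0, 100, c_total = 0), 100)
  # never negative
  expect_gte(competition_load(0, 5, c(100, 3), c_total = 5), 0)
})

test_that("cell resource uptake follows the printed form with its degenerate cases", {
  expect_equal(cell_resource_uptake(0, 50, 50, 1), 1)
  expect_equal(cell_resource_uptake(200, 100, 200, 1.5), 2.25)
  expect_equal(cell_resource_uptake(0, 0, 0, 0.7), 0.7)  # empty cell ratio 1
  # ABZ adds the resource transformation effect to the class suitability
  expect_equal(cell_resource_uptake(0, 10, 10, 1.05 + 1.0), 2.05)
  # inverted form reverses the orientation
  expect_equal(cell_resource_uptake(200, 100, 200, 1.5, form = "inverted"),
               1.5 * 200 / 300)
})

test_that("nest capacity scales suitability and the ABZ bonus", {
  expect_equal(nest_capacity(1.0, FALSE, 1, 50), 50)    # endogeic on bare
  expect_equal(nest_capacity(0.3, TRUE, 1, 50), 65)     # endogeic on ABZ
  expect_equal(nest_capacity(0, FALSE, 1, 50), 0)       # water
})

test_that("growth has the equilibrium, low-density and hand-computed values", {
  # N = K with neutral conditions is a fixed point
  expect_equal(grow(100, 5, 100), 100)
  # low-density limit: per-capita growth tends to R * weather * uptake
  expect_equal(grow(1e-9, 3, 100, extinction_threshold = 0) / 1e-9, 3,
               tolerance = 1e-6)
  # N=100, K=100, R=5, beta=100: 500 / (1 + 4 * 2) = 55.56
  expect_equal(grow(100, 5, 100, beta_nest = 100), 500 / 9,
               tolerance = 1e-12)
  # zero capacity forces extinction; small populations are removed
  expect_equal(grow(10, 5, 0), 0)
  expect_equal(grow(0.1, 1.5, 100), 0)
  expect_error(grow(-1, 5, 100), "nonnegative")
})

test_that("growth is monotone in its drivers", {
  b <- seq(0, 200, by = 25)
  g <- grow(50, 4, 100, beta_nest = b, extinction_threshold = 0)
  expect_true(all(diff(g) < 0))
  u <- seq(0.2, 2, by = 0.2)
  g <- grow(50, 4, 100, mean_uptake = u, extinction_threshold = 0)
  expect_true(all(diff(g) > 0))
  w <- seq(0.5, 1.5, by = 0.1)
  g <- grow(50, 4, 100, weather = w, extinction_threshold = 0)
  expect_true(all(diff(g) > 0))
})

test_that("growth step leaves an empty landscape empty and holds equilibria", {
  ls <- uniform_landscape(8)
  com <- small_community(list(profile()))
  state <- population_state(matrix(0, n_cells(ls), 1))
  out <- growth_step(state, ls, com)
  expect_equal(sum(out$abundance), 0)
  # single population at K on homogeneous grassland, alone in its range:
  # uptake 1 (oligolectic single-period grassland), so N stays at K
  K <- 50 * 0.7  # endogeic on grassland
  N <- matrix(0, n_cells(ls), 1)
  N[30] <- K
  st <- population_state(N)
  out <- growth_step(st, ls, com)
  expect_equal(out$abundance[30], K, tolerance = 1e-12)
})

test_that("vectorized growth step matches the literal scalar oracle", {
  # random 5x5 landscapes with 4 types drawn from contrasting profiles
  profs <- list(
    profile("short", "oligolectic", "first", "endogeic", "no"),
    profile("long", "polylectic", "both", "hypogean", "yes"),
    profile("medium", "polylectic", "second", "endogeic", "no"),
    profile("short", "polylectic", "both", "hypogean", "no"))
  com <- small_community(profs)
  classes <- names(land_use_classes())
  for (case in 1:40) {
    set.seed(1000 + case)
    nm <- matrix(sample(classes, 25, replace = TRUE), 5, 5)
    ls <- toy_landscape(nm)
    if (case %% 2 == 0) {
      cand <- potential_abz_cells(ls)
      if (nrow(cand) > 0) ls <- apply_abz(ls, 0.5)
    }
    st <- random_state(ls, 4, fill = 0.6)
    w <- runif(1, 0.7, 1.3)
    fast <- growth_step(st, ls, com, weather = w)
    slow <- oracle_growth_step(st, ls, com, weather = w)
    expect_equal(unname(fast$abundance), slow$abundance, tolerance = 1e-10)
  }
})

test_that("processing order of functional types does not change the growth step", {
  com <- small_community(list(
    profile("short", "oligolectic", "first", "endogeic", "no"),
    profile("long", "polylectic", "both", "hypogean", "yes"),
    profile("medium", "oligolectic", "second", "endogeic", "yes")))
  set.seed(5)
  nm <- matrix(sample(names(land_use_classes()), 36, replace = TRUE), 6, 6)
  ls <- toy_landscape(nm)
  st <- random_state(ls, 3, fill = 0.7)
  out <- growth_step(st, ls, com)
  perm <- c(3, 1, 2)
  com_p <- com[perm, ]
  st_p <- population_state(st$abundance[, perm])
  out_p <- growth_step(st_p, ls, com_p)
  expect_equal(out_p$abundance, out$abundance[, perm], tolerance = 1e-12)
})

test_that("single type without noise converges to carrying capacity", {
  ls <- uniform_landscape(6)
  com <- small_community(list(profile()))  # short oligolectic endogeic
  K <- 50 * 0.7
  N <- matrix(10, n_cells(ls), 1)
  st <- population_state(N)
  for (y in 1:200) st <- growth_step(st, ls, com)
  expect_true(all(abs(st$abundance - K) < 1e-6))
})

test_that("mean uptake averages the disk, water cells included", {
  # range half grassland (suitability 1), half water (0) -> mean 0.5
  nm <- rbind(rep("grassland", 10), rep("water", 10))
  ls <- toy_landscape(nm)
  com <- small_community(list(profile()))  # oligolectic one period
  N <- matrix(0, n_cells(ls), 1)
  idx <- (5 - 1) * 2 + 1  # row 1, col 5
  N[idx] <- 5
  st <- population_state(N)
  # radius 100 m = 5 cells, but the grid is 2 rows tall: the disk covers
  # columns around col 5 in both rows; compute expected mean directly
  cells <- foraging_cells(ls, c(1, 5), 100)
  suit <- ifelse(ls$land_use[cells] == land_use_classes()["grassland"], 1, 0)
  expect_equal(mean_resource_uptake(st, ls, com, c(1, 5), 1), mean(suit))
})
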