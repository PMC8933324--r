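test_that("richness counts strictly positive totals", {
  expect_equal(ft_richness(rep(10, 28)), 28)
  expect_equal(ft_richness(rep(0, 28)), 0)
  expect_equal(ft_richness(c(0, 0, 3, 0)), 1)
  expect_error(ft_richness(c(-1, 2)), "nonnegative")
})

test_that("Shannon diversity matches closed forms and bounds", {
  expect_equal(shannon(c(100, 0, 0)), 0)
  expect_equal(shannon(rep(7, 28)), log(28), tolerance = 1e-12)
  expect_equal(shannon(c(75, 25)),
               -0.75 * log(0.75) - 0.25 * log(0.25), tolerance = 1e-12)
  expect_error(shannon(c(0, 0)), "undefined")
  # bound: H <= log(richness), equality iff equal shares
  set.seed(1)
  for (i in 1:20) {
    x <- c(runif(8, 0, 50), rep(0, 3))
    expect_lte(shannon(x), log(ft_richness(x)) + 1e-12)
  }
})

test_that("quasi-extinction risk is the fraction of dipping repetitions", {
  yrs <- as.character(0:50)
  traj <- matrix(20000, 10, 51, dimnames = list(NULL, yrs))
  traj[4, 46] <- 9000  # one repetition dips inside the window
  expect_equal(quasi_extinction_risk(traj, 10000, c(40, 50)), 0.1)
  expect_equal(quasi_extinction_risk(traj, 10000, c(0, 39)), 0)
  expect_equal(quasi_extinction_risk(traj, 8000, c(40, 50)), 0)
  traj[] <- 100
  expect_equal(quasi_extinction_risk(traj, 10000, c(40, 50)), 1)
  expect_error(quasi_extinction_risk(traj, 10000, c(40, 60)), "window")
  # risks live on the grid {0, 1/R, ..., 1}
  set.seed(2)
  r <- quasi_extinction_risk(matrix(runif(10 * 51, 0, 2e4), 10,
                                    dimnames = list(NULL, yrs)), 1e4)
  expect_true(any(abs(r - (0:10) / 10) < 1e-12))
})

test_that("landscape threshold scales with area from the reference density", {
  expect_equal(quasi_extinction_threshold(9e6), 10000)
  expect_equal(quasi_extinction_threshold(1e6), 10000 / 9)
  ls <- uniform_landscape(50)  # 1 km x 1 km at 20 m cells
  expect_equal(quasi_extinction_threshold(ls), 10000 / 9)
})

test_that("community-weighted means average the coded traits", {
  com <- small_community(list(
    profile(flying_period = "first"),                 # coded 1
    profile(flying_period = "both", diet = "polylectic")))  # coded 3
  cwm <- community_weighted_mean(c(50, 50), com)
  expect_equal(unname(cwm["flying_period"]), 2)
  mono <- community_weighted_mean(c(0, 80), com)
  expect_equal(unname(mono["flying_period"]), 3)
  # all-endogeic community: susceptibility is the endogeic dist_eff
  expect_equal(unname(cwm["disturbance_susceptibility"]), 0.9)
  # foraging coding: ordinal by default, meters on request
  com2 <- small_community(list(profile(foraging_distance = "short"),
                               profile(foraging_distance = "long")))
  w2 <- ifelse(com2$foraging_distance == "short", 10, 30)
  expect_equal(unname(community_weighted_mean(w2, com2)["foraging"]),
               (10 * 1 + 30 * 3) / 40)
  expect_equal(unname(community_weighted_mean(w2, com2,
                                              foraging = "meters")["foraging"]),
               (10 * 100 + 30 * 600) / 40)
  expect_error(community_weighted_mean(c(0, 0), com), "positive")
  # CWMs stay inside the coded range
  set.seed(3)
  for (i in 1:10) {
    w <- runif(2, 0, 10)
    v <- community_weighted_mean(w, com2)["foraging"]
    expect_gte(v, 1); expect_lte(v, 3)
  }
})

test_that("feeding intensity sums population size times uptake per cell", {
  ls <- uniform_landscape(9)
  com <- small_community(list(profile()))  # grassland uptake 1 when alone
  N <- matrix(0, n_cells(ls), 1)
  src <- (5 - 1) * 9 + 5
  N[src] <- 12
  st <- population_state(N)
  fi <- feeding_intensity_map(st, ls, com)
  # the single population forages over its disk: each covered cell gets
  # N * uptake = 12 * 1; others 0
  disk <- foraging_cells(ls, c(5, 5), com$disp_mean[1])
  expect_equal(sum(fi > 0), nrow(disk))
  expect_equal(unique(fi[fi > 0]), 12)
  # empty cell: no foragers in range -> 0
  expect_equal(fi[1, 1], 0)
})

test_that("ABZ cells carry the highest feeding intensity in a toy landscape", {
  # forest strip through the middle so the ABZ cells sit in the interior
  nm <- matrix("arable", 15, 15)
  nm[, 8] <- "forest"
  ls <- toy_landscape(nm)
  set.seed(6)
  ls <- apply_abz(ls, 1)
  com <- small_community(list(profile(diet = "polylectic",
                                      flying_period = "both")))
  st <- population_state(matrix(10, n_cells(ls), 1))
  fi <- feeding_intensity_map(st, ls, com)
  # a single type forages at ratio 1, so per-cell intensity is F * class
  # suitability; the ABZ suitability (1.05 + 1.0) tops all classes and the
  # landscape maximum falls on an ABZ cell
  expect_true(all(which(fi == max(fi)) %in% which(as.vector(ls$abz))))
  interior <- matrix(FALSE, 15, 15)
  interior[6:10, 6:10] <- TRUE
  expect_gt(min(fi[ls$abz & interior]), max(fi[interior & !ls$abz]))
})

test_that("land-use-scale summaries apply the adjacency patch filter", {
  # arable block, an adjacent forest patch, and an isolated forest patch
  # separated by water
  nm <- matrix("arable", 10, 10)
  nm[, 6] <- "water"
  nm[, 7:10] <- "forest"
  nm[1:4, 4:5] <- "forest"  # adjacent forest patch inside arable block
  ls <- toy_landscape(nm)
  masks <- beescape:::landuse_masks(ls)
  expect_true(all(masks$arable[ls$land_use == land_use_classes()["arable"]]))
  # adjacent patch included, isolated patch beyond water excluded
  expect_true(all(masks$forest[1:4, 4:5]))
  expect_false(any(masks$forest[, 7:10]))

  com <- default_community(4, seed = 8)
  cfg <- sim_config(years = 3, repetitions = 2, base_seed = 3,
                    record_landuse = TRUE)
  run <- run_simulation(ls, com, cfg)
  summ <- landuse_scale_summary(run)
  expect_setequal(summ$class, c("arable", "forest", "grassland"))
  ar <- summ[summ$class == "arable", ]
  expect_equal(ar$cells, sum(masks$arable))
  expect_equal(ar$density_m2, ar$abundance / (ar$cells * 400))
  # grassland has no cells here: zero density, certain quasi-extinction
  gr <- summ[summ$class == "grassland", ]
  expect_equal(gr$density_m2, 0)
  expect_equal(gr$qe_risk, 1)
})
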