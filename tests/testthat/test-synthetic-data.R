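test_that("phantom regions: dimensions, determinism, limited overlap", {
  maps <- make_phantom_regions()
  expect_equal(dim(maps), c(16L, 64L * 64L))
  expect_identical(maps, make_phantom_regions())
  cors <- cor(t(maps))
  diag(cors) <- 0
  expect_lt(max(abs(cors)), 0.5)
  expect_error(make_phantom_regions(grid = 16, n_regions = 100),
               "too many regions")
  expect_error(make_phantom_regions(grid = 8), "at least 16")
})

test_that("structural connectivity from endpoint labels counts streamlines", {
  sc <- make_structural_connectivity(list(c(1, 2), c(1, 2), c(2, 1),
                                          c(3, 4)), n_regions = 4L)
  expect_equal(sc$raw_counts[1, 2], 3)
  expect_equal(sc$raw_counts[3, 4], 1)
  expect_equal(sc$weights[1, 2], 1)
  expect_equal(sc$weights[3, 4], 1 / 3, tolerance = 1e-12)

  empty <- make_structural_connectivity(matrix(integer(0), ncol = 2),
                                        n_regions = 4L)
  expect_true(all(empty$weights == 0))
  expect_error(make_structural_connectivity(list(c(1, 9)), n_regions = 4L),
               "endpoint label")

  # built-in phantom bundle design
  sc16 <- make_structural_connectivity()
  expect_equal(sc16$weights, t(sc16$weights))
  expect_true(all(diag(sc16$weights) == 0))
  expect_equal(max(sc16$weights), 1)
  expect_equal(sc16$weights[2, 4], 0.66)   # strong crossing bundle
  expect_equal(sc16$weights[2, 13], 0)     # unconnected probe pair
})

test_that("amplitude draws follow the group design distributions", {
  specA <- group_spec("A", seed = 77)
  pars <- draw_group_params(specA, n_components = 16L, n = 1000L)
  # ICN 6 amplitude in group A ~ Normal(2.5, 0.3)
  ks6 <- ks.test(pars$amplitudes[, 6], "pnorm", 2.5, 0.3)
  expect_gt(ks6$p.value, 0.01)
  # a non-overridden component follows the 3.5 +/- 0.3 base
  ks1 <- ks.test(pars$amplitudes[, 1], "pnorm", 3.5, 0.3)
  expect_gt(ks1$p.value, 0.01)
  # noise levels center on the group mean
  expect_equal(mean(pars$noise_levels), 1.7, tolerance = 0.05)

  specC <- group_spec("C", seed = 78)
  parsC <- draw_group_params(specC, n_components = 16L, n = 1000L)
  expect_gt(ks.test(parsC$amplitudes[, 8], "pnorm", 2.5, 0.3)$p.value, 0.01)
  expect_gt(ks.test(parsC$amplitudes[, 11], "pnorm", 2.5, 0.3)$p.value, 0.01)
  expect_equal(mean(parsC$noise_levels), 1.1, tolerance = 0.05)
})

test_that("zero noise and identity transforms give exact separability", {
  maps <- make_phantom_regions(grid = 16, seed = 5)
  spec <- group_spec("A", n_subjects = 1L, seed = 6)
  spec$noise_mean <- 0; spec$noise_sd <- 0
  spec$scale_factor <- 1; spec$max_translation <- 0; spec$max_rotation <- 0
  sc <- make_structural_connectivity()
  sims <- suppressMessages(
    simulate_group(spec, maps, n_time = 50, sc = sc, keep_raw = TRUE))
  g <- sims$truth$amplitudes[1, ]
  tc <- sims$truth$tcs[[1]]
  recon <- crossprod(tc * g, attr(sims$truth$maps[[1]], "raw"))
  expect_equal(sims$raw <- sims$truth$raw[[1]]$noiseless, recon,
               tolerance = 1e-10)
  # identity transforms leave the maps untouched
  expect_equal(attr(sims$truth$maps[[1]], "raw"), unclass(maps)[, ],
               ignore_attr = TRUE)
})

test_that("simulated time-course correlations track SC weights", {
  sc <- make_structural_connectivity()
  tc <- make_timecourses(16L, 3000L, sc, coupling = 0.5, seed = 42)
  emp <- cor(t(tc))
  ut <- upper.tri(emp)
  ct <- cor.test(emp[ut], sc$weights[ut], method = "spearman",
                 alternative = "greater", exact = FALSE)
  expect_lt(ct$p.value, 0.01)
  # coupled pairs approach the target correlation at T = 3000
  strong <- which(sc$weights == 1, arr.ind = TRUE)[1, ]
  expect_equal(emp[strong[1], strong[2]], 0.5, tolerance = 0.1)
})

test_that("simulate_group is seed-deterministic and standardized", {
  maps <- make_phantom_regions(grid = 16, seed = 8)
  spec <- group_spec("B", n_subjects = 2L, seed = 9)
  sc <- make_structural_connectivity()
  s1 <- simulate_group(spec, maps, n_time = 40, sc = sc)
  s2 <- simulate_group(spec, maps, n_time = 40, sc = sc)
  expect_identical(s1$subjects[[2]]$data, s2$subjects[[2]]$data)
  expect_lt(max(abs(colMeans(s1$subjects[[1]]$data))), 1e-8)
  expect_error(simulate_group(spec, maps, n_time = 1, sc = sc),
               "two time points")
})

test_that("the averaged template degrades monotonically with noise", {
  maps <- make_phantom_regions(grid = 32, seed = 12)
  tpl0 <- make_template(list(maps), deform_sd = 0, noise_sd = 0)
  # identity case: z-scored ground truth exactly
  expect_equal(tpl0$maps,
               t(apply(maps, 1, function(z) {
                 z <- z - mean(z); z / sqrt(mean(z^2))
               })), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(nrow(tpl0$maps), 16L)

  mean_corr <- function(noise_sd) {
    mean(sapply(1:6, function(sd) {
      tpl <- make_template(list(maps), deform_sd = 0, noise_sd = noise_sd,
                           seed = sd)
      mean(sapply(1:16, function(l) cor(tpl$maps[l, ], maps[l, ])))
    }))
  }
  cc <- sapply(c(0, 0.5, 1.5, 4), mean_corr)
  expect_true(all(diff(cc) < 0))
})

test_that("simulate_study assembles the three-group design", {
  st <- simulate_study(seed = 4, n_subjects = 2L, n_time = 30L)
  expect_named(st$groups, c("A", "B", "C"))
  expect_length(st$group_names, 6L)
  expect_equal(nrow(st$template$maps), 16L)
  expect_s3_class(st$sc, "sfcica_sc")
  expect_equal(dim(st$groups$B$subjects[[1]]$data), c(30L, 4096L))
})

test_that("warp_map with identity parameters is the identity", {
  maps <- make_phantom_regions(grid = 16, seed = 3)
  expect_equal(warp_map(maps[1, ], 16), maps[1, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # pure translation moves the centroid of an interior blob by exactly dx
  g <- 32
  xs <- seq_len(g)
  blob <- as.vector(exp(-((matrix(xs, g, g) - 14)^2 +
                            (matrix(xs, g, g, byrow = TRUE) - 16)^2) / 8))
  shifted <- warp_map(blob, g, dx = 2)
  cen <- function(v) sum(seq_len(g) * rowSums(matrix(v, g, g))) / sum(v)
  expect_equal(cen(shifted) - cen(blob), 2, tolerance = 1e-6)
})
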