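#' Phantom ICN spatial maps on a square grid
#'
#' Generates `n_regions` smooth, compact, minimally overlapping Gaussian
#' blobs arranged on a ring (emulating the 16 regions of a FiberCup-style
#' phantom) over a `grid x grid` plane. Deterministic given `seed`: the seed
#' only jitters blob centers and widths slightly so phantoms differ across
#' studies but not across runs.
#'
#' @param grid side length of the square plane (voxels).
#' @param n_regions number of phantom ICNs.
#' @param seed integer seed for the center/width jitter.
#' @return L x V matrix of maps (V = grid^2, x-fastest linearization), with
#'   attributes `grid` and `centers` (L x 2 matrix of blob centers).
#' @export
make_phantom_regions <- function(grid = 64L, n_regions = 16L, seed = 1L) {
  grid <- as.integer(grid)
  if (grid < 16L) stop("grid must be at least 16")
  if (n_regions > grid^2 / 4) stop("too many regions for this grid")
  set.seed(seed)
  cx <- (grid + 1) / 2
  radius <- 0.36 * grid
  ang <- 2 * pi * (seq_len(n_regions) - 1) / n_regions +
    stats::rnorm(n_regions, 0, 0.02)
  rr <- radius * (1 + stats::rnorm(n_regions, 0, 0.02))
  centers <- cbind(cx + rr * cos(ang), cx + rr * sin(ang))
  sds <- grid / 18 * (1 + stats::runif(n_regions, -0.1, 0.1))

  xs <- seq_len(grid)
  gx <- matrix(xs, grid, grid)          # x varies along rows (x-fastest)
  gy <- matrix(xs, grid, grid, byrow = TRUE)
  maps <- matrix(0, n_regions, grid^2)
  for (l in seq_len(n_regions)) {
    d2 <- (gx - centers[l, 1])^2 + (gy - centers[l, 2])^2
    blob <- exp(-d2 / (2 * sds[l]^2))
    blob[blob < 1e-4] <- 0              # compact support
    maps[l, ] <- as.vector(blob)
  }
  structure(maps, grid = grid, centers = centers, blob_sd = sds)
}

# fixed FiberCup-like bundle design: ring-adjacent connections plus crossing
# chords, with heterogeneous streamline counts spanning weak to strong.
phantom_bundles <- function() {
  ring <- cbind(1:16, c(2:16, 1))
  ring_counts <- c(40, 55, 30, 70, 25, 60, 35, 80, 20, 50, 45, 65, 28, 75,
                   38, 58)
  chords <- rbind(c(2, 4), c(1, 9), c(3, 11), c(6, 14), c(8, 16), c(5, 12),
                  c(7, 15))
  chord_counts <- c(66, 100, 48, 52, 34, 22, 18)
  list(pairs = rbind(ring, chords), counts = c(ring_counts, chord_counts))
}

#' Structural connectivity matrix of the phantom
#'
#' Either counts streamlines from explicit endpoint label pairs, or (the
#' default) uses the built-in phantom bundle design: every ring-adjacent
#' region pair is connected, plus a set of crossing chords, with streamline
#' counts spanning weak to strong. Counts are symmetrized, the diagonal is
#' zeroed, and weights are rescaled so the strongest connection is 1.
#'
#' @param endpoint_labels optional 2-column matrix (or list of length-2
#'   vectors) of streamline endpoint labels in `1..n_regions`; each row is
#'   one streamline.
#' @param n_regions number of nodes.
#' @return `sfcica_sc` object.
#' @export
make_structural_connectivity <- function(endpoint_labels = NULL,
                                         n_regions = 16L) {
  counts <- matrix(0, n_regions, n_regions)
  if (is.null(endpoint_labels)) {
    b <- phantom_bundles()
    if (n_regions != 16L)
      stop("the built-in phantom bundle design has 16 regions")
    for (i in seq_len(nrow(b$pairs))) {
      p <- b$pairs[i, ]
      counts[p[1], p[2]] <- counts[p[1], p[2]] + b$counts[i]
      counts[p[2], p[1]] <- counts[p[2], p[1]] + b$counts[i]
    }
  } else {
    if (is.list(endpoint_labels))
      endpoint_labels <- do.call(rbind, endpoint_labels)
    endpoint_labels <- matrix(as.integer(endpoint_labels), ncol = 2L)
    if (nrow(endpoint_labels) > 0) {
      if (any(endpoint_labels < 1L) || any(endpoint_labels > n_regions))
        stop("endpoint label outside 1..", n_regions)
      for (i in seq_len(nrow(endpoint_labels))) {
        p <- endpoint_labels[i, ]
        if (p[1] != p[2]) {
          counts[p[1], p[2]] <- counts[p[1], p[2]] + 1
          counts[p[2], p[1]] <- counts[p[2], p[1]] + 1
        }
      }
    }
  }
  structural_matrix(counts)
}

#' Group design specification for the synthetic study
#'
#' Returns the stated design parameters of the three synthetic groups: the
#' per-subject noise-level distribution (contrast-to-noise ratio; higher is
#' cleaner), component amplitude distributions (`g_ic`), the spatial
#' expansion/contraction factor, and the deformation ranges. Group A:
#' noise level ~ Normal(1.7, 0.2), expansion 1.2, ICN 6 amplitude
#' ~ Normal(2.5, 0.3); Group B: Normal(1.5, 0.4), contraction 0.9, ICN 6
#' ~ Normal(3.5, 0.3); Group C: Normal(1.1, 0.35), expansion 1.3, ICNs 8 and
#' 11 ~ Normal(2.5, 0.3). All other amplitudes ~ Normal(3.5, 0.3).
#'
#' @param name `"A"`, `"B"` or `"C"`.
#' @param n_subjects subjects in the group (default 10).
#' @param seed integer seed for all of the group's random draws.
#' @return list of class `sfcica_group_spec`.
#' @export
group_spec <- function(name = c("A", "B", "C"), n_subjects = 10L,
                       seed = NULL) {
  name <- match.arg(name)
  base <- list(name = name, n_subjects = as.integer(n_subjects),
               amplitude_base = c(mean = 3.5, sd = 0.3),
               max_translation = 2, max_rotation = 10, seed = seed)
  extra <- switch(name,
    A = list(noise_mean = 1.7, noise_sd = 0.2, scale_factor = 1.2,
             amplitude_overrides = list("6" = c(mean = 2.5, sd = 0.3))),
    B = list(noise_mean = 1.5, noise_sd = 0.4, scale_factor = 0.9,
             amplitude_overrides = list("6" = c(mean = 3.5, sd = 0.3))),
    C = list(noise_mean = 1.1, noise_sd = 0.35, scale_factor = 1.3,
             amplitude_overrides = list("8" = c(mean = 2.5, sd = 0.3),
                                        "11" = c(mean = 2.5, sd = 0.3))))
  structure(c(base, extra), class = "sfcica_group_spec")
}

#' Draw per-subject generative parameters for a group
#'
#' Exposes the random draws used by [simulate_group()]: component
#' amplitudes, per-subject noise level (CNR), and per-component rigid
#' deformation parameters (translations in voxels, rotation in degrees).
#'
#' @param spec `sfcica_group_spec`.
#' @param n_components number of ICNs.
#' @param n number of subjects to draw (default `spec$n_subjects`).
#' @param seed overrides `spec$seed`.
#' @return list with `amplitudes` (n x L), `noise_levels` (length n),
#'   `transforms` (list of n L x 3 matrices: dx, dy, rot).
#' @export
draw_group_params <- function(spec, n_components = 16L,
                              n = spec$n_subjects, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  L <- n_components
  amp_mean <- rep(spec$amplitude_base["mean"], L)
  amp_sd <- rep(spec$amplitude_base["sd"], L)
  for (k in names(spec$amplitude_overrides)) {
    i <- as.integer(k)
    amp_mean[i] <- spec$amplitude_overrides[[k]]["mean"]
    amp_sd[i] <- spec$amplitude_overrides[[k]]["sd"]
  }
  amplitudes <- matrix(stats::rnorm(n * L, rep(amp_mean, each = n),
                                    rep(amp_sd, each = n)), n, L)
  noise_levels <- stats::rnorm(n, spec$noise_mean, spec$noise_sd)
  noise_levels <- pmax(noise_levels, 0.1) * (spec$noise_mean > 0)
  transforms <- lapply(seq_len(n), function(i)
    cbind(dx = stats::runif(L, -spec$max_translation, spec$max_translation),
          dy = stats::runif(L, -spec$max_translation, spec$max_translation),
          rot = stats::runif(L, -spec$max_rotation, spec$max_rotation)))
  list(amplitudes = amplitudes, noise_levels = noise_levels,
       transforms = transforms)
}

# inverse-mapping bilinear warp of one grid x grid map: scale and rotate
# about the grid center, then translate by (dx, dy) voxels; zero outside.
warp_map <- function(map_vec, grid, scale = 1, rot_deg = 0, dx = 0, dy = 0) {
  img <- matrix(map_vec, grid, grid)
  c0 <- (grid + 1) / 2
  th <- rot_deg * pi / 180
  xs <- seq_len(grid)
  qx <- matrix(xs, grid, grid) - c0 - dx
  qy <- matrix(xs, grid, grid, byrow = TRUE) - c0 - dy
  # inverse rotation and scale back into source coordinates
  px <- (cos(th) * qx + sin(th) * qy) / scale + c0
  py <- (-sin(th) * qx + cos(th) * qy) / scale + c0
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  pick <- function(ix, iy) {
    ok <- ix >= 1 & ix <= grid & iy >= 1 & iy <= grid
    out <- numeric(length(ix))
    out[ok] <- img[cbind(ix[ok], iy[ok])]
    out
  }
  v <- pick(c(x0), c(y0)) * c((1 - fx) * (1 - fy)) +
    pick(c(x0 + 1), c(y0)) * c(fx * (1 - fy)) +
    pick(c(x0), c(y0 + 1)) * c((1 - fx) * fy) +
    pick(c(x0 + 1), c(y0 + 1)) * c(fx * fy)
  v
}

#' Temporally smooth time courses with an SC-coupled correlation target
#'
#' Generates L unit-variance, temporally smoothed Gaussian-process time
#' courses whose pairwise correlations target
#' `coupling * M_lj` (the rescaled structural connectivity weight): white
#' noise is convolved with a Gaussian kernel, z-scored, and mixed through
#' the Cholesky factor of the target correlation matrix.
#'
#' @param L number of components.
#' @param n_time number of time points.
#' @param sc `sfcica_sc` or L x L weight matrix (or `NULL` for independent
#'   courses).
#' @param coupling scalar in `[0, 1]` scaling the SC weights into target
#'   correlations.
#' @param seed integer seed.
#' @param smooth_sd Gaussian smoothing kernel width in samples.
#' @return L x n_time matrix with population-z-scored rows.
#' @export
make_timecourses <- function(L, n_time, sc = NULL, coupling = 0.5,
                             seed = NULL, smooth_sd = 2) {
  if (n_time < 2) stop("need at least two time points")
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  Mw <- as_sc_weights(sc, L)
  R <- coupling * Mw
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) NULL)
  lam <- 0
  while (is.null(ch)) {                  # ridge fallback for non-PD targets
    lam <- max(2 * lam, 1e-3)
    ch <- tryCatch(chol((R + lam * diag(L)) / (1 + lam)),
                   error = function(e) NULL)
  }
  k <- ceiling(3 * smooth_sd)
  kern <- stats::dnorm(seq(-k, k), sd = smooth_sd)
  kern <- kern / sqrt(sum(kern^2))
  Z <- matrix(stats::rnorm(L * (n_time + 2 * k)), L)
  Zs <- t(apply(Z, 1L, function(z)
    stats::convolve(z, kern, type = "filter")))
  Zs <- t(apply(Zs, 1L, zscore_pop))
  tc <- crossprod(ch, Zs)
  t(apply(tc, 1L, zscore_pop))
}

#' Simulate one synthetic group of subjects
#'
#' SimTB-style spatiotemporally separable simulation: for each subject,
#' component amplitudes `g_ic` are drawn from the group's normal
#' distributions, each phantom map is deformed (group expansion/contraction
#' plus per-component random translation and rotation), time courses are
#' smoothed Gaussian processes whose pairwise correlations target
#' `coupling * SC weight`, and the data are
#' `sum_l g_l * tc_l(t) * map_l(v)` plus Gaussian noise whose standard
#' deviation is `mean(g) / CNR` with the subject's noise level CNR drawn
#' from the group distribution (a noise level of 0 disables noise).
#' The generated volumes are standardized with [standardize_subject()].
#'
#' @param spec `sfcica_group_spec`.
#' @param maps L x V phantom maps from [make_phantom_regions()].
#' @param n_time time points (default 3000).
#' @param tr repetition time in seconds (metadata only; default 2).
#' @param sc `sfcica_sc` structural matrix.
#' @param coupling SC-correlation coupling in `[0, 1]` (default 0.5).
#' @param keep_raw keep each subject's raw (unstandardized) noiseless and
#'   noisy data matrices (memory heavy; for small examples and tests).
#' @return list with `subjects` (list of `sfcica_subject`) and `truth`
#'   (per-subject deformed `maps`, `tcs`, `amplitudes`, `noise_levels`,
#'   `transforms`, plus the shared `sc` and `tr`).
#' @export
simulate_group <- function(spec, maps, n_time = 3000L, tr = 2,
                           sc = make_structural_connectivity(),
                           coupling = 0.5, keep_raw = FALSE) {
  if (n_time < 2) stop("need at least two time points")
  grid <- attr(maps, "grid")
  if (is.null(grid)) grid <- as.integer(sqrt(ncol(maps)))
  L <- nrow(maps)
  pars <- draw_group_params(spec, n_components = L)
  n <- spec$n_subjects
  subjects <- vector("list", n)
  truth_maps <- vector("list", n)
  truth_tcs <- vector("list", n)
  raw <- if (keep_raw) vector("list", n) else NULL
  mask <- array(TRUE, c(grid, grid, 1L))
  base_seed <- if (is.null(spec$seed)) 0L else spec$seed
  for (i in seq_len(n)) {
    tf <- pars$transforms[[i]]
    Wm <- matrix(0, L, grid^2)
    for (l in seq_len(L))
      Wm[l, ] <- warp_map(maps[l, ], grid, scale = spec$scale_factor,
                          rot_deg = tf[l, "rot"], dx = tf[l, "dx"],
                          dy = tf[l, "dy"])
    tc <- make_timecourses(L, n_time, sc, coupling,
                           seed = base_seed + 1000L + i)
    g <- pars$amplitudes[i, ]
    signal <- crossprod(tc * g, Wm)      # n_time x V
    cnr <- pars$noise_levels[i]
    sigma <- if (cnr > 0) mean(g) / cnr else 0
    data <- signal
    if (sigma > 0)
      data <- data + matrix(stats::rnorm(length(signal), 0, sigma),
                            nrow(signal))
    if (keep_raw) raw[[i]] <- list(noiseless = signal, noisy = data)
    arr <- array(t(data), c(grid, grid, 1L, n_time))
    subjects[[i]] <- standardize_subject(arr, mask,
                                         sprintf("%s%02d", spec$name, i))
    # ground truth in the standardized data space: per-voxel variance
    # normalization rescales each map by 1/sd(v)
    sdv <- sqrt(pmax(colMeans(sweep(data, 2L, colMeans(data), "-")^2),
                     1e-12))
    truth_maps[[i]] <- sweep(Wm, 2L, sdv, "/")
    attr(truth_maps[[i]], "raw") <- Wm
    truth_tcs[[i]] <- tc
  }
  list(subjects = subjects,
       truth = list(maps = truth_maps, tcs = truth_tcs,
                    amplitudes = pars$amplitudes,
                    noise_levels = pars$noise_levels,
                    transforms = pars$transforms, sc = sc, tr = tr,
                    raw = raw))
}

#' Noisy averaged spatial template
#'
#' Builds the prior template the constrained models consume: each ICN map is
#' averaged over the supplied group-level maps, a small random rigid
#' deformation is applied, Gaussian noise is added, and the result is
#' z-scored per map.
#'
#' @param group_maps list of L x V map matrices (one per group).
#' @param deform_sd standard deviation of the per-map random translation in
#'   voxels (rotation sd is `2 * deform_sd` degrees). 0 disables.
#' @param noise_sd additive Gaussian noise sd relative to each averaged
#'   map's own sd. 0 disables.
#' @param seed integer seed.
#' @return `sfcica_template`.
#' @export
make_template <- function(group_maps, deform_sd = 0.5, noise_sd = 0.3,
                          seed = 1L) {
  if (length(group_maps) < 1L) stop("need at least one group of maps")
  set.seed(seed)
  avg <- Reduce("+", group_maps) / length(group_maps)
  grid <- as.integer(sqrt(ncol(avg)))
  L <- nrow(avg)
  out <- matrix(0, L, ncol(avg))
  for (l in seq_len(L)) {
    m <- avg[l, ]
    if (deform_sd > 0)
      m <- warp_map(m, grid, scale = 1,
                    rot_deg = stats::rnorm(1, 0, 2 * deform_sd),
                    dx = stats::rnorm(1, 0, deform_sd),
                    dy = stats::rnorm(1, 0, deform_sd))
    if (noise_sd > 0) {
      s <- sqrt(mean((m - mean(m))^2))
      m <- m + stats::rnorm(length(m), 0, noise_sd * s)
    }
    out[l, ] <- m
  }
  spatial_template(out)
}

#' Simulate the full three-group synthetic study
#'
#' Convenience wrapper generating the phantom maps, the structural
#' connectivity matrix, groups A, B and C with their stated design
#' parameters, and the noisy averaged template.
#'
#' @param seed master seed; all group and template seeds derive from it.
#' @param n_subjects subjects per group (default 10).
#' @param n_time time points (default 3000).
#' @param grid grid side (default 64).
#' @param coupling SC-correlation coupling (default 0.5).
#' @return list with `groups` (named list of [simulate_group()] outputs),
#'   `template`, `sc`, `maps` (undeformed phantom maps), `group_names`.
#' @export
simulate_study <- function(seed = 1L, n_subjects = 10L, n_time = 3000L,
                           grid = 64L, coupling = 0.5) {
  maps <- make_phantom_regions(grid = grid, n_regions = 16L, seed = seed)
  sc <- make_structural_connectivity()
  groups <- list()
  for (g in c("A", "B", "C")) {
    spec <- group_spec(g, n_subjects = n_subjects,
                       seed = seed + 17L * match(g, c("A", "B", "C")))
    groups[[g]] <- simulate_group(spec, maps, n_time = n_time, sc = sc,
                                  coupling = coupling)
  }
  ref_maps <- lapply(c(A = 1.2, B = 0.9, C = 1.3), function(sf) {
    t(vapply(seq_len(nrow(maps)),
             function(l) warp_map(maps[l, ], grid, scale = sf),
             numeric(ncol(maps))))
  })
  template <- make_template(ref_maps, seed = seed + 97L)
  list(groups = groups, template = template, sc = sc, maps = maps,
       group_names = rep(c("A", "B", "C"), each = n_subjects))
}
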