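test_that("negentropy is ~0 for Gaussian sources and even in w", {
  set.seed(10)
  V <- 1e5
  X <- matrix(rnorm(V), 1, V)       # w of length 1: source is the row itself
  expect_lt(negentropy_term(1, X), 1e-3)

  inst <- tiny_instance(seed = 3)
  w <- inst$W[1, ]
  expect_equal(negentropy_term(w, inst$X), negentropy_term(-w, inst$X))
  expect_gte(negentropy_term(w, inst$X), 0)
})

test_that("negentropy of a Laplacian source matches a Monte-Carlo oracle", {
  set.seed(11)
  V <- 1e5
  lap <- rexp(V) * sample(c(-1, 1), V, replace = TRUE) / sqrt(2)
  X <- matrix(lap, 1, V)
  J_hat <- negentropy_term(1, X)

  # independent high-precision oracle: 1e7 Laplacian draws, z-scored,
  # (E[G(s)] - E[G(nu)])^2 with the same analytic normal expectation
  set.seed(12)
  n <- 1e7
  s <- rexp(n) * sample(c(-1, 1), n, replace = TRUE)
  s <- (s - mean(s)) / sd(s)
  G <- function(x) { a <- abs(x); a + log1p(exp(-2 * a)) - log(2) }
  EGnu <- integrate(function(x) G(x) * dnorm(x), -Inf, Inf,
                    rel.tol = 1e-12)$value
  gbar <- mean(G(s))
  J_oracle <- (gbar - EGnu)^2
  # delta-method standard error of the V=1e5 estimate dominates
  se_mean <- sd(G((lap - mean(lap)) / sd(lap))) / sqrt(V)
  se_J <- 2 * abs(gbar - EGnu) * se_mean
  expect_lt(abs(J_hat - J_oracle), 3 * se_J)
})

test_that("template term is exactly the Pearson correlation", {
  inst <- tiny_instance(n_time = 30, n_vox = 500, seed = 4)
  w <- inst$W[2, ]
  s <- drop(crossprod(inst$X, w))
  expect_equal(template_term(w, inst$X, inst$TPL[2, ]),
               cor(s, inst$TPL[2, ]), tolerance = 1e-12)

  # self-correlation: data whose first time point carries the template
  tpl <- inst$TPL[1, ]
  X <- rbind(tpl, matrix(0, 4, length(tpl)))
  w <- c(1, 0, 0, 0, 0)
  expect_equal(template_term(w, X, tpl), 1, tolerance = 1e-12)

  # orthogonal (zero covariance) estimated map
  v <- length(tpl)
  tpl2 <- rep(c(1, -1), v / 2)        # orthogonal to any even/odd-flat map
  X2 <- rbind(rep(c(1, 1), v / 2) - 1, matrix(0, 3, v))
  X2[1, ] <- rnorm(v)
  X2[1, ] <- X2[1, ] - mean(X2[1, ])
  proj <- sum(X2[1, ] * tpl2) / sum(tpl2^2)
  X2[1, ] <- X2[1, ] - proj * tpl2    # make covariance exactly zero
  expect_equal(template_term(c(1, 0, 0, 0), X2, tpl2), 0, tolerance = 1e-12)
})

test_that("SC penalty matches its closed forms", {
  inst <- tiny_instance(seed = 5)
  L <- nrow(inst$W)
  expect_equal(sapply(seq_len(L), function(l)
    sc_penalty_term(inst$W, matrix(0, L, L), l)), rep(0, L))

  W_same <- matrix(rep(inst$W[1, ], L), L, byrow = TRUE)
  expect_equal(sc_penalty_term(W_same, inst$M, 1), 0)

  W2 <- rbind(c(1, 0), c(0, 1))
  M2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(sc_penalty_term(W2, M2, 1), 2)

  # distance/inner-product identity for unit rows
  for (l in seq_len(L)) {
    lhs <- sc_penalty_term(inst$W, inst$M, l)
    rhs <- sum(inst$M[l, ] * (2 - 2 * drop(inst$W %*% inst$W[l, ])))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("total cost is additive in its terms and respects the weights", {
  inst <- tiny_instance(seed = 6)
  cfg0 <- sfcica_config(alpha = 0, beta = 0, gamma = 0)
  expect_equal(total_cost(inst$W, inst$X, inst$TPL, inst$M, cfg0)$cost, 0)

  cfg <- sfcica_config(normalize_terms = FALSE)
  tc <- total_cost(inst$W, inst$X, inst$TPL, inst$M, cfg)
  L <- nrow(inst$W)
  J <- sapply(seq_len(L), function(l) negentropy_term(inst$W[l, ], inst$X))
  Fv <- sapply(seq_len(L), function(l)
    template_term(inst$W[l, ], inst$X, inst$TPL[l, ]))
  Lv <- sapply(seq_len(L), function(l) sc_penalty_term(inst$W, inst$M, l))
  expect_equal(tc$cost, 0.33 * sum(J) + 0.33 * sum(Fv) - 0.33 * sum(Lv),
               tolerance = 1e-12)

  cfg_g0 <- sfcica_config(gamma = 0, normalize_terms = FALSE)
  expect_equal(total_cost(inst$W, inst$X, inst$TPL, inst$M, cfg_g0)$cost,
               0.33 * sum(J) + 0.33 * sum(Fv), tolerance = 1e-12)
})


test_that("analytic gradient matches finite differences, per term and combined", {
  # each term in isolation, then the combined default weighting
  expect_lt(fd_check(sfcica_config(alpha = 1, beta = 0, gamma = 0), 21), 1e-4)
  expect_lt(fd_check(sfcica_config(alpha = 0, beta = 1, gamma = 0), 22), 1e-4)
  expect_lt(fd_check(sfcica_config(alpha = 0, beta = 0, gamma = 1), 23), 1e-4)
  expect_lt(fd_check(sfcica_config(), 24), 1e-4)
  expect_lt(fd_check(sfcica_config(contrast_fn = "kurtosis"), 25), 1e-4)
})

test_that("gradient lives in the tangent space and ignores an all-zero M", {
  inst <- tiny_instance(seed = 7)
  cfg <- sfcica_config()
  g <- cost_gradient(inst$W[1, ], inst$W, inst$X, inst$TPL, inst$M, cfg,
                     l = 1L)
  expect_lt(abs(sum(g * inst$W[1, ])), 1e-10)

  L <- nrow(inst$W)
  nrm <- c(J = 1, F = 1, L = 1)
  g_zero_m <- cost_gradient(inst$W[1, ], inst$W, inst$X, inst$TPL,
                            matrix(0, L, L), cfg, l = 1L, normalizers = nrm)
  g_gamma0 <- cost_gradient(inst$W[1, ], inst$W, inst$X, inst$TPL,
                            matrix(0, L, L), sfcica_config(gamma = 0),
                            l = 1L, normalizers = nrm)
  expect_equal(g_zero_m, g_gamma0)
})

test_that("Armijo line search accepts and backtracks as enumerated", {
  cfg <- sfcica_config(mu0 = 1, armijo_shrink = 0.5, armijo_c = 1e-4)
  w <- c(1, 0)
  d <- c(0, 1)
  grad <- d

  # locally linear ascent: the first trial must be accepted
  lin <- function(v) sum(v * c(0, 1))
  expect_equal(armijo_step(w, d, lin, grad, cfg), 1)

  # concave toy cost on the sphere: enumerate the backtracking sequence
  quad <- function(v) v[2] - 40 * (1 - v[1])^2
  mu_enum <- NA
  for (i in 0:cfg$max_backtracks) {
    mu <- cfg$mu0 * cfg$armijo_shrink^i
    trial <- (w + mu * d) / sqrt(1 + mu^2)
    if (quad(trial) >= quad(w) + cfg$armijo_c * mu * sum(grad * d)) {
      mu_enum <- mu
      break
    }
  }
  mu_got <- armijo_step(w, d, quad, grad, cfg)
  expect_equal(mu_got, mu_enum)
  expect_gt(mu_got, 0)
  # the returned step satisfies the sufficient-increase inequality
  trial <- (w + mu_got * d) / sqrt(1 + mu_got^2)
  expect_gte(quad(trial), quad(w) + cfg$armijo_c * mu_got * sum(grad * d))

  expect_error(armijo_step(w, d, lin, -grad, cfg), "non-ascent")
})

test_that("fit_subject honors its contracts on a small phantom", {
  ph <- small_phantom(seed = 31, n_time = 200)
  sub <- ph$sims$subjects[[1]]
  cfg <- sfcica_config(max_iter = 40)
  fit <- fit_subject(sub, ph$template, ph$sc, cfg)

  expect_equal(unname(rowSums(fit$W^2)), rep(1, 16), tolerance = 1e-10)
  expect_equal(fit$S, fit$W %*% sub$data)
  expect_true(all(fit$template_corr >= 0))   # sign anchoring
  # monotone ascent of the accepted-iteration cost trace
  expect_gte(min(diff(fit$cost_trace)), -1e-9 * max(abs(fit$cost_trace)))

  # deterministic
  fit2 <- fit_subject(sub, ph$template, ph$sc, cfg)
  expect_identical(fit$W, fit2$W)

  expect_error(fit_subject(matrix(rnorm(5 * 100), 5, 100),
                           matrix(rnorm(16 * 100), 16, 100), NULL, cfg),
               "more components than time points")
})

test_that("fit_dataset is order-preserving, independent, and validates", {
  ph <- small_phantom(seed = 32, n_time = 150, n_subjects = 3L)
  cfg <- sfcica_config(max_iter = 15)
  fits <- fit_dataset(ph$sims$subjects, ph$template, ph$sc, cfg)
  expect_length(fits, 3L)
  expect_true(all(vapply(fits, function(f) nrow(f$W), 0L) == 16L))

  perm <- c(3, 1, 2)
  fits_perm <- fit_dataset(ph$sims$subjects[perm], ph$template, ph$sc, cfg)
  for (i in seq_along(perm))
    expect_identical(fits_perm[[i]]$W, fits[[perm[i]]]$W)

  expect_identical(fit_dataset(list(), ph$template, ph$sc, cfg), list())
  expect_error(fit_dataset(ph$sims$subjects, rep(list(ph$template), 2),
                           ph$sc, cfg), "one template")
})

test_that("the structural penalty pulls the strongest SC pair together", {
  # paired over seeded subjects: |corr| of the maximal-M pair under sfCICA
  # >= CICA in expectation (one-sided sign test)
  n_sub <- 20L
  cfg1 <- sfcica_config(max_iter = 30)
  cfg0 <- sfcica_config(max_iter = 30, gamma = 0)
  wins <- logical(n_sub)
  deltas <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    ph <- small_phantom(seed = 200 + i, n_time = 300)
    sub <- ph$sims$subjects[[1]]
    idx <- which(ph$sc$weights == max(ph$sc$weights), arr.ind = TRUE)[1, ]
    f1 <- fit_subject(sub, ph$template, ph$sc, cfg1)
    f0 <- fit_subject(sub, ph$template, ph$sc, cfg0)
    r1 <- abs(cor(f1$W[idx[1], ], f1$W[idx[2], ]))
    r0 <- abs(cor(f0$W[idx[1], ], f0$W[idx[2], ]))
    wins[i] <- r1 > r0
    deltas[i] <- r1 - r0
  }
  bt <- binom.test(sum(wins), n_sub, p = 0.5, alternative = "greater")
  expect_lt(bt$p.value, 0.05)
  expect_gt(mean(deltas), 0)
})

test_that("template anchoring: optimized maps beat unoptimized random maps", {
  ph <- small_phantom(seed = 33, n_time = 200)
  sub <- ph$sims$subjects[[1]]
  fit <- fit_subject(sub, ph$template, ph$sc, sfcica_config(max_iter = 30))
  expect_gt(mean(fit$template_corr), 0)

  set.seed(99)
  W_rand <- matrix(rnorm(16 * 200), 16, 200)
  W_rand <- W_rand / sqrt(rowSums(W_rand^2))
  rand_corr <- sapply(1:16, function(l)
    template_term(W_rand[l, ], sub$data, ph$template$maps[l, ]))
  expect_gt(mean(fit$template_corr), mean(rand_corr))
})
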