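# shared fixtures, all generated in code; the expensive full-size study is
# memoized so several test files can share one computation

.fixtures <- new.env(parent = emptyenv())

# small random standardized instance for gradient/cost tests
tiny_instance <- function(n_time = 50L, n_vox = 200L, L = 4L, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n_time * n_vox), n_time, n_vox)
  X <- sweep(X, 2L, colMeans(X), "-")
  X <- sweep(X, 2L, sqrt(colMeans(X^2)), "/")
  TPL <- t(apply(matrix(rnorm(L * n_vox), L, n_vox), 1L, function(z) {
    z <- z - mean(z); z / sqrt(mean(z^2))
  }))
  M <- abs(matrix(rnorm(L * L), L, L))
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M <- M / max(M)
  W <- matrix(rnorm(L * n_time), L, n_time)
  W <- W / sqrt(rowSums(W^2))
  list(X = X, TPL = TPL, M = M, W = W)
}

# small phantom subject (32x32 grid, short series) for optimizer behavior
small_phantom <- function(seed = 1L, n_time = 400L, grid = 32L,
                          spec_name = "A", n_subjects = 1L,
                          coupling = 0.5) {
  maps <- make_phantom_regions(grid = grid, n_regions = 16L, seed = seed)
  sc <- make_structural_connectivity()
  spec <- group_spec(spec_name, n_subjects = n_subjects, seed = seed + 50L)
  sims <- simulate_group(spec, maps, n_time = n_time, sc = sc,
                         coupling = coupling)
  tpl <- make_template(list(maps), deform_sd = 0.25, noise_sd = 0.3,
                       seed = seed + 7L)
  list(maps = maps, sc = sc, sims = sims, template = tpl)
}

# the full-size three-group study shared by the acceptance tests
study_fixture <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- synthetic_study(seed = 1L)
  .fixtures$study
}

# independent global-efficiency oracle: Floyd-Warshall on the binary
# adjacency, mean over unordered pairs of 1/d (0 when unreachable)
global_efficiency_oracle <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# exhaustive best-modularity oracle over all partitions (n <= 8)
modularity_oracle <- function(A) {
  n <- nrow(A)
  m <- sum(A) / 2
  deg <- rowSums(A)
  q_of <- function(mem) {
    q <- 0
    for (c in unique(mem)) {
      idx <- which(mem == c)
      e_in <- sum(A[idx, idx]) / 2
      q <- q + e_in / m - (sum(deg[idx]) / (2 * m))^2
    }
    q
  }
  # enumerate set partitions via restricted growth strings
  best <- -Inf
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      best <<- max(best, q_of(rgs))
      return(invisible(NULL))
    }
    for (v in 0:(maxv + 1)) {
      rgs[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
  }
  recurse(1L, -1L)
  best
}

# finite-difference check of cost_gradient on a tiny instance:
# returns the max relative error over random tangent directions
fd_check <- function(cfg, seed, n_dirs = 20) {
  inst <- tiny_instance(seed = seed)
  nrm <- total_cost(inst$W, inst$X, inst$TPL, inst$M, cfg)$normalizers
  l <- 2L
  w <- inst$W[l, ]
  g <- cost_gradient(w, inst$W, inst$X, inst$TPL, inst$M, cfg, l = l,
                     normalizers = nrm)
  set.seed(seed + 100)
  max(sapply(seq_len(n_dirs), function(i) {
    d <- rnorm(length(w))
    d <- d - sum(d * w) * w
    d <- d / sqrt(sum(d^2))
    h <- 1e-5
    cost_at <- function(mu) {
      Wt <- inst$W
      wt <- w + mu * d
      Wt[l, ] <- wt / sqrt(sum(wt^2))
      total_cost(Wt, inst$X, inst$TPL, inst$M, cfg, normalizers = nrm)$cost
    }
    fd <- (cost_at(h) - cost_at(-h)) / (2 * h)
    abs(fd - sum(g * d)) / max(abs(fd), 1e-12)
  }))
}
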