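#' Functional network connectivity matrix
#'
#' Pearson correlations among the estimated component time courses of one
#' subject: symmetric, unit diagonal, entries in \[-1, 1\]. Rows with
#' (numerically) constant time courses get `NA` correlations and are
#' reported via the `undefined` attribute.
#'
#' @param W L x T matrix of time courses, or an `sfcica_fit`.
#' @return L x L correlation matrix of class `sfcica_fnc`.
#' @export
compute_fnc <- function(W) {
  if (inherits(W, "sfcica_fit")) W <- W$W
  W <- as.matrix(W)
  if (ncol(W) < 3L) stop("need at least three time points")
  sds <- apply(W, 1L, stats::sd)
  flat <- which(sds < 1e-12)
  fnc <- suppressWarnings(stats::cor(t(W)))
  fnc[flat, ] <- NA_real_
  fnc[, flat] <- NA_real_
  diag(fnc) <- 1
  structure(fnc, undefined = flat, class = c("sfcica_fnc", class(fnc)))
}

#' Summed squared time-course distance of one component
#'
#' `Dis_l = sum_{j != l} ||w_l - w_j||^2`, the total squared Euclidean
#' distance of component `l`'s (unit-norm) time course from all others. For
#' unit-norm rows this equals `2(L-1) - 2 sum_{j != l} <w_l, w_j>`.
#'
#' @param W L x T matrix of unit-norm time courses, or an `sfcica_fit`.
#' @param l component index; if missing, the full length-L vector is
#'   returned.
#' @return scalar (or vector) of distances.
#' @export
timecourse_distance <- function(W, l = NULL) {
  if (inherits(W, "sfcica_fit")) W <- W$W
  G <- tcrossprod(W)
  n2 <- diag(G)
  D <- outer(n2, n2, "+") - 2 * G
  dis <- rowSums(D)
  if (is.null(l)) dis else dis[l]
}

#' Per-component difference of time-course distances between two models
#'
#' Element-wise `dis_a - dis_b`; by convention `a` is the structurally
#' constrained model and `b` the baseline, so negative values mean the
#' structural penalty pulled time courses closer together.
#'
#' @param dis_a,dis_b equal-length per-component distance vectors.
#' @return vector of differences.
#' @export
distance_diff <- function(dis_a, dis_b) {
  if (length(dis_a) != length(dis_b)) stop("distance vectors differ in length")
  dis_a - dis_b
}

fnc_to_graph <- function(fnc, threshold) {
  A <- abs(as.matrix(fnc)) >= threshold
  A[is.na(A)] <- FALSE
  diag(A) <- FALSE
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' Threshold selection by global cost efficiency
#'
#' Scans a grid of correlation thresholds; at each, every FNC matrix is
#' binarized (`|r| >= t`), and the mean over matrices of global efficiency
#' minus edge density (the network cost) is computed. The threshold
#' maximizing this global cost efficiency is returned; ties break toward the
#' larger threshold.
#'
#' @param fnc_set one FNC matrix or a list of them.
#' @param grid thresholds to scan (default `seq(0.05, 0.95, by = 0.01)`).
#' @return selected threshold, with the scanned `curve` as an attribute.
#' @export
optimal_threshold_gce <- function(fnc_set, grid = seq(0.05, 0.95, by = 0.01)) {
  if (!is.list(fnc_set)) fnc_set <- list(fnc_set)
  if (length(fnc_set) == 0L) stop("empty FNC set")
  if (any(grid <= 0 | grid >= 1)) stop("grid thresholds must be in (0, 1)")
  gce <- vapply(grid, function(t) {
    mean(vapply(fnc_set, function(fnc) {
      g <- fnc_to_graph(fnc, t)
      ge <- igraph::global_efficiency(g)
      if (is.nan(ge)) ge <- 0                 # edgeless graph
      ge - igraph::edge_density(g)
    }, numeric(1)))
  }, numeric(1))
  best <- max(gce)
  sel <- max(grid[gce >= best - 1e-12])   # ties toward larger threshold
  structure(sel, curve = cbind(threshold = grid, gce = gce))
}

#' FNC sparsity at a threshold
#'
#' Fraction of weak connections: with `ST` the number of upper-triangle
#' entries with `|r| >= threshold` (strong connections) and
#' `N = L(L-1)/2` all possible connections, `SP = (N - ST) / N`.
#'
#' @param fnc L x L FNC matrix.
#' @param threshold correlation threshold in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
sparsity <- function(fnc, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  r <- abs(as.matrix(fnc)[upper.tri(fnc)])
  st <- sum(r >= threshold, na.rm = TRUE)
  n <- length(r)
  (n - st) / n
}

#' Graph metrics of a thresholded FNC network
#'
#' Binarizes `|r| >= threshold` and computes, on the unweighted graph:
#' Newman modularity (Louvain, best of `n_restarts` seeded restarts, ties
#' broken toward fewer communities), binary global efficiency (mean inverse
#' shortest path length; unreachable pairs contribute 0), local efficiency
#' (mean over nodes of the global efficiency of each node's neighborhood),
#' small-worldness `sigma = (C/C_rand) / (Lp/Lp_rand)` against `n_null`
#' degree-preserving rewired null graphs (C is the global clustering
#' coefficient, Lp the characteristic path length over reachable pairs), the
#' nonrandomness z-score of the observed clustering against the same null
#' ensemble, and the sparsity at the threshold.
#'
#' @param fnc L x L FNC matrix.
#' @param threshold correlation threshold.
#' @param n_null number of rewired null graphs (default 100).
#' @param seed integer seed for the null ensemble and Louvain restarts.
#' @param n_restarts Louvain restarts (default 10).
#' @return list of class `sfcica_graph_metrics` with `modularity`,
#'   `global_efficiency`, `local_efficiency`, `small_worldness`,
#'   `nonrandomness`, `sparsity`, `threshold`, `disconnected` flag.
#' @export
graph_metrics <- function(fnc, threshold, n_null = 100L, seed = 1L,
                          n_restarts = 10L) {
  g <- fnc_to_graph(fnc, threshold)
  n <- igraph::vcount(g)
  set.seed(seed)

  if (igraph::ecount(g) == 0L) {
    # edgeless graph: modularity is conventionally 0, nulls are meaningless
    return(structure(list(modularity = 0, global_efficiency = 0,
                          local_efficiency = 0, small_worldness = NA_real_,
                          nonrandomness = NA_real_,
                          sparsity = sparsity(fnc, threshold),
                          threshold = threshold, disconnected = TRUE),
                     class = "sfcica_graph_metrics"))
  }

  best_q <- -Inf; best_k <- Inf
  for (i in seq_len(n_restarts)) {
    cl <- igraph::cluster_louvain(g)
    q <- igraph::modularity(cl)
    k <- length(unique(igraph::membership(cl)))
    if (q > best_q + 1e-12 || (abs(q - best_q) <= 1e-12 && k < best_k)) {
      best_q <- q; best_k <- k
    }
  }

  geff <- igraph::global_efficiency(g)
  leff <- igraph::local_efficiency(g)
  leff <- mean(leff)
  if (is.nan(geff)) geff <- 0

  C_obs <- igraph::transitivity(g, type = "global")
  if (is.nan(C_obs)) C_obs <- 0
  Lp_obs <- igraph::mean_distance(g, unconnected = TRUE)
  disconnected <- !igraph::is_connected(g)

  C_null <- Lp_null <- numeric(n_null)
  for (i in seq_len(n_null)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(
      niter = max(10L * igraph::ecount(g), 1L)))
    cc <- igraph::transitivity(gr, type = "global")
    C_null[i] <- if (is.nan(cc)) 0 else cc
    Lp_null[i] <- igraph::mean_distance(gr, unconnected = TRUE)
  }
  Cr <- mean(C_null); Lr <- mean(Lp_null)
  sigma <- if (Cr > 0 && is.finite(Lp_obs) && is.finite(Lr) && Lr > 0)
    (C_obs / Cr) / (Lp_obs / Lr) else NA_real_
  sd_C <- stats::sd(C_null)
  nonrandom <- if (isTRUE(sd_C > 0)) (C_obs - Cr) / sd_C else NA_real_

  structure(list(modularity = best_q, global_efficiency = geff,
                 local_efficiency = leff, small_worldness = sigma,
                 nonrandomness = nonrandom,
                 sparsity = sparsity(fnc, threshold),
                 threshold = threshold, disconnected = disconnected),
            class = "sfcica_graph_metrics")
}

#' @export
print.sfcica_graph_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<sfcica_graph_metrics> threshold %.2f%s\n",
    "  modularity %.3f | global eff %.3f | local eff %.3f\n",
    "  small-worldness %.3f | nonrandomness %.2f | sparsity %.3f\n"),
    x$threshold, if (x$disconnected) " (disconnected)" else "",
    x$modularity, x$global_efficiency, x$local_efficiency,
    x$small_worldness, x$nonrandomness, x$sparsity))
  invisible(x)
}
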