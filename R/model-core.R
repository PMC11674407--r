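#' Optimizer configuration for the sfCICA model
#'
#' Collects the weights of the three cost terms, the contrast function used
#' by the negentropy term, the Armijo line-search constants, and convergence
#' controls. Setting `gamma = 0` removes the structural-connectivity penalty
#' and yields the unimodal spatially constrained ICA (CICA) baseline: the
#' optimizer path is then identical, iterate for iterate, to a fit that never
#' had a structural matrix.
#'
#' @param alpha,beta,gamma nonnegative weights of the negentropy, template
#'   similarity and structural penalty terms. Defaults follow the equal
#'   weighting 0.33/0.33/0.33.
#' @param contrast_fn `"logcosh"` (default) or `"kurtosis"`; the contrast G
#'   whose expectation difference from a standard normal defines negentropy.
#' @param armijo_c sufficient-increase constant in (0,1).
#' @param armijo_shrink backtracking factor in (0,1).
#' @param mu0 initial step length of the line search.
#' @param max_backtracks line-search trials before declaring a stall.
#' @param max_iter maximum outer iterations (one sweep over all components).
#' @param tol relative total-cost change below which the fit is converged.
#' @param seed integer seed; only consumed when `init = "random"`.
#' @param normalize_terms rescale the three cost terms at iteration 0 so no
#'   term dominates by sheer magnitude (see `normalize_method`).
#' @param normalize_method how the iteration-0 normalizers are measured:
#'   `"grad0"` (default) divides each term by the Frobenius norm of its
#'   gradient over all components at iteration 0, equalizing the terms'
#'   initial pull on the optimizer; `"cost0"` divides each term by the
#'   magnitude of its iteration-0 value so all three start at magnitude ~1.
#'   Both are floored at 1e-12. `"cost0"` can catastrophically over-weight
#'   negentropy when the initial sources are near-Gaussian (its value starts
#'   near zero while its gradient does not), which collapses components onto
#'   duplicate spiky sources; `"grad0"` is the robust default.
#' @param init `"template"` (deterministic dual-regression-style start,
#'   default) or `"random"` (seeded Gaussian start).
#' @param pca_denoise `FALSE` (default) or an integer k: project the data
#'   onto its top-k temporal principal components before fitting.
#' @return list of class `sfcica_config`.
#' @export
sfcica_config <- function(alpha = 0.33, beta = 0.33, gamma = 0.33,
                          contrast_fn = c("logcosh", "kurtosis"),
                          armijo_c = 1e-4, armijo_shrink = 0.5, mu0 = 1,
                          max_backtracks = 30L, max_iter = 256L, tol = 1e-6,
                          seed = NULL, normalize_terms = TRUE,
                          normalize_method = c("grad0", "cost0"),
                          init = c("template", "random"),
                          pca_denoise = FALSE) {
  contrast_fn <- match.arg(contrast_fn)
  normalize_method <- match.arg(normalize_method)
  init <- match.arg(init)
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0,
            armijo_c > 0, armijo_c < 1,
            armijo_shrink > 0, armijo_shrink < 1,
            mu0 > 0, max_backtracks >= 1, max_iter >= 1, tol > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 contrast_fn = contrast_fn, armijo_c = armijo_c,
                 armijo_shrink = armijo_shrink, mu0 = mu0,
                 max_backtracks = as.integer(max_backtracks),
                 max_iter = as.integer(max_iter), tol = tol, seed = seed,
                 normalize_terms = isTRUE(normalize_terms),
                 normalize_method = normalize_method, init = init,
                 pca_denoise = pca_denoise),
            class = "sfcica_config")
}

.sfcica_env <- new.env(parent = emptyenv())

# contrast function G, derivative g, and E[G(nu)] for standard normal nu.
# The normal expectation for log cosh is evaluated once by adaptive
# quadrature and cached.
contrast_spec <- function(name) {
  if (name == "logcosh") {
    if (is.null(.sfcica_env$EG_logcosh)) {
      .sfcica_env$EG_logcosh <- stats::integrate(
        function(x) logcosh(x) * stats::dnorm(x),
        -Inf, Inf, rel.tol = 1e-12)$value
    }
    list(G = logcosh, g = tanh, EGnu = .sfcica_env$EG_logcosh)
  } else if (name == "kurtosis") {
    list(G = function(u) u^4 / 4, g = function(u) u^3, EGnu = 3 / 4)
  } else stop("unknown contrast function: ", name)
}

# numerically safe log cosh: log cosh(x) = |x| + log1p(exp(-2|x|)) - log 2
logcosh <- function(x) {
  a <- abs(x)
  a + log1p(exp(-2 * a)) - log(2)
}

subject_matrix <- function(data) {
  if (inherits(data, "sfcica_subject")) data$data else as.matrix(data)
}

template_maps <- function(template) {
  if (inherits(template, "sfcica_template")) template$maps
  else as.matrix(template)
}

# source row and its population moments for one component
source_stats <- function(w, X) {
  s0 <- drop(crossprod(X, w))
  m <- mean(s0)
  sdv <- sqrt(mean((s0 - m)^2))
  list(s0 = s0, m = m, sd = sdv)
}

#' Negentropy of the spatial source of one component
#'
#' `J = (mean(G(s)) - E[G(nu)])^2` where `s` is the z-scored spatial source
#' `w' X` over voxels and `nu` is standard normal. Zero for Gaussian sources,
#' positive otherwise; maximizing it drives the component toward an
#' independent (non-Gaussian) spatial map.
#'
#' @param w unit-norm time course (length T).
#' @param data `sfcica_subject` or T x V matrix.
#' @param contrast_fn `"logcosh"` or `"kurtosis"`.
#' @return scalar J >= 0.
#' @export
negentropy_term <- function(w, data, contrast_fn = "logcosh") {
  X <- subject_matrix(data)
  cs <- contrast_spec(contrast_fn)
  st <- source_stats(w, X)
  if (st$sd < 1e-12) {
    warning("degenerate source (zero variance); negentropy set to 0")
    return(0)
  }
  s <- (st$s0 - st$m) / st$sd
  (mean(cs$G(s)) - cs$EGnu)^2
}

#' Template-similarity of the spatial source of one component
#'
#' Mean over voxels of the product of the (z-scored) prior template map and
#' the z-scored estimated source, i.e. the Pearson correlation between the
#' estimated and prior spatial map. Range [-1, 1].
#'
#' @param w unit-norm time course.
#' @param data `sfcica_subject` or T x V matrix.
#' @param template_map z-scored prior map (length V).
#' @return scalar correlation.
#' @export
template_term <- function(w, data, template_map) {
  X <- subject_matrix(data)
  st <- source_stats(w, X)
  if (st$sd < 1e-12) {
    warning("degenerate source (zero variance); template term set to 0")
    return(0)
  }
  mean(template_map * (st$s0 - st$m) / st$sd)
}

#' Structural-connectivity weighted time-course distance of one component
#'
#' `L_l = sum_j M_lj ||w_l - w_j||^2`: squared Euclidean distances of the
#' component's time course to every other component, weighted by structural
#' connectivity. For unit-norm rows this equals
#' `sum_j M_lj (2 - 2 <w_l, w_j>)`.
#'
#' @param W L x T matrix of time courses (rows).
#' @param M `sfcica_sc` object or L x L weight matrix.
#' @param l component index.
#' @return scalar >= 0.
#' @export
sc_penalty_term <- function(W, M, l) {
  Mw <- as_sc_weights(M, nrow(W))
  d2 <- rowSums(sweep(W, 2L, W[l, ], "-")^2)
  sum(Mw[l, ] * d2)
}

# raw (unnormalized) per-component term values at W
eval_terms <- function(W, X, TPL, Mw, contrast_fn) {
  L <- nrow(W)
  cs <- contrast_spec(contrast_fn)
  J <- Fv <- Lv <- numeric(L)
  S0 <- W %*% X
  for (l in seq_len(L)) {
    s0 <- S0[l, ]
    m <- mean(s0)
    sdv <- sqrt(mean((s0 - m)^2))
    if (sdv < 1e-12) { J[l] <- 0; Fv[l] <- 0 } else {
      s <- (s0 - m) / sdv
      J[l] <- (mean(cs$G(s)) - cs$EGnu)^2
      Fv[l] <- mean(TPL[l, ] * s)
    }
    d2 <- rowSums(sweep(W, 2L, W[l, ], "-")^2)
    Lv[l] <- sum(Mw[l, ] * d2)
  }
  list(J = J, F = Fv, L = Lv)
}

term_normalizers <- function(terms, normalize) {
  if (!normalize) return(c(J = 1, F = 1, L = 1))
  c(J = max(abs(sum(terms$J)), 1e-12),
    F = max(abs(sum(terms$F)), 1e-12),
    L = max(abs(sum(terms$L)), 1e-12))
}

# Frobenius norms of each term's (unprojected) gradient over all components
grad0_normalizers <- function(W, X, TPL, Mw, contrast_fn) {
  cs <- contrast_spec(contrast_fn)
  L <- nrow(W); V <- ncol(X)
  S0 <- W %*% X
  UJ <- UF <- matrix(0, V, L)
  for (l in seq_len(L)) {
    s0 <- S0[l, ]; m <- mean(s0); sdv <- sqrt(mean((s0 - m)^2))
    if (sdv < 1e-12) next
    s <- (s0 - m) / sdv
    gs <- cs$g(s)
    Ghat <- mean(cs$G(s))
    Fv <- mean(TPL[l, ] * s)
    UJ[, l] <- 2 * (Ghat - cs$EGnu) *
      (gs - mean(gs) - mean(gs * s) * s) / (V * sdv)
    UF[, l] <- (TPL[l, ] - Fv * s) / (V * sdv)
  }
  GJ <- X %*% UJ
  GF <- X %*% UF
  sL2 <- 0
  for (l in seq_len(L)) {
    scg <- 4 * (sum(Mw[l, ]) * W[l, ] - drop(crossprod(W, Mw[l, ])))
    sL2 <- sL2 + sum(scg^2)
  }
  c(J = max(sqrt(sum(GJ^2)), 1e-12),
    F = max(sqrt(sum(GF^2)), 1e-12),
    L = max(sqrt(sL2), 1e-12))
}

# dispatch on the configured iteration-0 normalization scheme
iteration0_normalizers <- function(W, X, TPL, Mw, config) {
  if (!config$normalize_terms) return(c(J = 1, F = 1, L = 1))
  method <- config$normalize_method
  if (is.null(method)) method <- "grad0"
  if (method == "cost0")
    term_normalizers(eval_terms(W, X, TPL, Mw, config$contrast_fn), TRUE)
  else grad0_normalizers(W, X, TPL, Mw, config$contrast_fn)
}

#' Total sfCICA cost
#'
#' `C = sum_l [alpha*J_l + beta*F_l - gamma*L_l]`, each term optionally
#' divided by its per-term normalizer (the magnitude of the term total at
#' iteration 0, floored at 1e-12). When `normalizers` is `NULL` the current
#' term values define the normalizers, which is the iteration-0 convention
#' used by [fit_subject()].
#'
#' @param W L x T matrix of unit-norm time courses.
#' @param data `sfcica_subject` or T x V matrix.
#' @param template `sfcica_template` or L x V z-scored matrix.
#' @param M `sfcica_sc`, L x L matrix, or `NULL` for no structural penalty.
#' @param config `sfcica_config`.
#' @param normalizers optional named vector `c(J=,F=,L=)` of frozen
#'   normalizers.
#' @return list with `cost`, per-component `terms` (`J`, `F`, `L`), and the
#'   `normalizers` used.
#' @export
total_cost <- function(W, data, template, M = NULL, config = sfcica_config(),
                       normalizers = NULL) {
  X <- subject_matrix(data)
  TPL <- template_maps(template)
  Mw <- as_sc_weights(M, nrow(W))
  terms <- eval_terms(W, X, TPL, Mw, config$contrast_fn)
  if (is.null(normalizers))
    normalizers <- iteration0_normalizers(W, X, TPL, Mw, config)
  C <- config$alpha * sum(terms$J) / normalizers["J"] +
    config$beta * sum(terms$F) / normalizers["F"] -
    config$gamma * sum(terms$L) / normalizers["L"]
  list(cost = unname(C), terms = terms, normalizers = normalizers)
}

#' Gradient of the total cost for one component
#'
#' Exact gradient of [total_cost()] with respect to `w_l`, projected onto the
#' tangent space of the unit sphere at `w_l` (the radial component is
#' removed, so `<grad, w_l> = 0`). The structural part is
#' `4 sum_j M_lj (w_l - w_j)` because `w_l` appears in the distance terms of
#' both members of every pair.
#'
#' @param w current time course of component `l` (unit norm).
#' @param W L x T matrix of all time courses (row `l` is ignored in favor of
#'   `w`).
#' @param data,template,M,config as in [total_cost()].
#' @param l component index.
#' @param normalizers optional frozen term normalizers; defaults to the
#'   normalizers at the current `W` (with row `l` set to `w`).
#' @return tangent gradient vector (length T).
#' @export
cost_gradient <- function(w, W, data, template, M = NULL,
                          config = sfcica_config(), l = 1L,
                          normalizers = NULL) {
  X <- subject_matrix(data)
  TPL <- template_maps(template)
  Mw <- as_sc_weights(M, nrow(W))
  W[l, ] <- w
  if (is.null(normalizers))
    normalizers <- iteration0_normalizers(W, X, TPL, Mw, config)
  cs <- contrast_spec(config$contrast_fn)
  V <- ncol(X)
  st <- source_stats(w, X)
  if (st$sd < 1e-12) stop("degenerate source (zero variance) in gradient")
  s <- (st$s0 - st$m) / st$sd
  gs <- cs$g(s)
  Ghat <- mean(cs$G(s))
  Fv <- mean(TPL[l, ] * s)
  uJ <- 2 * (Ghat - cs$EGnu) * (gs - mean(gs) - mean(gs * s) * s)
  uF <- TPL[l, ] - Fv * s
  u <- (config$alpha / normalizers["J"]) * uJ +
    (config$beta / normalizers["F"]) * uF
  grad <- drop(X %*% u) / (V * st$sd)
  if (config$gamma > 0) {
    scg <- 4 * (sum(Mw[l, ]) * w - drop(crossprod(W, Mw[l, ])))
    grad <- grad - (config$gamma / normalizers["L"]) * scg
  }
  if (!all(is.finite(grad))) {
    bad <- c(J = !all(is.finite(uJ)), F = !all(is.finite(uF)))
    stop("non-finite gradient (term: ",
         paste(names(bad)[bad], collapse = ","), ")")
  }
  grad - sum(grad * w) * w
}

#' Armijo backtracking line search on the unit sphere
#'
#' Finds the largest step `mu` in the backtracking sequence
#' `mu0 * shrink^i` such that the renormalized trial point satisfies the
#' sufficient-increase condition
#' `C(renorm(w + mu d)) >= C(w) + armijo_c * mu * <grad, d>`.
#'
#' @param w current unit-norm point.
#' @param d ascent direction (normalized tangent gradient).
#' @param cost_fn function of a unit vector returning the scalar objective.
#' @param grad gradient at `w`; `<grad, d>` must be positive.
#' @param config `sfcica_config` supplying `mu0`, `armijo_shrink`,
#'   `armijo_c`, `max_backtracks`.
#' @return accepted step `mu > 0`, or `0` with attribute `stall = TRUE` when
#'   every trial fails.
#' @export
armijo_step <- function(w, d, cost_fn, grad, config = sfcica_config()) {
  slope <- sum(grad * d)
  if (!is.finite(slope) || slope <= 0) stop("non-ascent direction")
  C0 <- cost_fn(w)
  mu <- config$mu0
  for (i in seq_len(config$max_backtracks)) {
    trial <- w + mu * d
    trial <- trial / sqrt(sum(trial^2))
    if (cost_fn(trial) >= C0 + config$armijo_c * mu * slope) return(mu)
    mu <- mu * config$armijo_shrink
  }
  structure(0, stall = TRUE)
}

#' Fit the sfCICA model for one subject
#'
#' Estimates L unit-norm component time courses `W` (and spatial maps
#' `S = W %*% data`) by projected steepest ascent on the multiobjective cost:
#' negentropy of each spatial source plus Pearson similarity to the prior
#' template map minus the structural-connectivity weighted distance penalty
#' on time courses. Components are updated sequentially within each outer
#' iteration (Gauss-Seidel: each update sees the latest value of the other
#' rows), with step lengths chosen by Armijo backtracking, so the accepted
#' total cost never decreases. With `config$gamma = 0` (or `M = NULL`) the
#' fit is the unimodal CICA baseline.
#'
#' Initialization is deterministic dual-regression style
#' (`w_l = data %*% template_l`, renormalized) unless
#' `config$init = "random"`. After convergence each component's sign is
#' flipped if needed so its template correlation is nonnegative.
#'
#' @param data `sfcica_subject` (or T x V standardized matrix).
#' @param template `sfcica_template` (or L x V z-scored matrix).
#' @param M `sfcica_sc`, L x L weight matrix, or `NULL`.
#' @param config `sfcica_config`.
#' @return `sfcica_fit` with `W` (L x T, unit-norm rows), `S` (L x V,
#'   `S = W %*% data` exactly), `cost_trace`, `term_traces` (per-iteration
#'   raw totals of J, F, L), `converged`, `n_iter`, `normalizers`,
#'   `config`, `subject_id`, `names`.
#' @export
fit_subject <- function(data, template, M = NULL, config = sfcica_config()) {
  X <- subject_matrix(data)
  TPL <- template_maps(template)
  T_ <- nrow(X); V <- ncol(X); L <- nrow(TPL)
  if (ncol(TPL) != V) stop("template and data do not share a voxel space")
  if (L > T_) stop("more components than time points")
  Mw <- as_sc_weights(M, L)
  gamma_on <- config$gamma > 0 && any(Mw > 0)
  cs <- contrast_spec(config$contrast_fn)

  if (!identical(config$pca_denoise, FALSE)) {
    k <- as.integer(config$pca_denoise)
    ee <- eigen(tcrossprod(X) / V, symmetric = TRUE)
    U <- ee$vectors[, seq_len(k), drop = FALSE]
    X <- U %*% crossprod(U, X)
  }

  if (config$init == "random") {
    if (!is.null(config$seed)) set.seed(config$seed)
    W <- matrix(stats::rnorm(L * T_), L, T_)
  } else {
    W <- TPL %*% t(X)                      # dual-regression-style start
  }
  W <- W / sqrt(rowSums(W^2))

  S0 <- W %*% X                            # raw source rows, kept in sync
  terms0 <- eval_terms(W, X, TPL, Mw, config$contrast_fn)
  nrm <- iteration0_normalizers(W, X, TPL, Mw, config)
  aJ <- config$alpha / nrm["J"]
  bF <- config$beta / nrm["F"]
  gL <- config$gamma / nrm["L"]

  Jv <- terms0$J; Fv <- terms0$F
  sc_total <- function(W) {
    G <- tcrossprod(W)
    sum(Mw * (outer(diag(G), diag(G), "+") - 2 * G))
  }
  cost_now <- function() {
    unname(aJ * sum(Jv) + bF * sum(Fv) - gL * sc_total(W))
  }
  # per-component J/F from a raw source row
  jf_of <- function(s0, tpl) {
    m <- mean(s0); sdv <- sqrt(mean((s0 - m)^2))
    if (sdv < 1e-12) return(list(J = 0, F = 0, s = NULL, sd = sdv))
    s <- (s0 - m) / sdv
    list(J = (mean(cs$G(s)) - cs$EGnu)^2, F = mean(tpl * s), s = s, sd = sdv)
  }

  cost_trace <- cost_now()
  term_traces <- matrix(c(sum(Jv), sum(Fv), sc_total(W)), 1L, 3L,
                        dimnames = list(NULL, c("J", "F", "L")))
  converged <- FALSE
  n_iter <- 0L

  for (iter in seq_len(config$max_iter)) {
    n_iter <- iter
    # batched X-side gradient pieces; each w_l is unchanged until its own
    # turn in the sweep, so these are exact for the Gauss-Seidel update
    Umat <- matrix(0, V, L)
    sds <- numeric(L)
    Smat <- matrix(0, L, V)               # z-scored sources
    for (l in seq_len(L)) {
      st <- jf_of(S0[l, ], TPL[l, ])
      sds[l] <- st$sd
      if (is.null(st$s)) next
      Smat[l, ] <- st$s
      gs <- cs$g(st$s)
      Ghat <- mean(cs$G(st$s))
      uJ <- 2 * (Ghat - cs$EGnu) * (gs - mean(gs) - mean(gs * st$s) * st$s)
      uF <- TPL[l, ] - st$F * st$s
      Umat[, l] <- (aJ * uJ + bF * uF) / (V * st$sd)
    }
    GJF <- X %*% Umat                     # T x L: X-part of each gradient
    HX <- crossprod(GJF, X)               # L x V: (GJF_l)' X rows

    for (l in seq_len(L)) {
      if (sds[l] < 1e-12) next
      w <- W[l, ]
      msum <- sum(Mw[l, ])
      if (gamma_on) {
        cv <- 4 * gL * Mw[l, ]            # coefficients on rows of W
        scg <- msum * 4 * gL * w - drop(crossprod(W, cv))
        grad <- GJF[, l] - scg
      } else {
        cv <- numeric(L)
        grad <- GJF[, l]
      }
      gw <- sum(grad * w)
      grad <- grad - gw * w
      gn <- sqrt(sum(grad^2))
      if (gn < 1e-12) next
      d <- grad / gn
      # source row of d without a fresh matvec:
      #   d = (GJF_l + (cw - gw) w + W' cv) / gn,  cw = -4 gL msum
      cw <- if (gamma_on) -4 * gL * msum else 0
      s0d <- (HX[l, ] + (cw - gw) * S0[l, ] + drop(cv %*% S0)) / gn
      Wd <- drop(W %*% d)
      Ww <- drop(W %*% w)
      # current per-component objective (SC pairs counted twice: both
      # appearances of w_l in the total)
      sc0 <- sum(Mw[l, ] * (2 - 2 * Ww))
      phi0 <- aJ * Jv[l] + bF * Fv[l] - 2 * gL * sc0
      mu <- config$mu0
      accepted <- FALSE
      for (bt in seq_len(config$max_backtracks)) {
        r <- sqrt(1 + mu^2)               # <d, w> = 0 on the tangent space
        s0t <- (S0[l, ] + mu * s0d) / r
        st <- jf_of(s0t, TPL[l, ])
        qt <- (Ww + mu * Wd) / r
        qt[l] <- 1
        sct <- sum(Mw[l, ] * (2 - 2 * qt))
        phit <- aJ * st$J + bF * st$F - 2 * gL * sct
        if (phit >= phi0 + config$armijo_c * mu * gn) {
          W[l, ] <- (w + mu * d) / r
          S0[l, ] <- s0t
          Jv[l] <- st$J; Fv[l] <- st$F
          accepted <- TRUE
          break
        }
        mu <- mu * config$armijo_shrink
      }
      if (!accepted) next                 # step stall: keep w_l
    }
    C_new <- cost_now()
    cost_trace <- c(cost_trace, C_new)
    term_traces <- rbind(term_traces, c(sum(Jv), sum(Fv), sc_total(W)))
    C_prev <- cost_trace[length(cost_trace) - 1L]
    if (abs(C_new - C_prev) / max(abs(C_prev), 1e-12) < config$tol) {
      converged <- TRUE
      break
    }
  }

  # resolve sign ambiguity: template correlation >= 0 per component
  flip <- Fv < 0
  if (any(flip)) {
    W[flip, ] <- -W[flip, , drop = FALSE]
    Fv[flip] <- -Fv[flip]
  }

  nm <- if (inherits(template, "sfcica_template")) template$names
        else paste0("ICN", seq_len(L))
  rownames(W) <- nm
  S <- W %*% X
  structure(
    list(W = W, S = S, cost_trace = cost_trace, term_traces = term_traces,
         converged = converged, n_iter = n_iter, normalizers = nrm,
         template_corr = Fv, config = config,
         subject_id = if (inherits(data, "sfcica_subject")) data$subject_id
                      else "subject",
         names = nm),
    class = "sfcica_fit")
}

#' @export
print.sfcica_fit <- function(x, ...) {
  cat(sprintf(
    "<sfcica_fit> %s: %d components x %d time points, %d iterations (%s)\n",
    x$subject_id, nrow(x$W), ncol(x$W), x$n_iter,
    if (x$converged) "converged" else "not converged"))
  cat(sprintf("  final cost %.6g, mean template correlation %.3f\n",
              x$cost_trace[length(x$cost_trace)], mean(x$template_corr)))
  invisible(x)
}

#' Fit a list of subjects
#'
#' Independent per-subject fits, order preserving. `template` and `M` may be
#' single objects shared across subjects or lists with one entry per
#' subject.
#'
#' @param subjects list of `sfcica_subject`.
#' @param template shared template or list of templates.
#' @param M shared structural matrix, list of matrices, or `NULL`.
#' @param config `sfcica_config`.
#' @return list of `sfcica_fit`, one per subject.
#' @export
fit_dataset <- function(subjects, template, M = NULL,
                        config = sfcica_config()) {
  n <- length(subjects)
  tpl_list <- if (inherits(template, "sfcica_template") ||
                  is.matrix(template)) rep(list(template), n) else template
  M_list <- if (is.null(M) || inherits(M, "sfcica_sc") || is.matrix(M))
    rep(list(M), n) else M
  if (length(tpl_list) != n) stop("one template (or one per subject) required")
  if (length(M_list) != n) stop("one structural matrix (or one per subject) required")
  lapply(seq_len(n), function(i)
    fit_subject(subjects[[i]], tpl_list[[i]], M_list[[i]], config))
}
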