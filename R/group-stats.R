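#' Paired t-test
#'
#' Classical paired t on the differences `x - y`: tests whether the mean
#' paired difference is zero, two-sided, with n-1 degrees of freedom.
#' Implemented from the closed form; degenerate (zero-variance) differences
#' are an error rather than an infinite statistic.
#'
#' @param x,y equal-length numeric vectors of paired observations
#'   (length >= 3).
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors differ in length")
  n <- length(x)
  if (n < 3L) stop("need at least three pairs")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d < 1e-12) stop("degenerate pairs (zero-variance differences)")
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       df = n - 1L, mean_diff = mean(d))
}

#' Diagnosis effect from a covariate-adjusted GLM
#'
#' Ordinary least squares of a per-subject scalar response on diagnosis plus
#' the covariates present in `covariates` (age, sex, motion as numeric;
#' site as a factor, one-hot with a reference level). Returns the t
#' statistic and two-sided p value of the diagnosis coefficient. With no
#' covariates this reduces exactly to the pooled two-sample t-test.
#'
#' @param response numeric vector, one value per subject.
#' @param covariates data frame with a `diagnosis` column (two levels, e.g.
#'   HC/SZ) and optionally `age`, `sex`, `site`, `motion`.
#' @return list with `t`, `p`, `estimate`, `df`.
#' @export
glm_group_difference <- function(response, covariates) {
  covariates <- as.data.frame(covariates)
  if (is.null(covariates$diagnosis)) stop("covariates must include diagnosis")
  if (length(response) != nrow(covariates))
    stop("response and covariates differ in length")
  if (stats::sd(response) < 1e-12)
    stop("degenerate response (zero variance)")
  df <- covariates
  df$diagnosis <- factor(df$diagnosis)
  if (nlevels(df$diagnosis) != 2L) stop("diagnosis must have two levels")
  if (!is.null(df$site)) df$site <- factor(df$site)
  keep <- intersect(c("age", "sex", "site", "motion", "diagnosis"),
                    names(df))
  df <- df[, keep, drop = FALSE]
  df$.y <- response
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  row <- grep("^diagnosis", rownames(sm))
  list(t = unname(sm[row, "t value"]), p = unname(sm[row, "Pr(>|t|)"]),
       estimate = unname(sm[row, "Estimate"]),
       df = fit$df.residual)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone-enforced cumulative minimum) and the
#' significance mask at `q_level`.
#'
#' @param p vector of p values in (0, 1].
#' @param q_level FDR level for the mask (default 0.05).
#' @return list with `q` (adjusted values) and `significant` (logical mask).
#' @export
fdr_bh <- function(p, q_level = 0.05) {
  if (length(p) == 0L) return(list(q = numeric(0), significant = logical(0)))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q < q_level)
}

signed_logp <- function(p, t) -log10(p) * sign(t)

#' Edgewise FNC group-difference analysis
#'
#' Runs [glm_group_difference()] on every upper-triangle FNC edge across
#' subjects, adjusts the edge family with Benjamini-Hochberg FDR, and
#' assembles symmetric display matrices of t values and signed
#' `-log10(p) * sign(t)`. Degenerate edges (zero variance across subjects)
#' are flagged and excluded from the FDR family.
#'
#' @param fnc_stack subjects x L x L array (or list of L x L FNC matrices).
#' @param covariates data frame as in [glm_group_difference()].
#' @param q_level FDR level (default 0.05).
#' @return list of class `sfcica_statmap`: `t_values`, `p_values`, `fdr_q`,
#'   `signed_logp` (symmetric L x L matrices), `significant` (logical L x L),
#'   `excluded_edges`, `n_significant`.
#' @export
edgewise_analysis <- function(fnc_stack, covariates, q_level = 0.05) {
  if (is.list(fnc_stack)) {
    L <- nrow(fnc_stack[[1]])
    arr <- array(NA_real_, c(length(fnc_stack), L, L))
    for (i in seq_along(fnc_stack)) arr[i, , ] <- as.matrix(fnc_stack[[i]])
    fnc_stack <- arr
  }
  n_sub <- dim(fnc_stack)[1]
  L <- dim(fnc_stack)[2]
  covariates <- as.data.frame(covariates)
  if (n_sub != nrow(covariates)) stop("subject count mismatch")
  dg <- table(factor(covariates$diagnosis))
  if (any(dg < 2L)) stop("need at least two subjects per diagnosis level")

  ut <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  tmat <- pmat <- matrix(NA_real_, L, L)
  excluded <- logical(nrow(ut))
  for (e in seq_len(nrow(ut))) {
    y <- fnc_stack[, ut[e, 1], ut[e, 2]]
    if (anyNA(y) || stats::sd(y) < 1e-12) {
      excluded[e] <- TRUE
      next
    }
    res <- glm_group_difference(y, covariates)
    tmat[ut[e, 1], ut[e, 2]] <- res$t
    pmat[ut[e, 1], ut[e, 2]] <- res$p
  }
  if (any(excluded))
    message(sprintf("%d degenerate edges excluded from the FDR family",
                    sum(excluded)))
  pvec <- pmat[upper.tri(pmat)]
  qvec <- rep(NA_real_, length(pvec))
  ok <- !is.na(pvec)
  adj <- fdr_bh(pvec[ok], q_level)
  qvec[ok] <- adj$q
  qmat <- matrix(NA_real_, L, L)
  qmat[upper.tri(qmat)] <- qvec

  sym <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; m }
  tmat <- sym(tmat); pmat <- sym(pmat); qmat <- sym(qmat)
  slp <- signed_logp(pmat, tmat)
  sig <- !is.na(qmat) & qmat < q_level
  structure(list(t_values = tmat, p_values = pmat, fdr_q = qmat,
                 signed_logp = slp, significant = sig,
                 excluded_edges = ut[excluded, , drop = FALSE],
                 n_significant = sum(sig[upper.tri(sig)], na.rm = TRUE),
                 q_level = q_level),
            class = "sfcica_statmap")
}

#' Voxelwise spatial-map group-difference analysis
#'
#' Per-voxel covariate-adjusted GLM over subjects, FDR across the voxel
#' family, and the percentage of voxels with uncorrected p < 0.05 per ICN
#' when a component assignment is supplied.
#'
#' @param map_stack subjects x V matrix of per-subject spatial map values
#'   (one component's maps, or all components' concatenated).
#' @param covariates data frame as in [glm_group_difference()].
#' @param q_level FDR level.
#' @param component_of optional length-V integer/factor assigning each voxel
#'   to an ICN; enables the per-ICN percent-significant summary. Components
#'   with no voxels get `NA`.
#' @return list of class `sfcica_statmap` with vectors `t_values`,
#'   `p_values`, `fdr_q`, `signed_logp`, `significant`, plus
#'   `percent_significant` per component (uncorrected p < 0.05).
#' @export
voxelwise_analysis <- function(map_stack, covariates, q_level = 0.05,
                               component_of = NULL) {
  map_stack <- as.matrix(map_stack)
  covariates <- as.data.frame(covariates)
  if (nrow(map_stack) != nrow(covariates)) stop("subject count mismatch")
  V <- ncol(map_stack)
  tv <- pv <- rep(NA_real_, V)
  for (v in seq_len(V)) {
    y <- map_stack[, v]
    if (stats::sd(y) < 1e-12) next
    res <- glm_group_difference(y, covariates)
    tv[v] <- res$t
    pv[v] <- res$p
  }
  qv <- rep(NA_real_, V)
  ok <- !is.na(pv)
  qv[ok] <- fdr_bh(pv[ok], q_level)$q
  pct <- NULL
  if (!is.null(component_of)) {
    component_of <- as.factor(component_of)
    pct <- vapply(levels(component_of), function(lv) {
      idx <- which(component_of == lv)
      if (length(idx) == 0L) return(NA_real_)
      100 * mean(pv[idx] < 0.05, na.rm = TRUE)
    }, numeric(1))
  }
  structure(list(t_values = tv, p_values = pv, fdr_q = qv,
                 signed_logp = signed_logp(pv, tv),
                 significant = !is.na(qv) & qv < q_level,
                 percent_significant = pct, q_level = q_level),
            class = "sfcica_statmap")
}
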