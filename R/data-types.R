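#' Build a standardized subject data object from a 4-D volume and mask
#'
#' Masks a 4-D fMRI array (x, y, z, time), linearizes the in-mask voxels in
#' column-major (x-fastest) order, and returns the time-by-voxel matrix with
#' every voxel series demeaned and variance-normalized. This is the canonical
#' input to [fit_subject()].
#'
#' Voxels with (numerically) constant series get a variance floor of `1e-12`
#' instead of dividing by zero; their indices are recorded in the
#' `degenerate_voxels` attribute and reported with a message.
#'
#' @param raw_4d numeric 4-D array, spatial dimensions matching `mask`.
#' @param mask logical 3-D array (or 2-D, which is treated as a single-slice
#'   volume); `TRUE` marks voxels to keep.
#' @param subject_id character label carried through fits and outputs.
#' @return An object of class `sfcica_subject` with elements `data`
#'   (T x V matrix), `mask`, `voxel_order` (linear indices into the volume),
#'   `subject_id`, and `dim` (spatial dimensions).
#' @export
standardize_subject <- function(raw_4d, mask, subject_id = "subject") {
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (length(dim(raw_4d)) == 3L) dim(raw_4d) <- c(dim(raw_4d)[1:2], 1L, dim(raw_4d)[3])
  dm <- dim(raw_4d)
  if (length(dm) != 4L) stop("raw_4d must be a 4-D array (x, y, z, time)")
  if (!identical(dm[1:3], dim(mask)))
    stop(sprintf("spatial dimensions of data (%s) and mask (%s) differ",
                 paste(dm[1:3], collapse = "x"),
                 paste(dim(mask), collapse = "x")))
  if (dm[4] < 2L) stop("need at least two time points")
  mask <- array(as.logical(mask), dim(mask))
  voxel_order <- which(mask)
  if (length(voxel_order) == 0L) stop("empty mask")

  nvox <- prod(dm[1:3])
  flat <- matrix(raw_4d, nrow = nvox, ncol = dm[4])   # voxels x time
  X <- t(flat[voxel_order, , drop = FALSE])           # time x voxels
  if (!all(is.finite(X))) stop("non-finite values in masked data")

  mu <- colMeans(X)
  X <- sweep(X, 2L, mu, "-")
  v <- colMeans(X^2)
  degenerate <- which(v < 1e-12)
  if (length(degenerate) > 0L)
    message(sprintf("variance floor applied to %d constant voxel series",
                    length(degenerate)))
  v[v < 1e-12] <- 1e-12
  X <- sweep(X, 2L, sqrt(v), "/")

  structure(
    list(data = X, mask = mask, voxel_order = voxel_order,
         subject_id = as.character(subject_id), dim = dm[1:3]),
    degenerate_voxels = degenerate,
    class = "sfcica_subject")
}

#' @export
print.sfcica_subject <- function(x, ...) {
  cat(sprintf("<sfcica_subject> %s: T=%d time points, V=%d voxels (%s volume)\n",
              x$subject_id, nrow(x$data), ncol(x$data),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Spatial template of prior ICN maps
#'
#' Wraps an L x V matrix of prior spatial maps (one row per intrinsic
#' connectivity network) and z-scores every map over voxels, so that the
#' template-similarity cost term equals the Pearson correlation between a
#' z-scored estimated map and the prior.
#'
#' @param maps numeric L x V matrix, rows in the same voxel linearization as
#'   the subject data they will be paired with.
#' @param names optional component labels (default `ICN1..ICNL`).
#' @param domains optional functional-domain tags (e.g. SC/AUD/SM/VS/CC/DM/CB).
#' @return `sfcica_template` object with z-scored `maps`, `names`, `domains`.
#' @export
spatial_template <- function(maps, names = NULL, domains = NULL) {
  maps <- as.matrix(maps)
  if (!all(is.finite(maps))) stop("non-finite values in template maps")
  L <- nrow(maps)
  maps <- t(apply(maps, 1L, zscore_pop))
  if (is.null(names)) names <- paste0("ICN", seq_len(L))
  if (length(names) != L) stop("need one name per template map")
  if (!is.null(domains) && length(domains) != L)
    stop("need one domain tag per template map")
  structure(list(maps = maps, names = as.character(names), domains = domains),
            class = "sfcica_template")
}

#' @export
print.sfcica_template <- function(x, ...) {
  cat(sprintf("<sfcica_template> %d maps x %d voxels\n",
              nrow(x$maps), ncol(x$maps)))
  invisible(x)
}

#' Structural connectivity weight matrix
#'
#' Validates an L x L matrix of streamline-count derived connectivity:
#' nonnegative, symmetric, zero diagonal. Weights are rescaled so the largest
#' off-diagonal entry is 1 (when any is nonzero); the raw counts are kept in
#' `raw_counts` for audit.
#'
#' @param counts square numeric matrix of streamline counts (or already
#'   normalized weights).
#' @param names optional node labels.
#' @return `sfcica_sc` object with `weights` (max-rescaled), `raw_counts`,
#'   `names`.
#' @export
structural_matrix <- function(counts, names = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("structural matrix must be square")
  if (any(!is.finite(counts))) stop("non-finite structural weights")
  if (any(counts < 0)) stop("negative structural weights")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts))))
    stop("structural matrix is not symmetric")
  counts <- (counts + t(counts)) / 2
  diag(counts) <- 0
  w <- counts
  mx <- max(w)
  if (mx > 0) w <- w / mx
  if (is.null(names)) names <- paste0("ICN", seq_len(nrow(w)))
  dimnames(w) <- list(names, names)
  structure(list(weights = w, raw_counts = counts, names = as.character(names)),
            class = "sfcica_sc")
}

#' @export
print.sfcica_sc <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<sfcica_sc> %d nodes, %d nonzero connections (max weight 1)\n",
              nrow(x$weights), nz))
  invisible(x)
}

# population z-score (divide by sqrt of mean squared deviation); constant
# vectors come back as zeros rather than NaN
zscore_pop <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s < 1e-12) return(x * 0)
  x / s
}

as_sc_weights <- function(M, L) {
  if (is.null(M)) return(matrix(0, L, L))
  if (inherits(M, "sfcica_sc")) M <- M$weights
  M <- as.matrix(M)
  if (!all(dim(M) == c(L, L)))
    stop(sprintf("structural matrix is %dx%d but %d components expected",
                 nrow(M), ncol(M), L))
  M
}
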