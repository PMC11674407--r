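#' Read a 4-D NIfTI time series
#'
#' @param path NIfTI-1/2 file.
#' @return list with `data` (4-D array), `affine` (4 x 4 xform matrix) and
#'   `header` (pixdim and dim summary). Voxel linearization used downstream
#'   is x-fastest over mask-true voxels.
#' @export
read_nifti_series <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L)
    stop("expected a 4-D series, got a 3-D volume: ", path)
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D series, got ", length(dim(arr)), "-D: ", path)
  list(data = arr, affine = RNifti::xform(img),
       header = list(dim = dim(arr), pixdim = RNifti::pixdim(img)))
}

#' Read a 3-D NIfTI mask
#'
#' @param path NIfTI file; nonzero voxels are in-mask.
#' @return logical 3-D array.
#' @export
read_nifti_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stop("mask must be a 3-D volume: ", path)
  array(arr != 0, dim(arr))
}

#' Write a numeric array as NIfTI (float32 on disk)
#' @param arr 3-D or 4-D array.
#' @param path output file.
#' @export
write_nifti <- function(arr, path) {
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  invisible(path)
}

#' Read a structural connectivity matrix from CSV/TSV
#'
#' Accepts a square numeric table, with or without a header row/column of
#' component names. The matrix is validated (no negative entries),
#' symmetrized when the asymmetry is below `1e-8` of the largest entry
#' (an error otherwise), and max-rescaled via [structural_matrix()]; raw
#' counts are preserved.
#'
#' @param path CSV (comma) or TSV (tab) file; the delimiter is inferred
#'   from the extension (default comma).
#' @return `sfcica_sc`.
#' @export
read_sc_matrix <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(
    cells[nchar(trimws(cells)) > 0]))))
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           row.names = if (has_header) 1L else NULL,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) stop("structural matrix file is not square: ",
                               nrow(m), "x", ncol(m))
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-numeric entries in ", path)
  nm <- if (has_header) colnames(m) else NULL
  structural_matrix(m, names = nm)
}

#' Write a structural connectivity (or any square) matrix as CSV
#' @param x `sfcica_sc`, or square matrix.
#' @param path output CSV.
#' @param raw write raw counts instead of rescaled weights.
#' @export
write_sc_matrix <- function(x, path, raw = FALSE) {
  m <- if (inherits(x, "sfcica_sc")) {
    if (raw) x$raw_counts else x$weights
  } else as.matrix(x)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Write one subject's fit: spatial maps (NIfTI), time courses (CSV),
#' cost traces and convergence (JSON sidecar)
#'
#' Spatial maps are z-scored per component and written as one 4-D NIfTI
#' volume (one volume per component) over the subject's mask; time courses
#' as a T x L CSV; the sidecar echoes the configuration, per-iteration cost
#' and term traces, normalizers and convergence flags.
#'
#' @param fit `sfcica_fit`.
#' @param subject the `sfcica_subject` the fit came from (for mask/voxel
#'   order).
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_fit_result <- function(fit, subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- fit$subject_id
  L <- nrow(fit$W)
  dm <- subject$dim
  arr <- array(0, c(dm, L))
  flat <- matrix(0, prod(dm), L)
  for (l in seq_len(L))
    flat[subject$voxel_order, l] <- zscore_pop(fit$S[l, ])
  arr <- array(flat, c(dm, L))
  maps_path <- file.path(dir, paste0(id, "_maps.nii.gz"))
  write_nifti(arr, maps_path)
  tc_path <- file.path(dir, paste0(id, "_timecourses.csv"))
  tc <- t(fit$W)
  colnames(tc) <- fit$names
  utils::write.csv(tc, tc_path, row.names = FALSE)
  side_path <- file.path(dir, paste0(id, "_fit.json"))
  side <- list(subject_id = id, converged = fit$converged,
               n_iter = fit$n_iter, cost_trace = fit$cost_trace,
               term_traces = as.data.frame(fit$term_traces),
               normalizers = as.list(fit$normalizers),
               template_corr = fit$template_corr,
               config = fit$config[setdiff(names(fit$config), "seed")])
  jsonlite::write_json(side, side_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(maps_path, tc_path, side_path))
}

#' Read a run configuration (YAML or JSON)
#'
#' Fills defaults for missing blocks and, when `check_paths` is on,
#' validates that every referenced input path exists.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param check_paths validate referenced input files exist (default TRUE).
#' @return nested list of class `sfcica_run_config`.
#' @export
read_run_config <- function(path, check_paths = TRUE) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_run_config(cfg, check_paths = check_paths)
}

#' @rdname read_run_config
#' @param cfg a nested list following the same structure as the file format.
#' @export
as_run_config <- function(cfg, check_paths = TRUE) {
  defaults <- list(
    seed = 1L, baseline = FALSE, out = "sfcica_out",
    simulate = NULL, paths = NULL,
    optimizer = list(), metrics = list(threshold = "auto", n_null = 100L),
    stats = list(q_level = 0.05, covariates = NULL))
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$optimizer <- do.call(sfcica_config,
                           cfg$optimizer[names(cfg$optimizer) %in%
                                           names(formals(sfcica_config))])
  if (is.null(cfg$simulate) && is.null(cfg$paths))
    stop("config needs either a 'simulate' block or a 'paths' block")
  if (check_paths && !is.null(cfg$paths)) {
    for (k in c("data", "mask", "template", "sc")) {
      for (p in cfg$paths[[k]])
        if (!is.null(p) && !file.exists(p))
          stop("input path does not exist: ", p)
    }
  }
  structure(cfg, class = "sfcica_run_config")
}
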