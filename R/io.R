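#' Load datasets from matrix files or a masked 4-D volume
#'
#' Two input styles are supported. (1) Delimited text matrices (whitespace,
#' comma, or tab separated; one file per dataset) loaded as-is with rows as
#' observations and columns as samples, or transposed when
#' `samples_axis = "rows"` — orientation is always explicit, never guessed.
#' (2) 4-D NIfTI volumes (one per subject) with a binary brain mask on the
#' same grid: each volume is masked and flattened so voxels become samples
#' and time points become observations, the spatial-decomposition
#' convention for fMRI. All datasets must share the sample count `T`.
#'
#' @param paths Character vector of file paths (text matrices or 4-D
#'   NIfTI volumes).
#' @param mask_path Optional path to a NIfTI mask; its nonzero voxels
#'   select the columns. Required for volumetric input.
#' @param samples_axis `"columns"` (default) if samples vary along columns
#'   of the text matrices, `"rows"` to transpose on load.
#' @return A `dataset_stack`.
#' @export
load_datasets <- function(paths, mask_path = NULL,
                          samples_axis = c("columns", "rows")) {
  samples_axis <- match.arg(samples_axis)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  is_nifti <- grepl("\\.nii(\\.gz)?$", paths, ignore.case = TRUE)
  X <- if (all(is_nifti)) {
    if (is.null(mask_path))
      stop("volumetric input requires `mask_path`")
    if (!file.exists(mask_path)) stop("mask file not found: ", mask_path)
    mask <- as.array(RNifti::readNifti(mask_path)) != 0
    lapply(paths, function(p) {
      vol <- as.array(RNifti::readNifti(p))
      if (length(dim(vol)) != 4L)
        stop("expected a 4-D volume in ", p, ", got ",
             length(dim(vol)), "-D")
      if (!identical(dim(vol)[1:3], dim(mask)))
        stop("mask grid ", paste(dim(mask), collapse = "x"),
             " does not match volume grid ",
             paste(dim(vol)[1:3], collapse = "x"), " for ", p)
      nt <- dim(vol)[4]
      flat <- matrix(vol, ncol = nt)      # voxels x time
      t(flat[as.vector(mask), , drop = FALSE])  # time x voxels
    })
  } else if (any(is_nifti)) {
    stop("cannot mix NIfTI and text matrix inputs")
  } else {
    lapply(paths, function(p) {
      M <- as.matrix(data.table::fread(p, header = FALSE))
      storage.mode(M) <- "double"
      dimnames(M) <- NULL
      if (samples_axis == "rows") t(M) else M
    })
  }
  Ts <- vapply(X, ncol, integer(1))
  if (length(unique(Ts)) != 1L)
    stop("datasets disagree on sample count T: ",
         paste(unique(Ts), collapse = ", "))
  Ns <- vapply(X, nrow, integer(1))
  if (length(unique(Ns)) != 1L)
    stop("datasets disagree on observation count: ",
         paste(unique(Ns), collapse = ", "))
  structure(list(X = X, N = Ns[1], K = length(X), T = Ts[1]),
            class = "dataset_stack")
}

#' Write a numeric matrix as tab-separated text
#'
#' @param M Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path) {
  data.table::fwrite(as.data.frame(M), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a simulation config from JSON
#'
#' Keys are the [sim_config()] fields (`n_sources`, `n_datasets`,
#' `n_shared`, optionally `n_samples`, `mu_lo`, `mu_hi`, `beta`, `seed`).
#'
#' @param path Path to a JSON file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("n_sources", "n_datasets", "n_shared", "n_samples",
               "mu_lo", "mu_hi", "beta", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, cfg)
}

# version string recorded in reports
.pkg_version <- function() {
  as.character(utils::packageVersion("ivas3"))
}

#' Save a decomposition result to a directory
#'
#' Writes one source matrix and one demixing matrix per dataset
#' (tab-separated text), a JSON report (spectral gap ratios, partition,
#' cost traces, iteration counts, threshold, seed, package version), and a
#' manifest listing every written file with an MD5 checksum. Two runs with
#' the same data, seed, and settings produce identical checksums.
#'
#' @param result An `iva_s3_result` or `ivag_result`.
#' @param dir Output directory (created if needed).
#' @param seed Seed to echo into the report, if any.
#' @param sources For an `ivag_result`, the estimated sources to write
#'   (list of matrices from [apply_demixing()]); ignored for
#'   `iva_s3_result`, which carries its own.
#' @return The manifest as a data frame (`file`, `md5`), invisibly.
#' @export
save_results <- function(result, dir, seed = NULL, sources = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)
  put <- function(rel, writer) {
    p <- file.path(dir, rel)
    writer(p)
    files <<- c(files, rel)
  }
  if (inherits(result, "iva_s3_result")) {
    W <- result$total_demixing
    Y <- result$final_sources
    report <- list(
      method = "ivas3",
      sigma = result$sigma,
      threshold = result$threshold,
      shared_idx = result$partition$shared_idx,
      nonshared_idx = result$partition$nonshared_idx,
      row_map = result$row_map,
      stage1 = list(n_iter = result$stage1$n_iter,
                    converged = result$stage1$converged,
                    cost_trace = result$stage1$cost_trace),
      stage3_shared = if (is.null(result$stage3_shared)) NULL else
        list(n_iter = result$stage3_shared$n_iter,
             converged = result$stage3_shared$converged,
             cost_trace = result$stage3_shared$cost_trace),
      stage3_nonshared = if (is.null(result$stage3_nonshared)) NULL else
        list(n_iter = result$stage3_nonshared$n_iter,
             converged = result$stage3_nonshared$converged,
             cost_trace = result$stage3_nonshared$cost_trace),
      seed = seed, version = .pkg_version())
  } else if (inherits(result, "ivag_result")) {
    W <- result$demixing
    Y <- sources
    report <- list(
      method = "ivag",
      n_iter = result$n_iter, converged = result$converged,
      cost_trace = result$cost_trace,
      seed = seed, version = .pkg_version())
  } else stop("`result` must be an iva_s3_result or ivag_result")
  for (k in seq_len(W$K)) {
    put(sprintf("demixing_%03d.tsv", k),
        function(p) write_matrix(W$W[[k]], p))
    if (!is.null(Y))
      put(sprintf("sources_%03d.tsv", k),
          function(p) write_matrix(Y[[k]], p))
  }
  put("report.json", function(p)
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
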