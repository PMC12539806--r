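# Label images are stored 16-bit: TIFF pages hold label/65535 directly; PNG
# slices encode the label in the red (high byte) and green (low byte)
# channels. Both round-trip integer labels up to 65535 exactly.

label_to_tiff <- function(sl) sl / 65535
tiff_to_label <- function(pg) {
  if (length(dim(pg)) == 3) pg <- pg[, , 1]
  matrix(as.integer(round(pg * 65535)), nrow(pg), ncol(pg))
}
label_to_png <- function(sl) {
  arr <- array(0, c(nrow(sl), ncol(sl), 3))
  arr[, , 1] <- (sl %/% 256L) / 255
  arr[, , 2] <- (sl %% 256L) / 255
  arr
}
png_to_label <- function(img) {
  if (length(dim(img)) == 2)
    return(matrix(as.integer(round(img * 65535)), nrow(img), ncol(img)))
  matrix(as.integer(round(img[, , 1] * 255)) * 256L +
           as.integer(round(img[, , 2] * 255)), nrow(img), ncol(img))
}

#' Write a label volume to disk
#'
#' Either a single multi-page 16-bit TIFF, or a directory of PNG slices with
#' zero-padded names (`slice_0001.png`, ...). Labels must be below 65536.
#'
#' @param vol a [label_volume()].
#' @param path output file (TIFF) or directory (PNG).
#' @param format `"tiff"` or `"png"`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path, format = c("tiff", "png")) {
  stopifnot(inherits(vol, "label_volume"))
  format <- match.arg(format)
  stop_if(max(vapply(vol$slices, max, numeric(1))) > 65535,
          "labels above 65535 cannot be stored")
  if (format == "tiff") {
    tiff::writeTIFF(lapply(vol$slices, label_to_tiff), path,
                    bits.per.sample = 16L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (z in seq_along(vol$slices)) {
      png::writePNG(label_to_png(vol$slices[[z]]),
                    file.path(path, sprintf("slice_%04d.png", z)))
    }
  }
  invisible(path)
}

#' Read a label stack from disk
#'
#' `path` is a multi-page TIFF file or a directory of PNG slices ordered by
#' zero-padded filename. PNG directories are checked for a contiguous slice
#' numbering; gaps are an error.
#'
#' @param path TIFF file or PNG directory.
#' @param pixel_size,z_spacing physical calibration in nm.
#' @param region optional inclusive slice range.
#' @return a [label_volume()].
#' @export
read_label_stack <- function(path, pixel_size, z_spacing, region = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    stop_if(length(files) == 0, sprintf("no PNG slices found in %s", path))
    idx <- suppressWarnings(as.integer(sub("^.*?(\\d+)\\.png$", "\\1",
                                           basename(files))))
    stop_if(any(is.na(idx)), "PNG slice filenames must carry a slice index")
    expect <- seq(min(idx), max(idx))
    missing_ <- setdiff(expect, idx)
    stop_if(length(missing_) > 0,
            sprintf("missing slice index(es): %s",
                    paste(missing_, collapse = ",")))
    slices <- lapply(files[order(idx)], function(f) png_to_label(png::readPNG(f)))
  } else {
    stop_if(!file.exists(path), sprintf("no such file: %s", path))
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    slices <- lapply(pages, tiff_to_label)
  }
  shp <- dim(slices[[1]])
  for (i in seq_along(slices)) {
    stop_if(!identical(dim(slices[[i]]), shp),
            sprintf("slice %d shape (%s) differs from slice 1 (%s)",
                    i, paste(dim(slices[[i]]), collapse = "x"),
                    paste(shp, collapse = "x")))
  }
  label_volume(slices, pixel_size = pixel_size, z_spacing = z_spacing,
               region = region)
}

#' Write an adjacency matrix as labeled CSV
#'
#' @param A labeled symmetric matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(A, path) {
  validate_adjacency(A)
  utils::write.csv(as.data.frame(A), path, row.names = TRUE)
  invisible(path)
}

#' Read a labeled adjacency matrix
#'
#' Reads a square CSV table with matching row and column label sets;
#' columns are realigned to the row order by label, so label-keyed files
#' with permuted columns load correctly. Relative asymmetries above 1e-6
#' are an error; smaller ones are symmetrized by the mean with a logged
#' notice. XLSX input is not supported; convert to CSV.
#'
#' @param path CSV file path.
#' @return labeled symmetric matrix with zero diagonal preserved as stored.
#' @export
read_adjacency <- function(path) {
  stop_if(grepl("\\.xlsx?$", path, ignore.case = TRUE),
          "XLSX input is not supported; export the sheet as CSV")
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  A <- as.matrix(df)
  stop_if(!is.numeric(A), "adjacency CSV must be numeric")
  stop_if(nrow(A) != ncol(A), "adjacency CSV must be square")
  stop_if(anyDuplicated(rownames(A)) > 0, "duplicate row labels")
  stop_if(anyDuplicated(colnames(A)) > 0, "duplicate column labels")
  stop_if(!setequal(rownames(A), colnames(A)),
          "row and column label sets must match")
  A <- A[, rownames(A), drop = FALSE]   # realign columns by label
  stop_if(any(A < 0), "negative adjacency entries")
  rel <- max(abs(A - t(A))) / max(1, max(abs(A)))
  stop_if(rel > 1e-6,
          sprintf("asymmetry above tolerance (relative %.3g)", rel))
  if (rel > 0) {
    ctm_warn("CTM_SYMMETRIZED",
             sprintf("input symmetrized by mean (relative asymmetry %.3g)", rel))
    A <- (A + t(A)) / 2
  }
  A
}

#' Pipeline run configuration
#'
#' Bundles the calibration and algorithm parameters of a full run; every
#' parameter defaults to the standard analysis values (epsilon divisor
#' 10000, C-PHATE lag weights 100 and 30, diffusion time 50, seed 1,
#' threshold 45 nm).
#'
#' @param dataset dataset name.
#' @param pixel_size,z_spacing calibration in nm.
#' @param region optional inclusive slice range.
#' @param threshold_nm adjacency distance threshold in nm.
#' @param epsilon_divisor,max_iterations,sigma_growth condensation
#'   parameters (see [condensation_params()]).
#' @param w1,w2 C-PHATE lag weights.
#' @param diffusion_time,seed embedding parameters.
#' @param out_dir output directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(dataset = "dataset",
                       pixel_size = 4.5, z_spacing = 30, region = NULL,
                       threshold_nm = 45,
                       epsilon_divisor = 10000, max_iterations = 1000L,
                       sigma_growth = 1.1,
                       w1 = 100, w2 = 30, diffusion_time = 50, seed = 1L,
                       out_dir = ".") {
  stop_if(pixel_size <= 0 || z_spacing <= 0 || threshold_nm <= 0,
          "physical quantities must be positive")
  structure(list(dataset = dataset, pixel_size = pixel_size,
                 z_spacing = z_spacing, region = region,
                 threshold_nm = threshold_nm,
                 epsilon_divisor = epsilon_divisor,
                 max_iterations = as.integer(max_iterations),
                 sigma_growth = sigma_growth,
                 w1 = w1, w2 = w2, diffusion_time = diffusion_time,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration file
#'
#' YAML is the primary format with JSON as a fallback; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML or JSON file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  stop_if(length(unknown) > 0,
          sprintf("unknown config key(s): %s", paste(unknown, collapse = ",")))
  do.call(run_config, vals)
}

#' Write a condensation trace as JSON
#'
#' Per-iteration assignments, cluster counts, modularity and sigma, plus
#' epsilon and the convergence flag.
#'
#' @param trace a [run_condensation()] trace.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "condensation_trace"))
  obj <- list(
    labels = trace$labels,
    epsilon = trace$epsilon,
    converged = trace$converged,
    iterations = lapply(trace$iterations, function(itr)
      list(iteration = itr$iteration,
           n_clusters = itr$n_clusters,
           modularity = itr$modularity,
           sigma = if (is.finite(itr$sigma)) itr$sigma else NULL,
           assignment = as.list(itr$assignment))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a condensation trace from JSON
#'
#' @param path JSON file written by [write_trace_json()].
#' @return a `condensation_trace`.
#' @export
read_trace_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  iters <- lapply(obj$iterations, function(itr) {
    assign <- unlist(itr$assignment)
    list(iteration = as.integer(itr$iteration),
         assignment = stats::setNames(as.integer(assign), names(assign)),
         n_clusters = as.integer(itr$n_clusters),
         modularity = as.numeric(itr$modularity),
         sigma = if (is.null(itr$sigma) || !is.numeric(itr$sigma))
           NA_real_ else as.numeric(itr$sigma))
  })
  structure(list(iterations = iters,
                 epsilon = as.numeric(obj$epsilon),
                 labels = unlist(obj$labels),
                 converged = isTRUE(obj$converged)),
            class = "condensation_trace")
}
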