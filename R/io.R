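# Dataset and report serialization.
#
# EEG datasets are written as per-split NPY arrays plus a JSON sidecar
# (channel names, sampling rate, subject/category/image ids). The NPY
# writer/reader below covers the little-endian float64 C-order subset used
# here; no installed R package provides the format.

npy_header <- function(shape) {
  dict <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%s), }",
                  paste0(paste(shape, collapse = ", "),
                         if (length(shape) == 1L) "," else ""))
  base <- 10L # magic(6) + version(2) + header-length(2)
  pad <- 64L - ((base + nchar(dict) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  paste0(dict, strrep(" ", pad), "\n")
}

#' Write / read a numeric array as NPY
#'
#' Little-endian float64, C (row-major) order, NPY format version 1.0 -
#' directly loadable with Python's numpy.
#'
#' @param x Numeric vector, matrix or array.
#' @param path File path.
#' @return `read_npy` returns the array (with dimensions restored).
#' @export
write_npy <- function(x, path) {
  shape <- dim(x) %||% length(x)
  # C order stores the last axis fastest; R arrays store the first fastest
  v <- if (length(shape) > 1L) as.vector(aperm(x, rev(seq_along(shape)))) else as.numeric(x)
  hdr <- npy_header(shape)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(hdr)), con, size = 2L, endian = "little")
  writeChar(hdr, con, eos = NULL)
  writeBin(v, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_npy
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59)))) {
    stop_arg("not an NPY file: ", path)
  }
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  hdr <- readChar(con, hlen, useBytes = TRUE)
  if (!grepl("'descr': '<f8'", hdr, fixed = TRUE) ||
      !grepl("'fortran_order': False", hdr, fixed = TRUE)) {
    stop_arg("unsupported NPY dtype/order (only <f8 C-order): ", hdr)
  }
  shape_str <- sub(".*'shape': \\(([^)]*)\\).*", "\\1", hdr)
  shape <- as.integer(strsplit(gsub("[ ]", "", shape_str), ",")[[1]])
  v <- readBin(con, "numeric", prod(shape), size = 8L, endian = "little")
  if (length(shape) <= 1L) {
    return(v)
  }
  aperm(array(v, rev(shape)), rev(seq_along(shape)))
}

#' Export / import a synthetic dataset as NPY + JSON sidecar
#'
#' Writes `train_eeg.npy`, `train_embeddings.npy`, `test_eeg.npy`,
#' `test_embeddings.npy` and `sidecar.json` (montage, sampling rate, ids,
#' configuration) into `dir`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `read_dataset_npy` returns a list with the same `train` / `test`
#'   structure (bank and forward model are not round-tripped).
#' @export
write_dataset_npy <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (split in c("train", "test")) {
    write_npy(dataset[[split]]$eeg, file.path(dir, paste0(split, "_eeg.npy")))
    write_npy(dataset[[split]]$embeddings,
              file.path(dir, paste0(split, "_embeddings.npy")))
  }
  sidecar <- list(
    channel_names = dataset$fm$channel_names,
    sampling_rate = dataset$fm$sampling_rate,
    config = dataset$config,
    train_meta = dataset$train$meta,
    test_meta = dataset$test$meta
  )
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset_npy
#' @export
read_dataset_npy <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                                 simplifyVector = TRUE)
  out <- list(channel_names = sidecar$channel_names,
              sampling_rate = sidecar$sampling_rate,
              config = sidecar$config)
  for (split in c("train", "test")) {
    out[[split]] <- list(
      eeg = read_npy(file.path(dir, paste0(split, "_eeg.npy"))),
      embeddings = read_npy(file.path(dir, paste0(split, "_embeddings.npy"))),
      meta = sidecar[[paste0(split, "_meta")]]
    )
  }
  out
}

#' Write a retrieval / CAT / Frechet report as JSON
#'
#' @param report Any of the package's report objects (lists).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
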