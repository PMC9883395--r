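#' Spectral dataset container
#'
#' Bundles an intensity matrix (one row per spectrum, one column per grid
#' point) with per-spectrum metadata and the shared wavenumber grid. The
#' metadata carries the acquisition hierarchy (mouse, tumour section, Raman
#' map) used by subject-wise validation.
#'
#' @param grid a [wavenumber_grid()].
#' @param intensities numeric matrix, `n_spectra x grid$n_points`.
#' @param meta data.frame with columns `dose_gy`, `day`, `mouse_id`,
#'   `section_id`, `map_id`, `spectrum_index`, `label`.
#' @return an object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(grid, intensities, meta) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != grid$n_points) {
    stop("intensity matrix has ", ncol(intensities),
         " columns but grid has ", grid$n_points, " points", call. = FALSE)
  }
  required <- c("dose_gy", "day", "mouse_id", "section_id", "map_id",
                "spectrum_index", "label")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(meta) != nrow(intensities)) {
    stop("metadata rows (", nrow(meta), ") != spectra (",
         nrow(intensities), ")", call. = FALSE)
  }
  key <- paste(meta$mouse_id, meta$section_id, meta$map_id,
               meta$spectrum_index)
  if (anyDuplicated(key)) {
    stop("duplicate (mouse_id, section_id, map_id, spectrum_index) keys",
         call. = FALSE)
  }
  bad <- xor(meta$label == "nonirradiated", meta$dose_gy == 0)
  if (any(bad)) {
    stop("label/dose mismatch: 'nonirradiated' iff dose_gy == 0",
         call. = FALSE)
  }
  structure(list(grid = grid, intensities = intensities,
                 meta = as.data.frame(meta, stringsAsFactors = FALSE)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(paste0("<spectral_dataset> %d spectra x %d points, doses {%s} ",
                     "Gy, %d mice\n"),
              nrow(x$intensities), x$grid$n_points,
              paste(sort(unique(x$meta$dose_gy)), collapse = ", "),
              length(unique(x$meta$mouse_id))))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensities)

#' Subset a spectral dataset by spectrum index
#'
#' @param ds a `spectral_dataset`.
#' @param idx integer or logical index into the spectra (rows).
#' @return the subsetted `spectral_dataset`.
#' @export
subset_spectra <- function(ds, idx) {
  stopifnot(inherits(ds, "spectral_dataset"))
  spectral_dataset(ds$grid, ds$intensities[idx, , drop = FALSE],
                   ds$meta[idx, , drop = FALSE])
}

#' Hierarchy unit identifiers
#'
#' Builds the composite identifier of each spectrum's mouse, tumour section
#' or Raman map, the units held out together in subject-wise validation.
#'
#' @param ds a `spectral_dataset`.
#' @param level one of `"mouse"`, `"section"`, `"map"`.
#' @return character vector, one identifier per spectrum.
#' @export
unit_ids <- function(ds, level = c("mouse", "section", "map")) {
  level <- match.arg(level)
  m <- ds$meta
  switch(level,
         mouse   = as.character(m$mouse_id),
         section = paste(m$mouse_id, m$section_id, sep = "."),
         map     = paste(m$mouse_id, m$section_id, m$map_id, sep = "."))
}

#' Class labels as a factor
#'
#' @param ds a `spectral_dataset`.
#' @return factor with levels `c("nonirradiated", "irradiated")` (the
#'   positive, irradiated class second).
#' @export
class_labels <- function(ds) {
  factor(ds$meta$label, levels = c("nonirradiated", "irradiated"))
}

#' Write / read a dataset as a delimited-text pair
#'
#' The spectra file is tab-separated with a header row of wavenumbers; the
#' metadata file carries the hierarchy columns. The round trip is lossless to
#' full double precision (values are written with 17 significant digits).
#'
#' @param ds a `spectral_dataset`.
#' @param spectra_file,meta_file output/input paths.
#' @return `write_dataset` returns `invisible(ds)`; `read_dataset` returns
#'   the reconstructed `spectral_dataset`.
#' @export
write_dataset <- function(ds, spectra_file, meta_file) {
  stopifnot(inherits(ds, "spectral_dataset"))
  mat <- ds$intensities
  con <- file(spectra_file, "w")
  on.exit(close(con))
  writeLines(paste(formatC(ds$grid$wavenumbers, digits = 17, format = "g"),
                   collapse = "\t"), con)
  apply_fmt <- function(row) {
    paste(formatC(row, digits = 17, format = "g"), collapse = "\t")
  }
  writeLines(vapply(seq_len(nrow(mat)),
                    function(i) apply_fmt(mat[i, ]), character(1)), con)
  write.table(ds$meta, meta_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ds)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(spectra_file, meta_file) {
  lines <- readLines(spectra_file)
  wn <- as.numeric(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
  mat <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  grid <- wavenumber_grid(wn[1], wn[length(wn)], length(wn))
  meta <- read.delim(meta_file, stringsAsFactors = FALSE)
  spectral_dataset(grid, mat, meta)
}
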