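#' Canopy spectrum collection
#'
#' A `spectra` object holds a set of curves sampled on one shared wavelength
#' grid: a samples-by-wavelengths value matrix, the grid in nm, the curve
#' kind (`"reflectance"` or `"derivative"`), and per-sample metadata
#' (treatment, growth stage, plot, scan number).
#'
#' Reflectance values are stored as unitless fractions in [0, 1]; derivative
#' curves are in reflectance units per nm. The default acquisition grid is
#' 350--1075 nm at 1 nm steps (726 points).
#'
#' @param values numeric matrix, one row per sample, one column per wavelength.
#' @param wavelengths strictly increasing numeric vector of nm values.
#' @param kind `"reflectance"` or `"derivative"`.
#' @param meta data frame with one row per sample; must contain `sample_id`.
#'   Missing metadata columns (`treatment`, `stage`, `plot`, `scan`) are
#'   filled with `NA`.
#' @return an object of class `spectra`.
#' @export
spectra <- function(values, wavelengths, kind = c("reflectance", "derivative"),
                    meta = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(values) != length(wavelengths))
    stop("`values` must have one column per wavelength", call. = FALSE)
  if (length(wavelengths) >= 2 && any(diff(wavelengths) <= 0))
    stop("grid error: wavelengths must be strictly increasing", call. = FALSE)
  if (is.null(meta)) {
    meta <- data.frame(sample_id = paste0("S", seq_len(nrow(values))))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(meta$sample_id))
    stop("`meta` must contain a sample_id column", call. = FALSE)
  for (col in c("treatment", "stage", "plot", "scan")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA
  }
  if (nrow(meta) != nrow(values))
    stop("`meta` must have one row per sample", call. = FALSE)
  if (kind == "reflectance" &&
      any(values < 0 | values > 1, na.rm = TRUE))
    stop("range error: reflectance values must lie in [0, 1]", call. = FALSE)
  rownames(values) <- NULL
  structure(list(values = values, wavelengths = wavelengths,
                 kind = kind, meta = meta),
            class = "spectra")
}

#' @export
print.spectra <- function(x, ...) {
  cat(sprintf("<spectra: %d %s curve(s), %d bands %g-%g nm>\n",
              nrow(x$values), x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Number of samples in a spectra object
#' @param x a `spectra` object.
#' @return integer sample count.
#' @export
n_samples <- function(x) nrow(x$values)

# shared-grid check used by every multi-set operation
stopifnot_same_grid <- function(x) {
  if (!inherits(x, "spectra")) stop("expected a `spectra` object", call. = FALSE)
  invisible(x)
}

#' Read spectra from CSV
#'
#' Reads a spectral dataset from a wide CSV (one row per sample, one column
#' per wavelength, wavelength columns named by their nm value) or a long CSV
#' (columns `sample_id`, `wavelength`, `value`). Non-wavelength columns in
#' the wide layout are treated as metadata and preserved.
#'
#' Reflectance exported as percent (values in 0--100) is auto-detected when
#' the maximum exceeds 1.5 and divided by 100 with a warning. Values below
#' -0.05 or above 1.05 raise a range error; small negatives in [-0.05, 0)
#' are clipped to 0 with a warning. Rows containing non-finite values are
#' rejected with a warning.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @return a `spectra` object of kind `"reflectance"`.
#' @export
read_spectra <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "long") {
    need <- c("sample_id", "wavelength", "value")
    if (!all(need %in% names(df)))
      stop("format error: long layout needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    wl <- sort(unique(df$wavelength))
    ids <- unique(df$sample_id)
    m <- matrix(NA_real_, length(ids), length(wl),
                dimnames = list(ids, wl))
    m[cbind(match(df$sample_id, ids), match(df$wavelength, wl))] <- df$value
    meta_cols <- setdiff(names(df), c("wavelength", "value"))
    meta <- unique(df[meta_cols])
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
    return(build_reflectance(m, wl, meta))
  }
  is_wl <- suppressWarnings(!is.na(as.numeric(names(df))))
  if (!any(is_wl))
    stop("format error: wide layout has no wavelength columns", call. = FALSE)
  wl <- as.numeric(names(df)[is_wl])
  ord <- order(wl)
  m <- as.matrix(df[, which(is_wl)[ord], drop = FALSE])
  storage.mode(m) <- "double"
  meta <- df[, !is_wl, drop = FALSE]
  if (is.null(meta$sample_id))
    meta$sample_id <- paste0("S", seq_len(nrow(m)))
  build_reflectance(m, wl[ord], meta)
}

build_reflectance <- function(m, wl, meta) {
  if (any(diff(wl) <= 0))
    stop("grid error: wavelengths must be strictly increasing", call. = FALSE)
  bad <- !apply(m, 1, function(r) all(is.finite(r)))
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite reflectance rejected")
    m <- m[!bad, , drop = FALSE]
    meta <- meta[!bad, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no valid spectra in file", call. = FALSE)
  if (max(m) > 1.5) {
    warning("reflectance appears to be in percent; dividing by 100")
    m <- m / 100
  }
  if (any(m < -0.05 | m > 1.05))
    stop("range error: reflectance outside [-0.05, 1.05]", call. = FALSE)
  if (any(m < 0)) {
    warning("clipping ", sum(m < 0), " small negative reflectance value(s) to 0")
    m[m < 0] <- 0
  }
  m[m > 1] <- 1
  spectra(m, wl, "reflectance", meta)
}

#' Write spectra to a wide CSV
#'
#' Inverse of [read_spectra()] with `layout = "wide"`: metadata columns
#' first, then one column per wavelength.
#'
#' @param x a `spectra` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot_same_grid(x)
  df <- cbind(x$meta, as.data.frame(x$values))
  names(df)[(ncol(x$meta) + 1):ncol(df)] <- x$wavelengths
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Average replicate scans
#'
#' Collapses repeated scans of the same sample to their arithmetic mean
#' curve, mirroring the standard field protocol of averaging the replicate
#' curves recorded per plot. Groups are formed by the metadata columns in
#' `group_key`; the resulting `sample_id` is the group key pasted with `"_"`
#' when grouping on several columns. The scan count is recorded in an
#' `n_scans` metadata column.
#'
#' Idempotent: averaging an already-averaged set returns the same curves.
#'
#' @param x a `spectra` object.
#' @param group_key character vector of metadata column names (default
#'   `"sample_id"`).
#' @return a `spectra` object with one record per group.
#' @export
average_scans <- function(x, group_key = "sample_id") {
  stopifnot_same_grid(x)
  missing_cols <- setdiff(group_key, names(x$meta))
  if (length(missing_cols))
    stop("unknown group column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  key <- do.call(paste, c(x$meta[group_key], sep = "_"))
  if (length(key) == 0) stop("empty spectra set", call. = FALSE)
  groups <- unique(key)
  m <- matrix(NA_real_, length(groups), ncol(x$values))
  meta_rows <- integer(length(groups))
  n_scans <- integer(length(groups))
  for (g in seq_along(groups)) {
    idx <- which(key == groups[g])
    m[g, ] <- colMeans(x$values[idx, , drop = FALSE])
    meta_rows[g] <- idx[1]
    n_scans[g] <- length(idx)
  }
  meta <- x$meta[meta_rows, setdiff(names(x$meta), "scan"), drop = FALSE]
  meta$sample_id <- groups
  meta$n_scans <- n_scans
  rownames(meta) <- NULL
  spectra(m, x$wavelengths, x$kind, meta)
}

#' Write a result table to CSV
#'
#' Writes any tabular result (feature tables, screening tables, evaluation
#' grids) as an RFC-4180 CSV with header, UTF-8, '.' decimal separator.
#' Numeric values round-trip through [utils::read.csv()] to full double
#' precision.
#'
#' @param rows non-empty data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop("refusing to write an empty table", call. = FALSE)
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read targets (petiole nitrate concentrations)
#'
#' Reads a two-column CSV (`sample_id`, `no3n`) of petiole nitrate-nitrogen
#' concentrations in g/L and validates positivity and uniqueness.
#'
#' @param path CSV path.
#' @return data frame with columns `sample_id`, `no3n`.
#' @export
read_targets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "no3n") %in% names(df)))
    stop("format error: target table needs sample_id and no3n", call. = FALSE)
  if (any(!is.finite(df$no3n)) || any(df$no3n <= 0))
    stop("target concentrations must be positive and finite", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in target table", call. = FALSE)
  df
}
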