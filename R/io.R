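# Reading and writing spectra datasets.
#
# On-disk dialect: comma-separated text, header "sample_id,label,<wn1>,<wn2>,..."
# with wavenumber column headers in strictly descending order (the spectroscopy
# plotting convention). Class labels are stored as the tokens FM / LC / HC and
# mapped to the dummy codes 1 / 2 / 0 only at model time.

CLASS_CODES <- c(HC = 0, FM = 1, LC = 2)

#' Wavenumber grid of a spectra table
#'
#' @param data A spectra tibble: columns `sample_id`, `label`, then one numeric
#'   column per wavenumber, named by the wavenumber value.
#' @return Numeric vector of wavenumbers in column order (descending).
#' @export
spectra_wavenumbers <- function(data) {
  cols <- setdiff(names(data), c("sample_id", "label"))
  wn <- suppressWarnings(as.numeric(cols))
  if (anyNA(wn)) {
    stop("non-numeric wavenumber column header(s): ",
         paste(cols[is.na(wn)], collapse = ", "), call. = FALSE)
  }
  wn
}

#' Absorbance matrix of a spectra table
#'
#' @inheritParams spectra_wavenumbers
#' @return Numeric matrix (samples x wavenumbers) with `sample_id` row names.
#' @export
spectra_matrix <- function(data) {
  wn <- spectra_wavenumbers(data)
  x <- as.matrix(data[, setdiff(names(data), c("sample_id", "label")), drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- data$sample_id
  colnames(x) <- format_wn(wn)
  x
}

#' Map class labels to the dummy response codes
#'
#' The discriminant response uses the dummy coding FM = 1, LC = 2, HC = 0.
#'
#' @param labels Character vector of class tokens (FM, LC, HC).
#' @return Numeric vector of class codes.
#' @export
label_code <- function(labels) {
  bad <- setdiff(unique(labels), names(CLASS_CODES))
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(CLASS_CODES[labels])
}

format_wn <- function(wn) {
  # fixed, locale-independent header formatting
  formatC(wn, format = "fg", digits = 10)
}

# assemble a spectra tibble from parts
new_spectra <- function(sample_id, label, x, wavenumbers) {
  stopifnot(length(sample_id) == nrow(x), length(label) == nrow(x),
            length(wavenumbers) == ncol(x))
  out <- tibble::as_tibble(as.data.frame(x, optional = TRUE),
                           .name_repair = "minimal")
  names(out) <- format_wn(wavenumbers)
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id, label = label), out)
}

validate_spectra <- function(data, min_points = 7L) {
  stopifnot(is.data.frame(data))
  if (!all(c("sample_id", "label") %in% names(data))) {
    stop("spectra table must have 'sample_id' and 'label' columns", call. = FALSE)
  }
  wn <- spectra_wavenumbers(data)
  if (length(wn) < min_points) {
    stop("spectra need at least ", min_points, " grid points", call. = FALSE)
  }
  d <- diff(wn)
  if (!(all(d > 0) || all(d < 0))) {
    stop("wavenumber grid is not strictly monotone", call. = FALSE)
  }
  label_code(data$label)
  x <- spectra_matrix(data)
  if (nrow(x) && any(!is.finite(x))) {
    bad <- data$sample_id[rowSums(!is.finite(x)) > 0]
    stop("non-finite absorbance in sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(data)
}

# normalize grid order to descending wavenumber
orient_spectra <- function(data) {
  wn <- spectra_wavenumbers(data)
  if (is.unsorted(rev(wn))) {
    ord <- order(wn, decreasing = TRUE)
    data <- data[, c(1:2, 2L + ord)]
  }
  data
}

#' Write a spectra dataset to delimited text
#'
#' Columns are emitted in descending wavenumber order; labels are written as
#' their FM/LC/HC tokens.
#'
#' @inheritParams spectra_wavenumbers
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(data, path) {
  if (nrow(data)) validate_spectra(data)
  data <- orient_spectra(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a spectra dataset from delimited text
#'
#' Accepts ascending or descending wavenumber columns and normalizes to
#' descending. Malformed rows, non-monotone grids and unknown label tokens
#' raise errors naming the offending row or sample.
#'
#' @param path Input file path (format produced by [write_spectra()]).
#' @return A spectra tibble.
#' @export
read_spectra <- function(path) {
  data <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    label = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE))
  probs <- readr::problems(data)
  if (nrow(probs)) {
    raw <- readLines(path, warn = FALSE)
    rows <- unique(probs$row)
    ids <- vapply(rows, function(r) {
      if (r >= 1 && r <= length(raw)) sub(",.*$", "", raw[r]) else "?"
    }, "")
    stop("malformed dataset row(s): ",
         paste(sprintf("%s (row %d)", ids, rows), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data)) {
    x <- spectra_matrix(data)
    if (anyNA(x)) {
      bad <- data$sample_id[rowSums(is.na(x)) > 0]
      stop("missing value(s) in sample(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    validate_spectra(data)
  }
  orient_spectra(data)
}
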