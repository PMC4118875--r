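#' Read a wide-format spectral table
#'
#' Reads spectra from CSV or XLSX laid out one spectrum per row, a header
#' row of numeric wavelength labels (nm), a class-label column and
#' optionally a provenance column. The transposed layout (one channel per
#' row, first column = wavelength, one column per spectrum) is supported
#' via `orientation = "channels"`, in which case per-spectrum class labels
#' must be supplied through `labels` (a character vector, or the path of a
#' two-column id,class CSV sidecar); this covers deposited spreadsheets
#' whose exact orientation varies.
#'
#' Masked channels are recognised by a `!` prefix on the wavelength header
#' (the dialect [write_spectra()] emits); headers without the prefix are
#' treated as valid channels, so plain exported tables read naturally.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`.
#' @param label_column Name of the class-label column (default `"class"`).
#' @param sheet Sheet name or index for XLSX input.
#' @param orientation `"spectra"` (rows are spectra, default) or
#'   `"channels"` (rows are wavelength channels).
#' @param labels Optional label vector or sidecar CSV path (required for
#'   `orientation = "channels"`).
#' @return A [spectra_set()] with wavelengths sorted ascending (columns
#'   reordered if needed).
#' @export
read_spectra <- function(path, format = c("auto", "csv", "xlsx"),
                         label_column = "class", sheet = 1,
                         orientation = c("spectra", "channels"),
                         labels = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xlsx?|xls)$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  tab <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLS/XLSX requires the 'readxl' package", call. = FALSE)
    }
    readxl::read_excel(path, sheet = sheet, .name_repair = "minimal")
  } else {
    readr::read_csv(path, show_col_types = FALSE, name_repair = "minimal",
                    progress = FALSE)
  }
  tab <- tibble::as_tibble(tab, .name_repair = "minimal")

  if (orientation == "channels") {
    wl <- as.numeric(tab[[1]])
    if (anyNA(wl)) {
      stop("first column must hold numeric wavelengths when orientation = \"channels\"",
           call. = FALSE)
    }
    mat <- t(as.matrix(tab[, -1, drop = FALSE]))
    storage.mode(mat) <- "double"
    ids <- colnames(tab)[-1]
    labels <- resolve_labels(labels, ids, nrow(mat))
    ord <- order(wl)
    return(spectra_set(wl[ord], mat[, ord, drop = FALSE], labels = labels,
                       provenance = ids))
  }

  nms <- colnames(tab)
  if (!label_column %in% nms) {
    stop(sprintf("label column '%s' not found in %s", label_column, path),
         call. = FALSE)
  }
  labs <- as.character(tab[[label_column]])
  prov <- if ("provenance" %in% nms) as.character(tab[["provenance"]]) else NULL
  chan_cols <- setdiff(nms, c(label_column, "provenance"))
  masked <- startsWith(chan_cols, "!")
  wl <- suppressWarnings(as.numeric(sub("^!", "", chan_cols)))
  if (anyNA(wl)) {
    stop(sprintf("column(s) %s cannot be parsed as wavelengths",
                 paste(sQuote(chan_cols[is.na(wl)]), collapse = ", ")),
         call. = FALSE)
  }
  mat <- as.matrix(tab[, chan_cols, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat[, !masked, drop = FALSE])) {
    stop("ragged or non-numeric intensity values detected", call. = FALSE)
  }
  ord <- order(wl)
  spectra_set(wl[ord], mat[, ord, drop = FALSE], labels = labs,
              valid_mask = !masked[ord], provenance = prov)
}

resolve_labels <- function(labels, ids, n) {
  if (is.null(labels)) {
    stop("per-spectrum labels must be supplied for orientation = \"channels\"",
         call. = FALSE)
  }
  if (length(labels) == 1L && is.character(labels) && file.exists(labels)) {
    side <- readr::read_csv(labels, show_col_types = FALSE, progress = FALSE)
    labels <- as.character(side[[2]])[match(ids, as.character(side[[1]]))]
  }
  if (length(labels) != n || anyNA(labels)) {
    stop("could not resolve one class label per spectrum", call. = FALSE)
  }
  as.character(labels)
}

#' Write a spectra set as a wide CSV
#'
#' Lossless round-trip companion of [read_spectra()]: one row per
#' spectrum, wavelength headers in nm, masked channels flagged by a `!`
#' header prefix, plus `class` and `provenance` columns.
#'
#' @param set A [spectra_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  if (n_spectra(set) < 1L || n_channels(set) < 1L) {
    stop("refusing to write an empty spectra set", call. = FALSE)
  }
  hdr <- format_wavelength(set$wavelengths)
  hdr[!set$valid_mask] <- paste0("!", hdr[!set$valid_mask])
  mat <- set$intensities
  colnames(mat) <- hdr
  out <- dplyr::bind_cols(
    tibble::tibble(class = set$labels, provenance = set$provenance),
    tibble::as_tibble(mat, .name_repair = "minimal")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write an evaluation report (or any result list) as JSON
#'
#' @param report An `evaluation_report` or a plain list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  obj <- if (inherits(report, "evaluation_report")) report_to_list(report) else report
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
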