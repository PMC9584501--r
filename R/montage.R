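#' Construct an electrode montage
#'
#' A montage places each EEG electrode on an integer grid abstracting the
#' scalp layout (10-20 style systems). The grid drives graph construction:
#' electrodes in neighbouring cells (Chebyshev grid distance 1) become graph
#' neighbours, so every interior electrode has the 8 natural neighbours
#' (up, down, left, right and the four diagonals).
#'
#' @param entries data.frame with columns `name` (character), `row`, `col`
#'   (non-negative integers).
#' @return an object of class `cgcnn_montage` with fields `entries` and
#'   `n_electrodes`.
#' @examples
#' m <- montage(data.frame(name = c("C3", "Cz", "C4"), row = 0, col = 0:2))
#' m$n_electrodes
#' @export
montage <- function(entries) {
  if (!is.data.frame(entries) || !all(c("name", "row", "col") %in% names(entries)))
    stop_arg("montage entries must be a data.frame with columns name, row, col")
  entries$name <- as.character(entries$name)
  for (fld in c("row", "col")) {
    v <- entries[[fld]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != floor(v)))
      stop_arg("montage column '", fld, "' must contain integers")
    if (any(v < 0)) stop_arg("montage column '", fld, "' must be non-negative")
    entries[[fld]] <- as.integer(v)
  }
  dup <- entries$name[duplicated(entries$name)]
  if (length(dup))
    stop_arg("duplicate electrode name(s): ", paste(unique(dup), collapse = ", "))
  cell <- paste(entries$row, entries$col, sep = ",")
  dupc <- cell[duplicated(cell)]
  if (length(dupc))
    stop_arg("duplicate grid cell(s): (", paste(unique(dupc), collapse = "), ("), ")")
  structure(
    list(entries = entries[, c("name", "row", "col")],
         n_electrodes = nrow(entries)),
    class = "cgcnn_montage"
  )
}

#' Read an electrode montage from CSV
#'
#' The file must have a header `name,row,col`, one electrode per line,
#' UTF-8 encoded. Coordinates are non-negative integers; one electrode per
#' grid cell.
#'
#' @param path path to the montage CSV.
#' @return a validated [montage()] object.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop_arg("montage file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("name", "row", "col") %in% names(df)))
    stop_arg("montage CSV must have header name,row,col (got: ",
             paste(names(df), collapse = ","), ")")
  for (fld in c("row", "col")) {
    if (!is.numeric(df[[fld]]))
      stop_arg("montage column '", fld, "' failed to parse as integer")
  }
  montage(df)
}

#' A full rectangular grid montage
#'
#' Convenience constructor used throughout the tests and by the synthetic
#' generator's default easy task (a 3 x 3 grid of 9 electrodes).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param prefix electrode name prefix.
#' @return a [montage()] object with `n_rows * n_cols` electrodes in row-major
#'   order.
#' @export
grid_montage <- function(n_rows, n_cols, prefix = "E") {
  g <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  montage(data.frame(
    name = paste0(prefix, seq_len(nrow(g))),
    row = g$row, col = g$col
  ))
}

#' @export
print.cgcnn_montage <- function(x, ...) {
  cat("<cgcnn_montage> ", x$n_electrodes, " electrodes on a ",
      max(x$entries$row) + 1L, "x", max(x$entries$col) + 1L, " grid\n", sep = "")
  invisible(x)
}
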