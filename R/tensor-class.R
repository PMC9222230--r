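#' Six-mode expression tensor
#'
#' Lightweight container for a multi-way expression array with the fixed
#' mode order `(probe, time, replicate, treatment, strain, tissue)`.
#' The underlying storage is a plain numeric array carrying complete
#' `dimnames`; the class only adds validation and printing.
#'
#' @param values numeric array with six modes. `dimnames` may be supplied
#'   here or via `probe_ids`/`axis_labels`.
#' @param probe_ids character vector of probe identifiers for mode 1;
#'   defaults to existing dimnames or `probe_<i>`.
#' @param axis_labels optional named list of level names for modes 2-6
#'   (names among `time`, `replicate`, `treatment`, `strain`, `tissue`).
#'
#' @return An object of class `expression_tensor`: the array with complete
#'   dimnames and mode names `c("probe","time","replicate","treatment",
#'   "strain","tissue")`.
#' @export
expression_tensor <- function(values, probe_ids = NULL, axis_labels = NULL) {
  if (!is.array(values) || length(dim(values)) != 6L) {
    stop("`values` must be a numeric array with exactly 6 modes", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression tensor must not contain missing values", call. = FALSE)
  }
  d <- dim(values)
  modes <- tensor_mode_names()
  dn <- dimnames(values)
  if (is.null(dn)) dn <- vector("list", 6L)
  if (!is.null(probe_ids)) {
    if (length(probe_ids) != d[1L]) {
      stop("length(probe_ids) must equal dim(values)[1]", call. = FALSE)
    }
    dn[[1L]] <- as.character(probe_ids)
  }
  if (is.null(dn[[1L]])) dn[[1L]] <- sprintf("probe_%06d", seq_len(d[1L]))
  for (k in 2:6) {
    lab <- axis_labels[[modes[k]]]
    if (!is.null(lab)) {
      if (length(lab) != d[k]) {
        stop(sprintf("axis_labels$%s has length %d, mode has size %d",
                     modes[k], length(lab), d[k]), call. = FALSE)
      }
      dn[[k]] <- as.character(lab)
    }
    if (is.null(dn[[k]])) dn[[k]] <- sprintf("%s%d", modes[k], seq_len(d[k]))
  }
  names(dn) <- modes
  dimnames(values) <- dn
  class(values) <- c("expression_tensor", "array")
  values
}

tensor_mode_names <- function() {
  c("probe", "time", "replicate", "treatment", "strain", "tissue")
}

#' @export
print.expression_tensor <- function(x, ...) {
  d <- dim(x)
  cat("expression_tensor: ",
      paste(sprintf("%d %s", d, names(dimnames(x))), collapse = " x "), "\n",
      sep = "")
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Probe identifiers of an expression tensor
#' @param x an `expression_tensor`
#' @return character vector of mode-1 names.
#' @export
probe_ids <- function(x) dimnames(x)[[1L]]

# strip the class so aperm/matrix reshaping never dispatches on it
as_plain_array <- function(x) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}
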