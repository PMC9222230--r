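#' Mode-n unfolding of a tensor
#'
#' Rearranges an N-mode array into a matrix whose rows index the chosen
#' mode and whose columns run over all remaining modes (kept in their
#' original relative order).
#'
#' @param x numeric array with at least two modes.
#' @param mode which mode becomes the rows.
#' @return a `dim(x)[mode]` by `prod(dim(x)[-mode])` matrix.
#' @export
unfold <- function(x, mode) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) stop("`x` must have >= 2 modes", call. = FALSE)
  if (mode < 1L || mode > length(d)) stop("`mode` out of range", call. = FALSE)
  x <- aperm(unclass(x), c(mode, seq_along(d)[-mode]))
  dim(x) <- c(d[mode], prod(d[-mode]))
  x
}

# x times matrix M along `mode`: replaces mode size d[mode] by nrow(M).
ttm <- function(x, M, mode) {
  d <- dim(x)
  perm <- c(mode, seq_along(d)[-mode])
  y <- aperm(unclass(x), perm)
  dim(y) <- c(d[mode], prod(d[-mode]))
  y <- M %*% y
  dim(y) <- c(nrow(M), d[-mode])
  aperm(y, order(perm))
}

# flip each column so its largest-magnitude entry is positive (first such
# entry on exact ties); makes the sign-ambiguous SVD columns deterministic
fix_column_signs <- function(U) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Higher-order singular value decomposition
#'
#' Computes the Tucker decomposition whose mode-n factor matrix holds the
#' left singular vectors of the mode-n unfolding, ordered by descending
#' singular value, and whose core is the tensor contracted with the
#' transposed factors:
#' \deqn{x_{i_1 \dots i_N} = \sum_{\ell_1} \cdots \sum_{\ell_N}
#'       G(\ell_1 \dots \ell_N)\, u_{\ell_1 i_1} \cdots u_{\ell_N i_N}.}
#' With full (economy) ranks the reconstruction is exact and
#' \eqn{\|G\|_F = \|x\|_F}.  Each factor column's sign is fixed so that
#' its largest-magnitude entry is positive, making the result
#' deterministic; ties in singular values keep the order returned by
#' LAPACK.
#'
#' Unfoldings are materialized in memory: intended for desk-scale tensors
#' (tens of millions of entries), not out-of-core data.
#'
#' @param x numeric array with at least two modes (an `expression_tensor`
#'   or any plain array).
#' @param ranks optional integer vector, one retained rank per mode;
#'   defaults to the economy rank `min(dim(x)[n], prod(dim(x)[-n]))`.
#' @return object of class `tucker`: list with `core` (array), `factors`
#'   (list of orthonormal matrices, one per mode), `d` (singular values
#'   per mode), `dims`, and `mode_names`.
#' @seealso [reconstruct()]
#' @export
hosvd <- function(x, ranks = NULL) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) stop("`x` must have >= 2 modes", call. = FALSE)
  N <- length(d)
  econ <- vapply(seq_len(N), function(n) min(d[n], prod(d[-n])), numeric(1))
  if (is.null(ranks)) ranks <- econ
  ranks <- as.integer(ranks)
  if (length(ranks) != N) stop("`ranks` must give one rank per mode", call. = FALSE)
  if (any(ranks < 1L) || any(ranks > d)) {
    stop(sprintf("retained rank must lie in [1, mode size]; offending mode(s): %s",
                 paste(which(ranks < 1L | ranks > d), collapse = ", ")),
         call. = FALSE)
  }
  ranks <- pmin(ranks, as.integer(econ))
  mode_names <- names(dimnames(x))
  if (is.null(mode_names) || !all(nzchar(mode_names))) {
    mode_names <- if (N == 6L) tensor_mode_names() else paste0("mode", seq_len(N))
  }
  factors <- vector("list", N)
  dvals <- vector("list", N)
  for (n in seq_len(N)) {
    sv <- svd(unfold(x, n), nu = ranks[n], nv = 0)
    factors[[n]] <- fix_column_signs(sv$u)
    dvals[[n]] <- sv$d[seq_len(ranks[n])]
  }
  core <- unclass(x)
  dimnames(core) <- NULL
  for (n in seq_len(N)) core <- ttm(core, t(factors[[n]]), n)
  structure(list(core = core, factors = factors, d = dvals,
                 dims = d, mode_names = mode_names),
            class = "tucker")
}

#' Reconstruct a tensor from its Tucker decomposition
#'
#' Contracts the core with every factor matrix, i.e. evaluates the HOSVD
#' series expansion.  With full economy ranks the result equals the
#' decomposed tensor to numerical precision; with truncated ranks it is
#' the corresponding low-multilinear-rank approximation.
#'
#' @param decomposition a `tucker` object from [hosvd()].
#' @return numeric array with the original mode sizes.
#' @export
reconstruct <- function(decomposition) {
  if (!inherits(decomposition, "tucker")) stop("need a `tucker` object", call. = FALSE)
  x <- decomposition$core
  for (n in seq_along(decomposition$factors)) {
    U <- decomposition$factors[[n]]
    if (!is.matrix(U) || ncol(U) != dim(x)[n]) {
      stop(sprintf("factor %d has %d columns but core mode %d has size %d",
                   n, ncol(U), n, dim(x)[n]), call. = FALSE)
    }
    x <- ttm(x, U, n)
  }
  x
}

#' @export
print.tucker <- function(x, ...) {
  cat("tucker decomposition\n")
  cat("  tensor dims: ", paste(x$dims, collapse = " x "), "\n", sep = "")
  cat("  core dims:   ", paste(dim(x$core), collapse = " x "), "\n", sep = "")
  if (!is.null(x$mode_names)) {
    cat("  modes:       ", paste(x$mode_names, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
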