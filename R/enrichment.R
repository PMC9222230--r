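#' Read a GMT gene-set library
#'
#' Standard GMT: one set per line, tab-separated fields
#' `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors (term -> gene symbols);
#'   descriptions kept as attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", which(short)[1L]),
         call. = FALSE)
  }
  terms <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(terms)) {
    stop("GMT contains duplicated term names", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- terms
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[`, character(1L), 2L), terms)
  sets
}

#' Build a gene-set collection over a background universe
#'
#' @param sets named list of gene-symbol vectors (e.g. from
#'   [read_gmt()]).
#' @param universe background symbols; defaults to the union of all
#'   sets.  Sets are restricted to the universe; sets that become empty
#'   are dropped with a warning.
#' @return list of class `gene_set_collection` with `sets` and
#'   `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list", call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty", call. = FALSE)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  restricted <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    warning(sprintf("%d set(s) empty after restriction to the universe; dropped",
                    sum(empty)), call. = FALSE)
    restricted <- restricted[!empty]
  }
  structure(list(sets = restricted, universe = universe),
            class = "gene_set_collection")
}

#' Map probe identifiers to gene symbols
#'
#' Collapses many-to-one probe/symbol annotation and drops unmapped
#' probes (missing or empty symbol), reporting how many were dropped.
#'
#' @param ids probe identifiers to map.
#' @param annotation data.frame with probe and symbol columns.
#' @param probe_col,symbol_col column names (defaults `probe_id`,
#'   `symbol`).
#' @return character vector of unique symbols, with attribute
#'   `n_unmapped` (probes with no non-empty symbol).
#' @export
map_probes_to_symbols <- function(ids, annotation, probe_col = "probe_id",
                                  symbol_col = "symbol") {
  if (!all(c(probe_col, symbol_col) %in% names(annotation))) {
    stop(sprintf("annotation must have columns '%s' and '%s'",
                 probe_col, symbol_col), call. = FALSE)
  }
  sym <- annotation[[symbol_col]][match(ids, annotation[[probe_col]])]
  sym[is.na(sym)] <- ""
  mapped <- nzchar(trimws(sym))
  out <- unique(trimws(sym[mapped]))
  attr(out, "n_unmapped") <- sum(!mapped)
  out
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided (enrichment-direction) hypergeometric upper-tail test per
#' term: with universe size N, term size K, query size n and overlap a,
#' the p-value is \eqn{P[X \ge a]} for \eqn{X \sim
#' \mathrm{Hypergeom}(N, K, n)} — equivalent to Fisher's exact test in
#' the enrichment direction.  BH correction across terms; rows sorted by
#' adjusted then raw p, then term.  The query is restricted to the
#' universe first; dropped symbols are reported via the `n_dropped`
#' attribute.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @return data.frame with `term`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `overlap_str` (`"a/K"`), `p_raw`, `p_adj`.
#' @export
enrich <- function(query, collection) {
  if (!inherits(collection, "gene_set_collection")) {
    stop("`collection` must come from gene_set_collection()", call. = FALSE)
  }
  query <- unique(as.character(query))
  in_universe <- query %in% collection$universe
  n_dropped <- sum(!in_universe)
  query <- query[in_universe]
  if (!length(query)) {
    stop("query is empty after restriction to the universe", call. = FALSE)
  }
  N <- length(collection$universe)
  n <- length(query)
  K <- lengths(collection$sets)
  a <- vapply(collection$sets, function(s) length(intersect(s, query)), integer(1L))
  p_raw <- stats::phyper(a - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  out <- data.frame(term = names(collection$sets), overlap = a, set_size = K,
                    query_size = n, universe_size = N,
                    overlap_str = sprintf("%d/%d", a, K),
                    p_raw = p_raw, p_adj = p_adj,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_adj, out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Venn-style overlap report between selections
#'
#' Computes every exclusive region of the Venn partition of two or more
#' named sets (membership-pattern counts), plus all pairwise
#' intersection sizes.  Region counts are inclusion-exclusion consistent
#' by construction: they sum to the union size.
#'
#' @param selections named list (>= 2) of character vectors, e.g.
#'   selected probe or gene sets per method.
#' @return list with `regions` (data.frame: one row per non-empty
#'   membership pattern with per-set indicator columns and `count`),
#'   `pairwise` (matrix of intersection sizes, diagonal = set sizes) and
#'   `union_size`.
#' @export
overlap_report <- function(selections) {
  if (length(selections) < 2L || is.null(names(selections))) {
    stop("`selections` must be a named list of >= 2 sets", call. = FALSE)
  }
  sets <- lapply(selections, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  patterns <- expand.grid(rep(list(c(1L, 0L)), length(sets)))[-2^length(sets), ,
                                                              drop = FALSE]
  names(patterns) <- names(sets)
  key <- apply(patterns, 1L, paste, collapse = "")
  counts <- vapply(key, function(k) sum(pattern == k), integer(1L))
  regions <- cbind(patterns, count = counts)
  rownames(regions) <- NULL
  pairwise <- outer(seq_along(sets), seq_along(sets),
                    Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pairwise) <- list(names(sets), names(sets))
  list(regions = regions, pairwise = pairwise,
       union_size = length(universe))
}
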