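#' Parse a GEO series-matrix style file
#'
#' Reads the tab-separated series-matrix dialect: metadata lines prefixed
#' `!`, a probe-by-sample numeric table delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end`, first table
#' column `ID_REF`.  Plain or gzip-compressed files are both accepted.
#'
#' @param path path to a series-matrix file (`.txt` or `.txt.gz`).
#' @return list with
#'   \describe{
#'     \item{table}{numeric matrix, probes as rownames, sample ids as
#'       colnames}
#'     \item{metadata}{named list of `!Sample_*` (and `!Series_*`) fields;
#'       a field occurring on several lines (e.g.
#'       `Sample_characteristics_ch1`) becomes a character matrix with one
#'       row per line and one column per sample}
#'   }
#' @export
parse_series_matrix <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop(sprintf("'%s': series-matrix table delimiters missing or malformed",
                 path), call. = FALSE)
  }

  split_fields <- function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    gsub('^"|"$', "", f)
  }

  meta_lines <- grep("^!", lines[c(seq_len(begin - 1L),
                                   seq(end + 1L, length.out = max(0L, length(lines) - end)))],
                     value = TRUE)
  meta_lines <- meta_lines[!grepl("^!series_matrix_table", meta_lines)]
  metadata <- list()
  for (ln in meta_lines) {
    f <- split_fields(ln)
    key <- sub("^!", "", f[1L])
    val <- f[-1L]
    if (is.null(metadata[[key]])) {
      metadata[[key]] <- matrix(val, nrow = 1L)
    } else {
      metadata[[key]] <- rbind(metadata[[key]], val)
    }
  }
  # single-line fields stay plain character vectors
  metadata <- lapply(metadata, function(m) if (nrow(m) == 1L) drop(m) else m)

  header <- split_fields(lines[begin + 1L])
  if (header[1L] != "ID_REF") {
    stop(sprintf("'%s': table header must start with ID_REF", path), call. = FALSE)
  }
  sample_ids <- header[-1L]
  body <- lines[seq(begin + 2L, end - 1L)]
  rows <- lapply(body, split_fields)
  nc <- lengths(rows)
  if (any(nc != length(header))) {
    stop(sprintf("'%s': row %d has %d fields, expected %d", path,
                 which(nc != length(header))[1L],
                 nc[nc != length(header)][1L], length(header)), call. = FALSE)
  }
  probe <- vapply(rows, `[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids),
                 dimnames = list(probe, sample_ids))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    bad <- which(is.na(v) & rows[[i]][-1L] != "NA")
    if (length(bad)) {
      stop(sprintf("'%s': non-numeric value '%s' at probe '%s', sample '%s'",
                   path, rows[[i]][-1L][bad[1L]], probe[i], sample_ids[bad[1L]]),
           call. = FALSE)
    }
    vals[i, ] <- v
  }
  list(table = vals, metadata = metadata)
}

#' Default sample-to-design extraction rules
#'
#' GEO sample metadata encodes the experimental design in free-text
#' `characteristics` lines whose wording varies between series, so the
#' mapping is regex-driven and user-configurable.  Each rule is a regular
#' expression with exactly one capture group; it is applied to every
#' `Sample_characteristics_ch1` entry (and the sample title) of a sample,
#' and the first match supplies the value.  The defaults match the
#' canonical encoding used by [write_series_matrices()]
#' (`"time: 3"`, `"strain: 2"`, ...).
#'
#' @return named list of regex rules for fields `tissue`, `time`,
#'   `replicate`, `treatment`, `strain`.
#' @export
default_design_rules <- function() {
  list(tissue    = "^tissue:\\s*(.+)\\s*$",
       time      = "^time:\\s*([0-9]+)\\s*$",
       replicate = "^replicate:\\s*([0-9]+)\\s*$",
       treatment = "^treatment:\\s*([0-9]+)\\s*$",
       strain    = "^strain:\\s*([0-9]+)\\s*$")
}

#' Read design-extraction rules from a YAML config file
#'
#' The file maps field names (`tissue`, `time`, `replicate`, `treatment`,
#' `strain`) to regular expressions with one capture group each; fields
#' left out keep their [default_design_rules()] entry.
#'
#' @param path YAML file path.
#' @return named list of rules, as [default_design_rules()].
#' @export
read_design_rules <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading rule files requires the 'yaml' package", call. = FALSE)
  }
  rules <- default_design_rules()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(rules))
  if (length(unknown)) {
    stop(sprintf("unknown design field(s) in '%s': %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  rules[names(user)] <- user
  rules
}

#' Extract the sample design from series-matrix metadata
#'
#' @param metadata the `metadata` element returned by
#'   [parse_series_matrix()].
#' @param sample_ids sample identifiers (column order of the table);
#'   defaults to the `Sample_geo_accession` field.
#' @param rules regex rules, see [default_design_rules()].
#' @return data.frame with one row per sample: `sample_id`, `tissue`
#'   (character) and integer `time`, `replicate`, `treatment`, `strain`
#'   (1-based level labels as encoded in the metadata).
#' @export
extract_design <- function(metadata, sample_ids = NULL,
                           rules = default_design_rules()) {
  if (is.null(sample_ids)) sample_ids <- c(metadata[["Sample_geo_accession"]])
  if (is.null(sample_ids)) {
    stop("no sample ids: supply `sample_ids` or a Sample_geo_accession field",
         call. = FALSE)
  }
  char_fields <- metadata[grep("^Sample_(characteristics|title)", names(metadata))]
  lines_per_sample <- function(j) {
    unlist(lapply(char_fields, function(m) {
      if (is.matrix(m)) m[, j] else m[j]
    }), use.names = FALSE)
  }
  out <- data.frame(sample_id = sample_ids, tissue = NA_character_,
                    time = NA_integer_, replicate = NA_integer_,
                    treatment = NA_integer_, strain = NA_integer_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(sample_ids)) {
    entries <- lines_per_sample(j)
    for (field in names(rules)) {
      hit <- regmatches(entries, regexec(rules[[field]], entries))
      hit <- Filter(function(h) length(h) == 2L, hit)
      if (!length(hit)) {
        stop(sprintf("sample '%s': no metadata entry matches the '%s' rule",
                     sample_ids[j], field), call. = FALSE)
      }
      val <- hit[[1L]][2L]
      out[[field]][j] <- if (field == "tissue") val else as.integer(val)
    }
  }
  out
}

#' Assemble the six-mode expression tensor from per-tissue tables
#'
#' Takes one probe-by-sample matrix per tissue plus a design table mapping
#' each sample to its `(time, replicate, treatment, strain, tissue)` cell
#' and fills the full factorial grid.  The probe set is the intersection
#' across tissues, in the first table's order.  Assembly is keyed entirely
#' by the design, so permuting sample columns leaves the tensor unchanged.
#'
#' @param tables named list of numeric matrices (name = tissue label,
#'   rownames = probe ids, colnames = sample ids), e.g. the `table`
#'   elements from [parse_series_matrix()].
#' @param designs data.frame as from [extract_design()], covering every
#'   sample of every table; its `tissue` values must match `names(tables)`.
#' @param log2_transform take `log2(x)` of all values before assembly
#'   (requires strictly positive input).
#' @return an [expression_tensor()] of shape
#'   (probes, times, replicates, treatments, strains, tissues).
#' @export
assemble_tensor <- function(tables, designs, log2_transform = FALSE) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("`tables` must be a named list (names = tissue labels)", call. = FALSE)
  }
  probes <- rownames(tables[[1L]])
  for (tb in tables[-1L]) probes <- probes[probes %in% rownames(tb)]
  if (!length(probes)) stop("empty probe intersection across tissues", call. = FALSE)

  tissues <- names(tables)
  times <- sort(unique(designs$time))
  reps <- sort(unique(designs$replicate))
  treats <- sort(unique(designs$treatment))
  strains <- sort(unique(designs$strain))
  d <- c(length(probes), length(times), length(reps), length(treats),
         length(strains), length(tissues))
  values <- array(NA_real_, dim = d)
  filled <- array(FALSE, dim = d[-1L])

  for (ti in seq_along(tissues)) {
    tb <- tables[[ti]]
    des <- designs[designs$tissue == tissues[ti], , drop = FALSE]
    des <- des[des$sample_id %in% colnames(tb), , drop = FALSE]
    for (r in seq_len(nrow(des))) {
      j <- match(des$time[r], times)
      k <- match(des$replicate[r], reps)
      m <- match(des$treatment[r], treats)
      s <- match(des$strain[r], strains)
      if (filled[j, k, m, s, ti]) {
        stop(sprintf(
          "duplicated design cell (time %s, replicate %s, treatment %s, strain %s, tissue %s)",
          des$time[r], des$replicate[r], des$treatment[r], des$strain[r],
          tissues[ti]), call. = FALSE)
      }
      values[, j, k, m, s, ti] <- tb[probes, des$sample_id[r]]
      filled[j, k, m, s, ti] <- TRUE
    }
  }
  if (!all(filled)) {
    miss <- which(!filled, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "design grid incomplete: no sample for (time %s, replicate %s, treatment %s, strain %s, tissue %s)",
      times[miss[1L]], reps[miss[2L]], treats[miss[3L]], strains[miss[4L]],
      tissues[miss[5L]]), call. = FALSE)
  }
  if (log2_transform) {
    if (any(values <= 0)) {
      stop("log2 transform requires strictly positive expression values",
           call. = FALSE)
    }
    values <- log2(values)
  }
  expression_tensor(values, probe_ids = probes,
                    axis_labels = list(time = as.character(times),
                                       replicate = as.character(reps),
                                       treatment = as.character(treats),
                                       strain = as.character(strains),
                                       tissue = tissues))
}

#' Per-sample fiber normalization
#'
#' For every fixed `(time, replicate, treatment, strain, tissue)` cell the
#' probe fiber is centered to mean zero and rescaled so that its sum of
#' squares equals the number of probes N:
#' \deqn{\sum_i x_{ijkmst} = 0, \qquad \sum_i x_{ijkmst}^2 = N.}
#' The operation is idempotent.
#'
#' @param x an [expression_tensor()] (or any array whose first mode indexes
#'   probes).
#' @return tensor of the same shape and labels with every fiber satisfying
#'   both identities.
#' @export
normalize_tensor <- function(x) {
  d <- dim(x)
  N <- d[1L]
  if (N < 2L) stop("normalization needs at least 2 probes", call. = FALSE)
  atts <- attributes(x)
  m <- matrix(as.numeric(x), nrow = N)
  m <- sweep(m, 2L, colMeans(m), "-")
  ss <- colSums(m^2)
  degenerate <- ss <= N * 1e-24
  if (any(degenerate)) {
    fib <- arrayInd(which(degenerate)[1L], d[-1L])
    stop(sprintf(
      "zero-variance sample fiber at (time %d, replicate %d, treatment %d, strain %d, tissue %d)",
      fib[1L], fib[2L], fib[3L], fib[4L], fib[5L]), call. = FALSE)
  }
  m <- sweep(m, 2L, sqrt(N / ss), "*")
  out <- m
  attributes(out) <- atts
  out
}
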