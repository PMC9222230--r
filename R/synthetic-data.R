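#' Configuration for the synthetic multi-tissue study generator
#'
#' Describes a two-treatment, two-strain, multi-tissue time-course design
#' of the kind the tensor pipeline targets: five time points, five
#' replicates and three tissues by default, with a chosen fraction of
#' probes planted as differentially expressed between the two treatment
#' arms uniformly across tissues (the tissue-independent,
#' treatment-distinct signal the pipeline is built to find).
#'
#' @param n_probes number of probes.
#' @param n_times number of time points (default 5).
#' @param n_replicates replicates per design cell (default 5).
#' @param n_treatments number of treatment arms; the generator plants its
#'   effect on arm 1 and requires the value 2.
#' @param n_strains number of strains; must be 2.
#' @param n_tissues number of tissues (default 3).
#' @param frac_deg fraction of probes planted as DEGs, in (0, 1).
#' @param effect_size standardized mean shift added to treatment arm 1 of
#'   every DEG probe (dimensionless, on the expression scale of
#'   `noise_sd`).
#' @param noise_sd standard deviation of the i.i.d. Gaussian measurement
#'   noise; must be positive.
#' @param tissue_baseline_sd SD of the per-probe, per-tissue baseline
#'   levels (tissue-specific expression structure).
#' @param time_ramp if `TRUE`, the planted effect grows linearly with the
#'   time index (mean across time points kept at `effect_size`); default
#'   is an effect constant in time.
#' @param sign_mix if `TRUE`, each DEG probe's effect gets an independent
#'   random sign (up- and down-regulation); default all positive.
#' @param seed integer RNG seed; generation is reproducible given the
#'   seed.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_probes, n_times = 5L, n_replicates = 5L,
                              n_treatments = 2L, n_strains = 2L,
                              n_tissues = 3L, frac_deg = 0.1,
                              effect_size = 1, noise_sd = 1,
                              tissue_baseline_sd = 1, time_ramp = FALSE,
                              sign_mix = FALSE, seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_times = as.integer(n_times),
              n_replicates = as.integer(n_replicates),
              n_treatments = as.integer(n_treatments),
              n_strains = as.integer(n_strains),
              n_tissues = as.integer(n_tissues),
              frac_deg = frac_deg, effect_size = effect_size,
              noise_sd = noise_sd, tissue_baseline_sd = tissue_baseline_sd,
              time_ramp = isTRUE(time_ramp), sign_mix = isTRUE(sign_mix),
              seed = as.integer(seed))
  bad <- function(field, msg) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  for (f in c("n_probes", "n_times", "n_replicates", "n_tissues")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) bad(f, "must be a count >= 1")
  }
  if (cfg$n_treatments != 2L) bad("n_treatments", "must equal 2")
  if (cfg$n_strains != 2L) bad("n_strains", "must equal 2")
  if (!is.finite(cfg$frac_deg) || cfg$frac_deg <= 0 || cfg$frac_deg >= 1) {
    bad("frac_deg", "must lie in (0, 1)")
  }
  if (round(cfg$frac_deg * cfg$n_probes) < 1) {
    bad("frac_deg", "must plant at least one DEG (frac_deg * n_probes >= 1)")
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0) {
    bad("noise_sd", "must be > 0")
  }
  if (!is.finite(cfg$effect_size)) bad("effect_size", "must be finite")
  if (!is.finite(cfg$tissue_baseline_sd) || cfg$tissue_baseline_sd < 0) {
    bad("tissue_baseline_sd", "must be >= 0")
  }
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a synthetic multi-tissue expression dataset with ground truth
#'
#' Draws a six-mode tensor
#' (probe, time, replicate, treatment, strain, tissue) as
#' per-probe/per-tissue Gaussian baselines plus i.i.d. Gaussian noise on a
#' log-like scale, and adds `effect_size` to treatment arm 1 of the
#' planted DEG probes in every tissue, strain, time point and replicate
#' (optionally ramped in time or sign-mixed, see [simulation_config()]).
#' Non-DEG probes carry no planted effect, so with `effect_size = 0` DEG
#' and non-DEG probes are exchangeable.
#'
#' @param config a [simulation_config()].
#' @return list with
#'   \describe{
#'     \item{tensor}{the [expression_tensor()]}
#'     \item{truth}{data.frame `probe_id`, `is_deg`, `effect` (the signed
#'       per-probe planted shift; 0 for non-DEGs)}
#'     \item{config}{the config used}
#'   }
#' @examples
#' sim <- generate_dataset(simulation_config(n_probes = 50, seed = 1))
#' dim(sim$tensor)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("`config` must come from simulation_config()", call. = FALSE)
  }
  set.seed(config$seed)
  d <- with(config, c(n_probes, n_times, n_replicates, n_treatments,
                      n_strains, n_tissues))
  n_deg <- round(config$frac_deg * config$n_probes)
  deg_idx <- sort(sample.int(config$n_probes, n_deg))
  is_deg <- rep(FALSE, config$n_probes)
  is_deg[deg_idx] <- TRUE
  effect <- numeric(config$n_probes)
  sgn <- if (config$sign_mix) sample(c(-1, 1), n_deg, replace = TRUE) else rep(1, n_deg)
  effect[deg_idx] <- sgn * config$effect_size

  values <- array(stats::rnorm(prod(d), sd = config$noise_sd), dim = d)

  # per-probe per-tissue baseline, constant over time/replicate/treatment/strain
  baseline <- matrix(stats::rnorm(d[1L] * d[6L], sd = config$tissue_baseline_sd),
                     nrow = d[1L])
  values <- values + c(baseline[, rep(seq_len(d[6L]), each = prod(d[2:5]))])

  # planted treatment effect on arm 1, identical in every tissue
  ramp <- if (config$time_ramp) {
    2 * seq_len(d[2L]) / (d[2L] + 1)
  } else {
    rep(1, d[2L])
  }
  shift <- outer(effect, ramp)            # probe x time
  values[, , , 1L, , ] <- values[, , , 1L, , , drop = FALSE] +
    c(shift[, rep(seq_len(d[2L]), times = prod(d[c(3L, 5L, 6L)]))])

  pid <- sprintf("probe_%06d", seq_len(config$n_probes))
  tensor <- expression_tensor(values, probe_ids = pid,
                              axis_labels = list(tissue = sprintf("tissue%d", seq_len(d[6L]))))
  truth <- data.frame(probe_id = pid, is_deg = is_deg, effect = effect,
                      stringsAsFactors = FALSE)
  list(tensor = tensor, truth = truth, config = config)
}

#' Write one series-matrix style file per tissue
#'
#' Serializes a six-mode tensor as GEO-flavoured series-matrix files, one
#' per tissue: a `!`-prefixed metadata block whose
#' `Sample_characteristics_ch1` lines encode time, replicate, treatment,
#' strain and tissue in the canonical form understood by
#' [default_design_rules()], followed by the probe-by-sample table between
#' the standard delimiters.  Files round-trip through
#' [parse_series_matrix()] + [extract_design()] + [assemble_tensor()] up
#' to the numeric formatting precision.
#'
#' @param tensor an [expression_tensor()].
#' @param out_dir output directory (created if needed).
#' @param digits significant digits written (default 6, typical of
#'   series-matrix files).
#' @param gzip write gzip-compressed files (`.txt.gz`).
#' @return character vector of file paths, one per tissue.
#' @export
write_series_matrices <- function(tensor, out_dir, digits = 6L, gzip = FALSE) {
  d <- dim(tensor)
  if (length(d) != 6L) stop("`tensor` must have a tissue axis (6 modes)", call. = FALSE)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  dn <- dimnames(tensor)
  tissues <- dn[[6L]]
  grid <- expand.grid(time = seq_len(d[2L]), replicate = seq_len(d[3L]),
                      treatment = seq_len(d[4L]), strain = seq_len(d[5L]))
  q <- function(x) paste0('"', x, '"')
  fmt <- paste0("%.", as.integer(digits), "g")
  paths <- character(length(tissues))
  for (ti in seq_along(tissues)) {
    sample_ids <- sprintf("S%s_%03d", ti, seq_len(nrow(grid)))
    slab <- as_plain_array(tensor)[, , , , , ti]
    dim(slab) <- c(d[1L], nrow(grid))
    lines <- c(
      paste0("!Series_title\t", q(sprintf("synthetic multi-tissue expression, tissue %s", tissues[ti]))),
      paste0("!Sample_geo_accession\t", paste(q(sample_ids), collapse = "\t")),
      paste0("!Sample_title\t",
             paste(q(sprintf("%s t%d r%d trt%d strain%d", tissues[ti], grid$time,
                             grid$replicate, grid$treatment, grid$strain)),
                   collapse = "\t")),
      paste0("!Sample_characteristics_ch1\t",
             paste(q(sprintf("tissue: %s", tissues[ti]))[rep(1L, nrow(grid))], collapse = "\t")),
      paste0("!Sample_characteristics_ch1\t",
             paste(q(sprintf("time: %d", grid$time)), collapse = "\t")),
      paste0("!Sample_characteristics_ch1\t",
             paste(q(sprintf("replicate: %d", grid$replicate)), collapse = "\t")),
      paste0("!Sample_characteristics_ch1\t",
             paste(q(sprintf("treatment: %d", grid$treatment)), collapse = "\t")),
      paste0("!Sample_characteristics_ch1\t",
             paste(q(sprintf("strain: %d", grid$strain)), collapse = "\t")),
      "!series_matrix_table_begin",
      paste(c(q("ID_REF"), q(sample_ids)), collapse = "\t")
    )
    body <- vapply(seq_len(d[1L]), function(i) {
      paste(c(q(dn[[1L]][i]), sprintf(fmt, slab[i, ])), collapse = "\t")
    }, character(1L))
    lines <- c(lines, body, "!series_matrix_table_end")
    fname <- sprintf("tissue_%s_series_matrix.txt%s", tissues[ti],
                     if (gzip) ".gz" else "")
    paths[ti] <- file.path(out_dir, fname)
    con <- if (gzip) gzfile(paths[ti], open = "wt") else file(paths[ti], open = "wt")
    ok <- try(writeLines(lines, con), silent = TRUE)
    close(con)
    if (inherits(ok, "try-error")) {
      stop(sprintf("cannot write '%s'", paths[ti]), call. = FALSE)
    }
  }
  paths
}

#' Write planted-truth labels as a two-column TSV
#'
#' @param truth the `truth` data.frame from [generate_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth[, c("probe_id", "is_deg")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
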