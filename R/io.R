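# Readers, writers and configuration-driven entry points.

#' Write a time series as delimited text
#'
#' One row per sample, one column per channel, preceded by `#`-prefixed
#' metadata lines (sampling rate, channel names, package version).
#'
#' @param x a [timeseries()].
#' @param path output file path.
#' @param extra named list of additional metadata lines.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, extra = list()) {
  stopifnot(inherits(x, "timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(fs = x$fs,
                 channels = paste(rownames(x$data), collapse = ","),
                 duration_s = ncol(x$data) / x$fs,
                 package = paste0("npdirect ", as.character(utils::packageVersion("npdirect")))),
            extra)
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(t(x$data), con, sep = "\t", row.names = FALSE,
                     col.names = rownames(x$data), quote = FALSE)
  invisible(path)
}

#' Read a time series written by [write_timeseries()]
#' @param path input file path.
#' @return A [timeseries()].
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  fs <- as.numeric(meta$fs)
  if (!length(fs) || is.na(fs)) stop("missing 'fs' metadata in ", path)
  dat <- utils::read.table(text = lines[-hdr], header = TRUE, sep = "\t")
  timeseries(t(as.matrix(dat)), fs = fs, channel_names = colnames(dat))
}

#' Write an NPD result as a delimited table
#'
#' Columns: frequency, coherence, forward, reverse, zero. Scalar components,
#' the channel pair, any conditioning reference and surrogate thresholds go
#' into `#`-prefixed metadata header lines.
#'
#' @param res an `"npd_result"`.
#' @param path output path.
#' @param threshold optional surrogate threshold recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_npd_table <- function(res, path, threshold = NULL) {
  stopifnot(inherits(res, "npd_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pair: %d->%d", res$pair[1], res$pair[2]), con)
  if (!is.null(res$ref_channel))
    writeLines(sprintf("# conditioned_on: %d", res$ref_channel), con)
  writeLines(sprintf("# scalar_reverse: %.10g", res$scalar["reverse"]), con)
  writeLines(sprintf("# scalar_zero: %.10g", res$scalar["zero"]), con)
  writeLines(sprintf("# scalar_forward: %.10g", res$scalar["forward"]), con)
  if (!is.null(threshold)) writeLines(sprintf("# threshold: %.10g", threshold), con)
  df <- data.frame(freq = res$freqs, coherence = res$coherence,
                   forward = res$forward, reverse = res$reverse, zero = res$zero)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML configuration with blocks `simulation` (edges, lags, coupling,
#' peak_hz, fs, n_samples, seed), `observation` (snr_db, shared_variance,
#' band), `estimation` (seg_len, methods, condition_on), `surrogates`
#' (n, percentile). Unknown top-level keys are rejected.
#'
#' @param path YAML file path, or a list already in memory.
#' @return A validated config list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  known <- c("experiment", "simulation", "observation", "estimation",
             "surrogates", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg$simulation <- cfg$simulation %||% list()
  cfg$estimation <- cfg$estimation %||% list()
  cfg$surrogates <- cfg$surrogates %||% list()
  sim <- cfg$simulation
  cfg$simulation$fs <- sim$fs %||% 200
  cfg$simulation$n_samples <- sim$n_samples %||% 5e4
  cfg$simulation$seed <- sim$seed %||% 1
  cfg$simulation$coupling <- sim$coupling %||% 0.5
  cfg$simulation$peak_hz <- sim$peak_hz %||% 55
  cfg$estimation$seg_len <- cfg$estimation$seg_len %||% 256
  cfg$surrogates$n <- cfg$surrogates$n %||% 1000
  cfg$surrogates$percentile <- cfg$surrogates$percentile %||% 99.9
  class(cfg) <- "run_config"
  cfg
}

config_model <- function(cfg) {
  sim <- cfg$simulation
  if (is.null(sim$edges)) stop("config simulation block needs an 'edges' list")
  ed <- do.call(rbind, lapply(sim$edges, function(e)
    data.frame(from = e$from, to = e$to, lag = e$lag %||% 2)))
  n_nodes <- sim$n_nodes %||% max(ed$from, ed$to)
  build_periodic_model(directed_graph(n_nodes, ed), coupling = sim$coupling,
                       peak_hz = sim$peak_hz, fs = sim$fs)
}

#' Simulate from a configuration and write the result
#'
#' @param config path to a YAML config or a config list.
#' @param out output file for the simulated (optionally observed) series.
#' @return The written [timeseries()], invisibly.
#' @export
cli_simulate <- function(config, out) {
  cfg <- read_run_config(config)
  model <- config_model(cfg)
  sim <- cfg$simulation
  x <- simulate_mvar(model, sim$n_samples, seed = sim$seed, fs = sim$fs)
  obs <- cfg$observation
  if (!is.null(obs)) {
    band <- obs$band %||% c(50, 60)
    lam <- 0
    if (!is.null(obs$snr_db))
      lam <- vapply(seq_len(n_channels(x)), function(ch)
        lambda_for_snr(x, ch, obs$snr_db, band = band,
                       seg_len = cfg$estimation$seg_len), 0)
    L <- NULL
    if (!is.null(obs$shared_variance) && obs$shared_variance > 0)
      L <- calibrate_mixing(x, obs$shared_variance)
    x <- observe(x, observation_spec(mixing = L, noise_scale = lam, snr_band = band),
                 seed = child_seed(sim$seed, 1))
  }
  write_timeseries(x, out, extra = list(seed = sim$seed,
                                        config_hash = config_hash(cfg)))
  invisible(x)
}

#' Analyze a time series from a configuration and write result tables
#'
#' Writes coherence + NPD tables per channel pair (and conditioned NPD when
#' `estimation$condition_on` names a reference channel), plus pairwise NPG
#' tables, into `out_dir`. Surrogate thresholds are recorded in each table's
#' metadata when `surrogates$n > 0`.
#'
#' @param x a [timeseries()] or a path readable by [read_timeseries()].
#' @param config config path or list.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of written files, invisibly.
#' @export
cli_analyze <- function(x, config, out_dir) {
  cfg <- read_run_config(config)
  if (is.character(x)) x <- read_timeseries(x)
  if (n_channels(x) < 2L) stop("need at least 2 channels to analyze")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seg_len <- cfg$estimation$seg_len
  ref <- cfg$estimation$condition_on
  if (!is.null(ref) && (ref < 1 || ref > n_channels(x)))
    stop(sprintf("condition_on channel %s does not exist (have %d channels)",
                 ref, n_channels(x)))
  S <- spectral_matrix(x, seg_len = seg_len)
  nsur <- cfg$surrogates$n
  files <- character()
  N <- n_channels(x)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      d <- npd_decompose(S, i, j)
      thr <- NULL
      if (nsur > 0)
        thr <- permutation_threshold(
          function(s) npd_decompose(spectral_matrix(s, seg_len = seg_len), i, j)$forward[-1],
          x, n = nsur, percentile = cfg$surrogates$percentile,
          seed = child_seed(cfg$simulation$seed, 50 + i * 10 + j))[1]
      f <- file.path(out_dir, sprintf("NPD_%d_%d.tsv", i, j))
      write_npd_table(d, f, threshold = thr)
      files[sprintf("npd_%d_%d", i, j)] <- f
      if (!is.null(ref) && ref != i && ref != j) {
        dcond <- conditioned_npd(S, i, j, ref = ref)
        f <- file.path(out_dir, sprintf("NPDcond_%d_%d_%d.tsv", ref, i, j))
        write_npd_table(dcond, f)
        files[sprintf("npdcond_%d_%d", i, j)] <- f
      }
      g <- pairwise_npg(S, i, j)
      f <- file.path(out_dir, sprintf("NPG_%d_%d.tsv", i, j))
      df <- data.frame(freq = g$freqs,
                       forward = g$granger$forward, reverse = g$granger$reverse,
                       instantaneous = g$instantaneous)
      con <- file(f, "w")
      writeLines(sprintf("# pair: %d->%d", i, j), con)
      utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
      close(con)
      files[sprintf("npg_%d_%d", i, j)] <- f
    }
  }
  invisible(files)
}

#' Run the graph-recovery benchmark from a configuration
#'
#' Per-graph results are checkpointed as individual TSV rows in `out_dir`;
#' an interrupted run resumes without recomputing finished graphs.
#'
#' @param config config path or list; the `simulation` block may carry
#'   `n_graphs`, `n_edges`, `n_nodes`, `trial_len`, `n_trials`; `estimation$method`
#'   picks the estimator.
#' @param out_dir output directory.
#' @return data.frame of per-graph scores, invisibly.
#' @export
cli_benchmark <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$simulation
  n_graphs <- sim$n_graphs %||% 3
  n_edges <- sim$n_edges %||% 1
  n_nodes <- sim$n_nodes %||% 3
  method <- cfg$estimation$method %||% "npd"
  rows <- vector("list", n_graphs)
  for (gidx in seq_len(n_graphs)) {
    ck <- file.path(out_dir, sprintf("graph_%03d.tsv", gidx))
    if (file.exists(ck)) {
      rows[[gidx]] <- utils::read.table(ck, header = TRUE, sep = "\t")
      next
    }
    graph <- random_graph(n_nodes, n_edges, seed = child_seed(sim$seed, gidx))
    res <- run_benchmark(list(graph), method = method,
                         seed = child_seed(sim$seed, 1000 + gidx),
                         trial_len = sim$trial_len %||% 256,
                         n_trials = sim$n_trials %||% 100,
                         fs = sim$fs, coupling = sim$coupling,
                         peak_hz = sim$peak_hz,
                         n_surrogates = cfg$surrogates$n,
                         percentile = cfg$surrogates$percentile)[[1]]
    row <- data.frame(graph = gidx, method = method,
                      raw_score = res$raw_score,
                      percent_score = res$percent_score)
    utils::write.table(row, ck, sep = "\t", row.names = FALSE, quote = FALSE)
    rows[[gidx]] <- row
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, file.path(out_dir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(out)
}

# Stable short hash of a config (order-independent within blocks).
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}
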