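#' Write / read a multi-subject ROI time-series set as delimited text
#'
#' On disk the set is a directory with `meta.json` (sampling rate, node
#' labels, subject ids) and one `<subject>.csv` per subject (rows = samples,
#' columns = nodes, header = node labels). Round-tripping is exact to the
#' printed precision (15 significant digits).
#'
#' @param ts a [roi_timeseries_set()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_timeseries <- function(ts, dir) {
  stopifnot(inherits(ts, "roi_timeseries_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(fs = ts$fs, labels = ts$labels, subjects = names(ts$data))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in names(ts$data)) {
    m <- t(ts$data[[s]])
    colnames(m) <- ts$labels
    utils::write.csv(format(m, digits = 15, trim = TRUE, scientific = TRUE),
                     file.path(dir, paste0(s, ".csv")), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_timeseries
#' @param path directory written by [write_timeseries()].
#' @return For `read_timeseries`: a [roi_timeseries_set()].
#' @export
read_timeseries <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop("not a time-series directory (missing meta.json): ", path,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  labels <- meta$labels
  data <- list()
  for (s in meta$subjects) {
    f <- file.path(path, paste0(s, ".csv"))
    if (!file.exists(f) || file.size(f) == 0) {
      stop(sprintf("subject %s: file missing or empty (%s)", s, f),
           call. = FALSE)
    }
    m <- utils::read.csv(f, check.names = FALSE)
    missing_cols <- setdiff(labels, colnames(m))
    if (length(missing_cols) > 0) {
      stop(sprintf("subject %s: missing node column(s) %s", s,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    data[[s]] <- t(as.matrix(m[, labels, drop = FALSE]))
  }
  roi_timeseries_set(data, fs = meta$fs, labels = labels)
}

#' Assemble and validate a pipeline run configuration
#'
#' A run is fully described by: the input (either a time-series directory or
#' a [synth_config()]), the carrier grid, Morse parameters, connectivity
#' options, the density grid, null-model replication count, the PRE/POST
#' design (optional), and one master seed. All randomness derives from the
#' seed (no wall-clock seeding), so reruns are bit-identical.
#'
#' @param input_dir directory readable by [read_timeseries()], or `NULL` to
#'   generate data from `synth`.
#' @param synth a [synth_config()] (used when `input_dir` is `NULL`).
#' @param grid a [carrier_frequencies()] grid.
#' @param morse [morse_params()].
#' @param density_grid densities in percent.
#' @param rectify_negative see [build_adjacency()].
#' @param n_reps random-null realizations per curve cell.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, synth = NULL,
                       grid = carrier_frequencies(),
                       morse = morse_params(), density_grid = 1:100,
                       rectify_negative = TRUE, n_reps = 10L, seed = 1L,
                       out_dir = tempfile("swpnet_run_")) {
  if (is.null(input_dir) && is.null(synth)) {
    stop("provide input_dir or a synth_config", call. = FALSE)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  fs <- if (!is.null(synth)) synth$fs else {
    jsonlite::read_json(file.path(input_dir, "meta.json"),
                        simplifyVector = TRUE)$fs
  }
  if (max(grid$frequencies_hz) >= fs / 2) {
    stop(sprintf("top carrier %.4g Hz is at/above Nyquist (%g Hz)",
                 max(grid$frequencies_hz), fs / 2), call. = FALSE)
  }
  structure(list(input_dir = input_dir, synth = synth, grid = grid,
                 morse = morse, density_grid = density_grid,
                 rectify_negative = rectify_negative,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Recognized keys mirror the [run_config()] arguments, with nested
#' `grid: {min_exp, max_exp, step}`, `morse: {gamma, beta}`,
#' `density: {min, max, step}` and `synth: {...}` sections.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  g <- raw$grid %||% list()
  grid <- carrier_frequencies(g$min_exp %||% 0.5, g$max_exp %||% 6,
                              g$step %||% 0.25)
  m <- raw$morse %||% list()
  morse <- morse_params(m$gamma %||% 3, m$beta %||% (25 / 3))
  d <- raw$density %||% list()
  density_grid <- seq(d$min %||% 1, d$max %||% 100, by = d$step %||% 1)
  synth <- NULL
  if (!is.null(raw$synth)) {
    sc <- raw$synth
    bb <- sc$backbone %||% list()
    backbone <- backbone_spec(bb$kind %||% "watts_strogatz",
                              n = sc$n_nodes %||% 20L,
                              k = bb$k %||% 4L,
                              p_rewire = bb$p_rewire %||% 0.1,
                              weight_dist = bb$weight_dist %||% c(1, 1))
    synth <- synth_config(
      n_subjects = sc$n_subjects %||% 12L, n_nodes = sc$n_nodes %||% 20L,
      fs = sc$fs %||% 256, duration = sc$duration %||% 60,
      backbone = backbone,
      coupling_band_hz = sc$coupling_band_hz %||% 8,
      band_halfwidth_hz = sc$band_halfwidth_hz %||% 2,
      envelope_coupling = sc$envelope_coupling %||% 0.8,
      noise_exponent = sc$noise_exponent %||% 1,
      snr = sc$snr %||% 2, seed = sc$seed %||% raw$seed %||% 1L)
  }
  run_config(input_dir = raw$input_dir, synth = synth, grid = grid,
             morse = morse, density_grid = density_grid,
             rectify_negative = raw$rectify_negative %||% TRUE,
             n_reps = raw$n_reps %||% 10L, seed = raw$seed %||% 1L,
             out_dir = raw$out_dir %||% tempfile("swpnet_run_"))
}

config_hash <- function(config) {
  s <- config
  s$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(utils::capture.output(dput(unclass(s))), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Tidy long-format export of a curve set
#'
#' @param curves a `swp_curve_set` from [metric_density_curves()].
#' @return data.frame with columns subject, carrier_hz, density_pct, swp,
#'   sigma, unreliable, edgeless.
#' @export
curves_to_df <- function(curves) {
  d <- dim(curves$swp)
  idx <- expand.grid(subject = seq_len(d[1]), carrier = seq_len(d[2]),
                     density = seq_len(d[3]))
  data.frame(subject = idx$subject,
             carrier_hz = curves$carriers_hz[idx$carrier],
             density_pct = curves$density_grid[idx$density],
             swp = curves$swp[as.matrix(idx)],
             sigma = curves$sigma[as.matrix(idx)],
             unreliable = curves$unreliable[as.matrix(idx)],
             edgeless = curves$edgeless[as.matrix(idx)])
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load or synthesize ROI time series; (2) wavelet transform
#' and orthogonalized envelope connectivity (adjacency stack); (3)
#' consistency thresholding across the density grid; (4) SWP and sigma
#' density curves; (5) statistics — repeated-measures ANOVA over carriers
#' on average connectivity with Tukey HSD and the Bonferroni display
#' threshold. Every artifact is written under `config$out_dir` as CSV/TSV,
#' with a JSON manifest carrying the config hash, per-file checksums and
#' accumulated warnings. Rerunning with an unchanged config and existing,
#' checksum-matching outputs is a no-op resume.
#'
#' @param config a [run_config()].
#' @return The manifest (list, also written to `manifest.json`), invisibly
#'   carrying the in-memory results as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest_file <- file.path(config$out_dir, "manifest.json")
  if (file.exists(manifest_file)) {
    old <- jsonlite::read_json(manifest_file, simplifyVector = TRUE)
    files <- file.path(config$out_dir, names(old$checksums))
    if (identical(old$config_hash, unname(hash)) && all(file.exists(files)) &&
        identical(unname(tools::md5sum(files)),
                  unname(unlist(old$checksums)))) {
      old$resumed <- TRUE
      return(old)
    }
  }
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  # stage 1: input
  if (!is.null(config$input_dir)) {
    ts <- read_timeseries(config$input_dir)
    truth <- NULL
  } else {
    gen <- generate_roi_timeseries(config$synth)
    ts <- gen$ts
    truth <- gen$truth
  }

  # stage 2: spectra + adjacency
  stack <- build_adjacency_stack(ts, config$grid, config$morse,
                                 rectify_negative = config$rectify_negative)
  rect_frac <- mean(stack$weights == 0) -
    1 / stack$n_nodes  # diagonal share of zeros
  note(sprintf("zero/rectified weight fraction: %.3f", max(rect_frac, 0)))

  # stage 3: consistency sweep
  sweep <- consistency_threshold(stack, config$density_grid)

  # stage 4: curves
  curves <- withCallingHandlers(
    metric_density_curves(sweep, stack, seed = config$seed,
                          n_reps = config$n_reps),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      note(trimws(conditionMessage(m))); invokeRestart("muffleMessage")
    })
  note(sprintf("unreliable (>5%% unreachable) curve cells: %d",
               sum(curves$unreliable)))

  # stage 5: statistics across carriers
  conn <- t(vapply(seq_len(stack$n_subjects), function(s) {
    vapply(seq_along(stack$carriers_hz), function(ci) {
      average_connectivity(stack$weights[s, ci, , ])
    }, numeric(1))
  }, numeric(length(stack$carriers_hz))))
  anova_res <- rm_anova(conn)
  tukey <- tukey_hsd_within(conn)
  bonf <- bonferroni_threshold(0.05, length(stack$carriers_hz))

  # outputs
  out <- function(name) file.path(config$out_dir, name)
  utils::write.csv(curves_to_df(curves), out("swp_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(carrier_hz = stack$carriers_hz,
                              mean_connectivity = colMeans(conn)),
                   out("average_connectivity.csv"), row.names = FALSE)
  utils::write.csv(tukey, out("tukey_p.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    el <- which(upper.tri(truth$weights) & truth$weights > 0,
                arr.ind = TRUE)
    utils::write.table(
      data.frame(node_i = el[, 1], node_j = el[, 2],
                 weight = truth$weights[el]),
      out("truth_edges.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("swpnet")),
    config_hash = unname(hash),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    anova = list(f = anova_res$f_stat, df_num = anova_res$df_num,
                 df_den = anova_res$df_den, p_gg = anova_res$p_gg,
                 gg_epsilon = anova_res$gg_epsilon),
    bonferroni_display = bonf$display,
    warnings = warnings,
    resumed = FALSE,
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files))[
      order(files)] |> stats::setNames(sort(files)))
  )
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA)
  attr(manifest, "results") <- list(ts = ts, truth = truth, stack = stack,
                                    sweep = sweep, curves = curves,
                                    anova = anova_res, tukey = tukey)
  manifest
}

#' Minimal command-line entry point
#'
#' Verbs: `synth --config <file> --out <dir>` (generate and write a
#' synthetic time-series set) and `run --config <file>` (full pipeline).
#' Used by the `inst/cli/swpnet` wrapper script.
#'
#' @param args character vector, e.g. `c("run", "--config", "cfg.yaml")`.
#' @return exit status (0 on success), invisibly.
#' @export
swpnet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: swpnet <synth|run> --config <yaml|json> [--out <dir>]"
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  verb <- args[1]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
  }
  cfg_path <- opt("--config")
  if (is.null(cfg_path)) { message(usage); return(invisible(1L)) }
  config <- load_run_config(cfg_path)
  if (!is.null(opt("--out"))) config$out_dir <- opt("--out")
  if (verb == "synth") {
    if (is.null(config$synth)) stop("config has no synth section",
                                    call. = FALSE)
    gen <- generate_roi_timeseries(config$synth)
    write_timeseries(gen$ts, config$out_dir)
    message("wrote ", length(gen$ts$data), " subjects to ", config$out_dir)
  } else if (verb == "run") {
    m <- run_pipeline(config)
    message("pipeline finished; manifest at ",
            file.path(config$out_dir, "manifest.json"))
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
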