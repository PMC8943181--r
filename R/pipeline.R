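# End-to-end orchestration: simulate -> process -> summarize -> expose ->
# stats -> report, with a manifest and a run log.

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. With `input_dir = NULL` the
#' pipeline simulates `n_ops` operations from `sim` (SES assignment by
#' blocked randomization; approach and location alternate deterministically);
#' otherwise it reads series written by [write_ion_series()] from
#' `input_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param registry Registry path or `"packaged"`.
#' @param input_dir Directory of series CSVs + sidecars, or `NULL` to
#'   simulate.
#' @param n_ops Number of synthetic operations when simulating.
#' @param duration Synthetic operation duration, seconds.
#' @param sim A [sim_config()], or `NULL` for
#'   [sim_config_from_registry()] defaults.
#' @param exposure An [exposure_params()].
#' @param factors Factors to compare in the stats stage.
#' @param responses Response fields for comparisons and decomposition.
#' @param K Channels per operation for [max_time_distribution()].
#' @param alpha Significance level, in (0, 1).
#' @param seed Integer seed controlling the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            registry = "packaged",
                            input_dir = NULL,
                            n_ops = 12,
                            duration = 600,
                            sim = NULL,
                            exposure = exposure_params(),
                            factors = c("ses", "approach"),
                            responses = c("harmful_total_mean_ppb",
                                          "total_voc_max_ppb"),
                            K = 100,
                            alpha = 0.05,
                            seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("validation error: alpha must be in (0, 1)")
  if (!identical(registry, "packaged") && !file.exists(registry)) {
    stop("validation error: registry path does not exist: ", registry)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("validation error: input_dir does not exist: ", input_dir)
  }
  if (is.null(input_dir) && n_ops < 4) {
    stop("validation error: n_ops must be >= 4 for the stats stage")
  }
  structure(list(out_dir = out_dir, registry = registry,
                 input_dir = input_dir, n_ops = n_ops, duration = duration,
                 sim = sim, exposure = exposure, factors = factors,
                 responses = responses, K = K, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full exposure-analysis pipeline
#'
#' Stages: (1) obtain per-operation series (simulated or read from disk);
#' (2) blank-subtract and calibrate; (3) summarize each operation;
#' (4) exposure stage — dose table from mean concentrations, exceedance
#' screen from pooled per-compound maxima; (5) statistics — two-group
#' comparisons, effect decomposition, time-of-maximum distribution;
#' (6) write all artifacts with a MANIFEST and run log. Deterministic given
#' the configuration (identical config + seed gives byte-identical tables).
#'
#' @param config A [pipeline_config()].
#' @param force Overwrite an existing output directory's artifacts.
#' @return Invisibly, a list with `manifest` (files written), `summaries`,
#'   and the stats results.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest_path <- file.path(out, "MANIFEST")
  if (file.exists(manifest_path) && !force) {
    stop("validation error: output directory already contains a run; ",
         "use force = TRUE to overwrite")
  }
  registry <- if (identical(config$registry, "packaged")) {
    load_registry()
  } else {
    load_registry(config$registry)
  }
  log_lines <- c(sprintf("orsmoke run, seed %d", config$seed),
                 sprintf("registry: %s (%d compounds)",
                         attr(registry, "version"), nrow(registry)))
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, name)
    path
  }

  # -- stage 1: series ------------------------------------------------------
  if (is.null(config$input_dir)) {
    sim <- if (is.null(config$sim)) {
      sim_config_from_registry(registry)
    } else config$sim
    ses <- randomize_operations(config$n_ops, 4, seed = config$seed)
    designs <- lapply(seq_len(config$n_ops), function(i) {
      operation_design(sprintf("op%03d", i),
                       approach = if (i %% 2 == 1) "open" else "minimally_invasive",
                       ses = ses[i],
                       location = if (i %% 4 %in% c(1, 2)) "surgeon_level"
                                  else "room_air",
                       duration = config$duration)
    })
    sims <- lapply(seq_along(designs), function(i) {
      simulate_operation(designs[[i]], sim, seed = config$seed + i)
    })
    series <- lapply(sims, `[[`, "series")
    log_lines <- c(log_lines,
                   sprintf("simulated %d operations (duration %g s)",
                           length(series), config$duration))
    standards <- sim$calib_standard_ppb
  } else {
    paths <- sort(list.files(config$input_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(paths) == 0) {
      stop("validation error: no series CSVs found in ", config$input_dir)
    }
    series <- lapply(paths, read_ion_series)
    designs <- lapply(series, attr, "design")
    if (any(vapply(designs, is.null, TRUE))) {
      stop("validation error: every input series needs a design in its sidecar")
    }
    log_lines <- c(log_lines, sprintf("read %d operations from %s",
                                      length(series), config$input_dir))
    standards <- NULL
  }

  # -- stage 2+3: process and summarize -------------------------------------
  summaries <- vector("list", length(series))
  for (i in seq_along(series)) {
    s <- series[[i]]
    # calibrate on the raw record (sensitivity factor = standard / calib mean),
    # then remove instrument background; both are linear so the order only
    # matters for exactness of the recovered factor
    if (!is.null(standards) && !is.null(s$segments$calib)) {
      s <- calibrate(s, standards)
    }
    s <- subtract_blank(s)
    summaries[[i]] <- summarize_operation(s, designs[[i]], registry)
  }
  tab <- summaries_table(summaries)
  emit(tab, "summaries.csv")
  log_lines <- c(log_lines, sprintf("summarized %d operations", nrow(tab)))

  # -- stage 4: exposure -----------------------------------------------------
  pooled_mean <- Reduce(`+`, lapply(summaries, function(s) {
    stats::setNames(s$channel_stats$mean_ppb, s$channel_stats$channel)
  })) / length(summaries)
  pooled_max <- Reduce(pmax, lapply(summaries, function(s) {
    stats::setNames(s$channel_stats$max_ppb, s$channel_stats$channel)
  }))
  doses <- dose_table(pooled_mean, registry, config$exposure)
  emit(doses, "dose_table.csv")
  exceed <- exceedance_report(pooled_max, registry)
  emit(as.data.frame(exceed), "exceedance.csv")

  # -- stage 5: statistics ---------------------------------------------------
  comparisons <- do.call(rbind, lapply(config$factors, function(f) {
    do.call(rbind, lapply(config$responses, function(r) {
      cr <- compare_groups(summaries, f, r)
      data.frame(factor = f, response = r,
                 level1 = cr$groups$level[1], n1 = cr$groups$n[1],
                 mean1 = cr$groups$mean[1], sd1 = cr$groups$sd[1],
                 level2 = cr$groups$level[2], n2 = cr$groups$n[2],
                 mean2 = cr$groups$mean[2], sd2 = cr$groups$sd[2],
                 mean_difference = cr$mean_difference,
                 p_value = cr$p_value, stringsAsFactors = FALSE)
    }))
  }))
  emit(comparisons, "comparisons.csv")
  decomp <- effect_decomposition(summaries, config$responses[1])
  emit(data.frame(term = c("(intercept)", names(decomp$coefficients)),
                  coefficient_ppb = c(decomp$intercept,
                                      unname(decomp$coefficients)),
                  R = decomp$R, residual_sd = decomp$residual_sd),
       "effect_decomposition.csv")
  maxtime <- max_time_distribution(summaries, K = config$K)
  emit(maxtime$histogram, "max_time_histogram.csv")
  log_lines <- c(log_lines,
                 sprintf("stats: %d comparisons, decomposition R = %.3f, KS p = %.3g",
                         nrow(comparisons), decomp$R, maxtime$p_value))

  # -- stage 6: report, log, manifest ---------------------------------------
  report <- render_report(registry, maxima = pooled_max,
                          exceedance = exceed)
  writeLines(report, file.path(out, "report.txt"))
  written <- c(written, "report.txt")
  writeLines(log_lines, file.path(out, "run.log"))
  written <- c(written, "run.log")
  writeLines(c("complete", written), manifest_path)

  invisible(list(manifest = written, summaries = summaries,
                 comparisons = comparisons, decomposition = decomp,
                 max_time = maxtime, exceedance = exceed,
                 dose_table = doses))
}

#' Render a panel-style text report
#'
#' Emits a harmful-panel table in the source study's layout — one row per
#' compound with average and maximum detected concentration, the applicable
#' exposure limit, and an exceedance flag — followed by a totals row and a
#' footnote section enumerating suspect-limit compounds.
#'
#' @param registry A `compound_table` supplying the panel (its recorded
#'   average/maximum columns are used unless overridden).
#' @param averages,maxima Optional named vectors overriding the per-compound
#'   average and maximum concentrations (ppb).
#' @param exceedance Optional precomputed [exceedance_report()]; computed
#'   from `maxima` (or the registry maxima) otherwise.
#' @return Character vector of report lines, invisibly printable.
#' @export
render_report <- function(registry, averages = NULL, maxima = NULL,
                          exceedance = NULL) {
  stopifnot(inherits(registry, "compound_table"))
  avg <- if (is.null(averages)) {
    stats::setNames(registry$avg_ppb_paper, registry$name)
  } else averages
  mx <- if (is.null(maxima)) {
    stats::setNames(registry$max_ppb_paper, registry$name)
  } else maxima
  lim <- applicable_limit(registry)
  rows <- registry$name[registry$name %in% names(avg) &
                          registry$name %in% names(mx)]
  if (is.null(exceedance)) {
    exceedance <- if (length(rows) > 0) {
      exceedance_report(mx, registry)
    } else {
      structure(data.frame(compound = character(0), exceeds = logical(0)),
                notes = character(0))
    }
  }
  header <- sprintf("%-48s %12s %12s %12s %8s", "Compound",
                    "Avg (ppb)", "Max (ppb)", "Limit (ppb)", "Exceeds")
  lines <- c("Harmful volatile compound panel", header,
             strrep("-", nchar(header)))
  for (nm in rows) {
    ex <- exceedance$exceeds[match(nm, exceedance$compound)]
    lines <- c(lines, sprintf(
      "%-48s %12.2f %12.2f %12s %8s", nm, avg[[nm]], mx[[nm]],
      if (is.na(lim[[nm]])) "unassessed" else format(lim[[nm]]),
      if (isTRUE(ex)) "YES" else ""))
  }
  lines <- c(lines, strrep("-", nchar(header)),
             sprintf("%-48s %12.2f %12.2f", "Total (panel)",
                     sum(avg[rows]), sum(mx[rows])))
  notes <- attr(exceedance, "notes")
  if (length(notes) > 0) {
    lines <- c(lines, "", "Footnotes:",
               unlist(lapply(notes, strwrap, width = 78)))
  }
  lines
}
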