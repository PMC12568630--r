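# Trace CSV format, pipeline driver and run manifests.
#
# The on-disk concentration unit is molar and is named in the column
# headers, so a file can never be silently misread in nM.

.trace_csv_header <- c("trace_id", "time_s", "signal", "signal_kind",
                       "protein_conc_M", "substrate_conc_M",
                       "competitor_conc_M", "replicate")

#' Read a trace set from CSV
#'
#' Expects exactly the columns
#' `trace_id,time_s,signal,signal_kind,protein_conc_M,substrate_conc_M,competitor_conc_M,replicate`
#' with one row per sample; rows of one `trace_id` must be in strictly
#' increasing time order. All concentrations are molar.
#'
#' @param path CSV file path.
#' @param design Design label for the returned set.
#' @return An `slk_traceset`.
#' @export
read_traces <- function(path, design = "platereader") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trace_csv_header, names(df))
  if (length(missing_cols))
    stop("trace CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("trace CSV contains a header but no data")
  num_cols <- c("time_s", "signal", "protein_conc_M", "substrate_conc_M",
                "competitor_conc_M")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) | is.na(df[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   cc, bad[1]))
    df[[cc]] <- v
  }
  ids <- unique(df$trace_id)
  traces <- lapply(ids, function(id) {
    d <- df[df$trace_id == id, ]
    if (any(diff(d$time_s) <= 0)) {
      row <- which(diff(d$time_s) <= 0)[1] + 1L
      stop(sprintf(
        "non-increasing time in trace '%s' at its row %d", id, row))
    }
    trace(d$time_s, d$signal, trace_id = id, kind = d$signal_kind[1],
          protein_conc = d$protein_conc_M[1],
          substrate_conc = d$substrate_conc_M[1],
          competitor_conc = d$competitor_conc_M[1],
          replicate = as.integer(d$replicate[1]))
  })
  trace_set(traces, design = design)
}

#' Write a trace set to CSV
#'
#' Inverse of [read_traces()]; numeric values are written with 15
#' significant digits so a read/write round trip is lossless beyond float
#' formatting.
#'
#' @param set An `slk_traceset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(set, path) {
  stopifnot(inherits(set, "slk_traceset"))
  rows <- lapply(set$traces, function(tr) {
    a <- .trace_annotations(tr)
    data.frame(trace_id = a$trace_id,
               time_s = sprintf("%.15g", tr$time),
               signal = sprintf("%.15g", tr$signal),
               signal_kind = a$kind,
               protein_conc_M = sprintf("%.15g", a$protein_conc),
               substrate_conc_M = sprintf("%.15g", a$substrate_conc),
               competitor_conc_M = sprintf("%.15g", a$competitor_conc),
               replicate = a$replicate)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, package version, input file
#' checksums and a timestamp next to a pipeline's outputs.
#'
#' @param out_dir Output directory.
#' @param config The configuration list used for the run.
#' @param seed The master seed.
#' @param inputs Character vector of input file paths to checksum.
#' @return Path of the written manifest, invisibly.
#' @export
write_manifest <- function(out_dir, config, seed, inputs = character(0)) {
  checksums <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
    character(1))
  manifest <- list(
    package = "slpkinetics",
    version = as.character(utils::packageVersion("slpkinetics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config,
    input_checksums = as.list(checksums))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the simulate / preprocess / fit / Monte Carlo pipeline
#'
#' Drives the full analysis from a configuration (a YAML file path or an
#' equivalent nested list): optionally simulate a dataset from a design
#' template or read traces from CSV, preprocess (average replicates, trim
#' pretrigger, extract the baseline), run the global fit, optionally run
#' Monte Carlo, and write a key-value fit report, a residual CSV and a
#' run manifest to `out_dir`.
#'
#' Configuration sections: `scheme` (required: `model1`, `model2` or
#' `competition`); either `simulate` (with `template`, `truth` as a named
#' list of rates, optional `noise_sd`, `r_free`, `r_bound`,
#' `true_substrate_conc`) or `input` (trace CSV path); optional `fit`
#' (fields of [fit_spec()]); optional `montecarlo` (`n`, `drop_frac`);
#' `out_dir`; `seed`.
#'
#' @param config YAML file path or configuration list.
#' @param quiet Suppress progress messages to stderr.
#' @return A list with the fit (`slk_fit`), the Monte Carlo result (or
#'   `NULL`) and the output paths, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  say <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  if (is.null(config$scheme) ||
      !config$scheme %in% c("model1", "model2", "competition"))
    stop("config validation: 'scheme' must be model1, model2 or ",
         "competition")
  if (is.null(config$simulate) && is.null(config$input))
    stop("config validation: need a 'simulate' or an 'input' section")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  inputs <- character(0)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    truth <- do.call(switch(config$scheme, model1 = model1_params,
                            model2 = model2_params,
                            competition = competition_params),
                     as.list(sim$truth))
    bound <- switch(config$scheme, model1 = "PS",
                    model2 = c("PSstar", "PS"), competition = "PI")
    map <- observable_map(sim$r_free %||% 60, sim$r_bound %||% 220, bound)
    tpl <- design_template(sim$template,
                           protein_concs = sim$protein_concs,
                           substrate_conc = sim$substrate_conc,
                           competitor_concs = sim$competitor_concs,
                           replicates = sim$replicates,
                           grid = sim$grid, noise_sd = sim$noise_sd)
    say("simulate", "design %s, scheme %s, seed %d", sim$template,
        config$scheme, seed)
    set <- generate_traces(tpl, truth, map, seed = seed,
                           true_substrate_conc = sim$true_substrate_conc)
  } else {
    say("read", "reading traces from %s", config$input)
    inputs <- config$input
    set <- read_traces(config$input)
  }

  say("preprocess", "averaging replicates and zeroing times")
  set <- average_replicates(set)
  set <- trim_and_zero(set, 0)

  fit_cfg <- config$fit %||% list()
  spec <- fit_spec(config$scheme,
                   fixed = fit_cfg$fixed %||% list(),
                   s0_adjustable = fit_cfg$s0_adjustable %||% TRUE,
                   s0_rel_bound = fit_cfg$s0_rel_bound %||% 0.5,
                   delay = fit_cfg$delay %||% 0,
                   n_starts = fit_cfg$n_starts %||% 5L)
  say("fit", "global %s fit over %d traces", config$scheme, length(set))
  fit <- slk_fit(set, spec)

  mc <- NULL
  if (!is.null(config$montecarlo)) {
    mcc <- config$montecarlo
    say("montecarlo", "n = %d", as.integer(mcc$n %||% 1000L))
    mc <- monte_carlo_ci(fit, n = as.integer(mcc$n %||% 1000L),
                         drop_frac = mcc$drop_frac %||% 0.05,
                         seed = seed + 1L)
  }

  report_path <- file.path(out_dir, "fit_report.txt")
  est <- coef(fit)
  lines <- c(sprintf("scheme\t%s", config$scheme),
             sprintf("%s\t%.15g", names(est), est),
             sprintf("objective\t%.15g", fit$objective),
             sprintf("residual_sd\t%.15g", fit$residual_sd),
             sprintf("n_points\t%d", fit$n_points),
             sprintf("converged\t%s", fit$converged))
  if (!is.null(mc))
    lines <- c(lines,
               sprintf("mc_sd_%s\t%.15g", names(mc$sd), mc$sd),
               sprintf("mc_ci_low_%s\t%.15g", colnames(mc$ci), mc$ci[1, ]),
               sprintf("mc_ci_high_%s\t%.15g", colnames(mc$ci), mc$ci[2, ]))
  writeLines(lines, report_path)

  resid_path <- file.path(out_dir, "residuals.csv")
  pred <- predict(fit)
  resid_df <- do.call(rbind, Map(function(tr, mu) {
    data.frame(trace_id = attr(tr, "trace_id"),
               time_s = sprintf("%.15g", tr$time),
               observed = sprintf("%.15g", tr$signal),
               fitted = sprintf("%.15g", mu),
               residual = sprintf("%.15g", tr$signal - mu))
  }, fit$set$traces[fit$fit_idx], pred))
  write.csv(resid_df, resid_path, row.names = FALSE, quote = FALSE)

  manifest_path <- write_manifest(out_dir, config, seed, inputs)
  say("report", "wrote %s", report_path)
  invisible(list(fit = fit, mc = mc,
                 paths = list(report = report_path, residuals = resid_path,
                              manifest = manifest_path)))
}
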