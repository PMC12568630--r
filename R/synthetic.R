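# Instrument-faithful synthetic datasets for the standard experimental
# designs, so every pipeline stage can be exercised without raw
# instrument files. The template defaults ARE the study conditions:
# plate-reader FP series (substrate 20 nM, protein 0 and a 2-fold ladder
# from 900 nM; fast variant substrate 2 nM, protein 0 and 0.78-50 nM),
# stopped-flow anisotropy (substrate 0.5 uM, protein 0.25-3.13 uM, 15
# replicates at 1 ms sampling over 2 s), competition (reporter 100 nM,
# competitor 0-1 uM, protein 200 nM) and in-cell ratio traces sampled
# every 30 s.

#' Experimental design templates for synthetic data
#'
#' Encodes one of the standard designs with overridable parameters.
#' Defaults by template:
#' \describe{
#'   \item{platereader_std}{substrate 20 nM; protein 0 and a 2-fold ladder
#'     900 down to 7.03 nM (8 levels); 0-3600 s every 15 s; mP signal.}
#'   \item{platereader_fast}{substrate 2 nM; protein 0 and 2-fold ladder
#'     50 down to 0.78 nM; 0-600 s every 2 s; mP signal.}
#'   \item{stoppedflow}{substrate 0.5 uM; protein 0 and 6 levels
#'     0.25-3.13 uM; 15 replicates; 1 ms sampling over 2 s with 10 ms of
#'     pretrigger baseline samples; anisotropy signal.}
#'   \item{competition}{reporter 100 nM; protein 200 nM; competitor 0 and
#'     0.1-1 uM; 0-300 s every 2 s; mP signal.}
#'   \item{incell}{ratio traces every 30 s over 90 min.}
#'   \item{dilution_series}{1.5-fold serial dilution 7.5-2.22 uM,
#'     absorbance.}
#'   \item{line_profile}{25 nm pixels over +/- 500 nm, intensity.}
#' }
#' The default noise standard deviation is 2% of the free-to-bound
#' dynamic range (set at generation time); `noise_sd = 0` gives noiseless
#' data.
#'
#' @param name Template name (see Details).
#' @param protein_concs Optional protein ladder override (M), including 0
#'   for designs with a baseline trace.
#' @param substrate_conc Optional fluorophore concentration override (M).
#' @param competitor_concs Optional competitor ladder (M), competition
#'   template only.
#' @param replicates Technical replicates per condition.
#' @param grid Optional time grid override (seconds).
#' @param noise_sd Gaussian noise sd in signal units, or `NULL` for the
#'   2%-of-range default.
#' @param pretrigger Stopped-flow only: seconds of pretrigger baseline
#'   samples to prepend (at the sampling rate).
#' @return A list of class `slk_design`.
#' @export
design_template <- function(name = c("platereader_std", "platereader_fast",
                                     "stoppedflow", "competition", "incell",
                                     "dilution_series", "line_profile"),
                            protein_concs = NULL, substrate_conc = NULL,
                            competitor_concs = NULL, replicates = NULL,
                            grid = NULL, noise_sd = NULL,
                            pretrigger = NULL) {
  name <- match.arg(name)
  d <- switch(name,
    platereader_std = list(
      protein_concs = c(0, 900e-9 / 2^(0:7)), substrate_conc = 20e-9,
      replicates = 1L, grid = seq(0, 3600, by = 15), kind = "mP",
      pretrigger = 0),
    platereader_fast = list(
      protein_concs = c(0, 50e-9 / 2^(0:6)), substrate_conc = 2e-9,
      replicates = 1L, grid = seq(0, 600, by = 2), kind = "mP",
      pretrigger = 0),
    stoppedflow = list(
      protein_concs = c(0, 0.25e-6 * (3.13 / 0.25)^((0:5) / 5)),
      substrate_conc = 0.5e-6, replicates = 15L,
      grid = seq(0, 2, by = 0.001), kind = "anisotropy",
      pretrigger = 0.01),
    competition = list(
      protein_concs = c(0, rep(200e-9, 6)), substrate_conc = 100e-9,
      competitor_concs = c(0, 0, 0.1, 0.25, 0.5, 0.75, 1) * 1e-6,
      replicates = 1L, grid = seq(0, 300, by = 2), kind = "mP",
      pretrigger = 0),
    incell = list(
      protein_concs = numeric(0), substrate_conc = 0, replicates = 1L,
      grid = seq(0, 90, by = 0.5), kind = "ratio", pretrigger = 0),
    dilution_series = list(
      protein_concs = numeric(0), substrate_conc = 7.5e-6,
      replicates = 1L, grid = 7.5e-6 / 1.5^(0:3), kind = "absorbance",
      pretrigger = 0),
    line_profile = list(
      protein_concs = numeric(0), substrate_conc = 0, replicates = 1L,
      grid = seq(-500, 500, by = 25), kind = "intensity", pretrigger = 0))
  if (!is.null(protein_concs)) d$protein_concs <- protein_concs
  if (!is.null(substrate_conc)) d$substrate_conc <- substrate_conc
  if (!is.null(competitor_concs)) d$competitor_concs <- competitor_concs
  if (!is.null(replicates)) d$replicates <- as.integer(replicates)
  if (!is.null(grid)) d$grid <- grid
  if (!is.null(pretrigger)) d$pretrigger <- pretrigger
  d$noise_sd <- noise_sd
  d$name <- name
  stopifnot(all(d$protein_concs >= 0), d$replicates >= 1L,
            is.null(d$noise_sd) || d$noise_sd >= 0)
  structure(d, class = "slk_design")
}

# deterministic per-trace substream: adding traces never reshuffles the
# noise of earlier ones
.trace_seed <- function(master, index) {
  (as.integer(master) + 7919L * as.integer(index)) %% 2147483647L
}

#' Generate a synthetic trace set from a design template
#'
#' Simulates the noiseless model signal for every condition of the design
#' and adds i.i.d. Gaussian noise. The design template names the scheme
#' family the truth must belong to: plate-reader templates take
#' [model1_params()], the stopped-flow template takes [model2_params()],
#' the competition template takes [competition_params()] and the in-cell
#' template takes a list with `Y0`, `Ymax`, `t_half` (in the grid's time
#' units) and `H`.
#'
#' @param template A [design_template()].
#' @param truth Ground-truth parameters (see Details).
#' @param map An [observable_map()] (ignored for the in-cell template).
#' @param seed Master seed; per-trace noise streams are derived from it
#'   deterministically.
#' @param true_substrate_conc Optional actual fluorophore concentration
#'   (M) used to simulate, while traces stay annotated with the template's
#'   nominal value — emulates a quantification error that the global fit's
#'   adjustable concentration should recover.
#' @return An `slk_traceset` with attribute `"truth"` recording the
#'   generating parameters.
#' @export
generate_traces <- function(template, truth, map, seed = 1L,
                            true_substrate_conc = NULL) {
  stopifnot(inherits(template, "slk_design"))
  if (template$name == "incell")
    return(.generate_incell(template, truth, seed))
  stopifnot(inherits(map, "slk_observable_map"))
  scheme <- attr(truth, "scheme")
  need <- if (template$name == "competition") "competition" else
          if (template$name == "stoppedflow") c("model1", "model2") else
          "model1"
  if (is.null(scheme) || !(scheme %in% need))
    stop(sprintf("template '%s' requires %s parameters, got '%s'",
                 template$name, paste(need, collapse = " or "),
                 scheme %||% "none"))
  s0_true <- true_substrate_conc %||% template$substrate_conc
  noise_sd <- template$noise_sd %||% (0.02 * (map$r_bound - map$r_free))
  grid <- template$grid
  traces <- list()
  idx <- 0L
  for (ci in seq_along(template$protein_concs)) {
    p0 <- template$protein_concs[ci]
    comp <- if (!is.null(template$competitor_concs))
      template$competitor_concs[ci] else 0
    mu <- if (p0 == 0) rep(map$r_free, length(grid)) else {
      ic <- switch(scheme,
        model1 = initial_conditions(p0, s0_true),
        model2 = initial_conditions(p0, s0_true),
        competition = initial_conditions(p0, S0 = comp, I0 = s0_true))
      traj <- switch(scheme,
        model1 = simulate_model1(truth, ic, grid),
        model2 = simulate_model2(truth, ic, grid),
        competition = simulate_competition(truth, ic, grid))
      bound <- rowSums(as.data.frame(traj)[, map$bound_species,
                                           drop = FALSE])
      map$r_free + (map$r_bound - map$r_free) * bound / s0_true
    }
    # optional pretrigger: baseline-level samples before the trigger
    tpre <- if (template$pretrigger > 0) {
      dt <- grid[2] - grid[1]
      seq(-template$pretrigger, -dt, by = dt)
    } else numeric(0)
    tt <- c(tpre, grid)
    mm <- c(rep(map$r_free, length(tpre)), mu)
    for (r in seq_len(template$replicates)) {
      idx <- idx + 1L
      set.seed(.trace_seed(seed, idx))
      sig <- mm + rnorm(length(mm), 0, noise_sd)
      traces[[idx]] <- trace(tt, sig,
        trace_id = sprintf("%s_P%02d_r%02d", template$name, ci, r),
        kind = template$kind, protein_conc = p0,
        substrate_conc = template$substrate_conc,
        competitor_conc = comp, replicate = r)
    }
  }
  design <- switch(template$name, stoppedflow = "stoppedflow",
                   competition = "competition", "platereader")
  out <- trace_set(traces, design = design)
  attr(out, "truth") <- list(params = truth, map = map,
                             s0_true = s0_true, noise_sd = noise_sd,
                             seed = seed)
  out
}

.generate_incell <- function(template, truth, seed) {
  stopifnot(is.list(truth),
            all(c("Y0", "Ymax", "t_half", "H") %in% names(truth)))
  grid <- template$grid
  mu <- ifelse(grid > 0,
               truth$Y0 + (truth$Ymax - truth$Y0) /
                 (1 + (truth$t_half / grid)^truth$H),
               truth$Y0)
  noise_sd <- template$noise_sd %||% (0.02 * (truth$Ymax - truth$Y0))
  set.seed(.trace_seed(seed, 1L))
  tr <- trace(grid, mu + rnorm(length(mu), 0, noise_sd),
              trace_id = "incell_r01", kind = "ratio")
  out <- trace_set(list(tr), design = "incell")
  attr(out, "truth") <- list(params = truth, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Generate a synthetic Gaussian line profile
#'
#' Samples a Gaussian intensity profile with
#' `omega = fwhm_true / sqrt(2 ln 2)` on the template's pixel grid, plus
#' noise. A 25 nm pixel grid adequately samples widths down to about
#' 60 nm FWHM.
#'
#' @param fwhm_true True full width at half maximum, in the grid's units
#'   (default template: nm).
#' @param template A [design_template()] of name `"line_profile"`.
#' @param amplitude Peak height above offset.
#' @param offset Baseline intensity.
#' @param center Peak center.
#' @param seed Seed for the noise stream.
#' @return A [trace()] of kind `"intensity"`.
#' @export
generate_profile <- function(fwhm_true,
                             template = design_template("line_profile"),
                             amplitude = 1, offset = 0.1, center = 0,
                             seed = 1L) {
  stopifnot(inherits(template, "slk_design"),
            template$name == "line_profile", fwhm_true > 0)
  x <- template$grid
  omega <- fwhm_true / sqrt(2 * log(2))
  mu <- offset + amplitude * exp(-2 * (x - center)^2 / omega^2)
  noise_sd <- template$noise_sd %||% (0.02 * amplitude)
  set.seed(.trace_seed(seed, 1L))
  trace(x, mu + rnorm(length(x), 0, noise_sd),
        trace_id = "line_profile", kind = "intensity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
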