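#' Rate-constant containers for the three kinetic schemes
#'
#' Constructors for the parameter sets of the three mass-action labeling
#' schemes. All rate constants must be non-negative; association rates are
#' second-order (M^-1 s^-1), dissociation and chemical-step rates are
#' first-order (s^-1).
#'
#' @param k_app Apparent second-order labeling rate constant (M^-1 s^-1).
#' @return An object of class `slk_params` (subclassed by scheme) holding
#'   the named rate constants.
#' @examples
#' model1_params(1.51e5)
#' model2_params(k1 = 1e7, k_minus1 = 100, k2 = 100)
#' competition_params(kS_app = 3e6, kI_app = 1e6)
#' @export
model1_params <- function(k_app) {
  stopifnot(is.numeric(k_app), length(k_app) == 1L, is.finite(k_app))
  if (k_app < 0) stop("'k_app' must be >= 0")
  structure(list(k_app = as.numeric(k_app)),
            class = c("slk_model1_params", "slk_params"),
            scheme = "model1")
}

#' @rdname model1_params
#' @param k1 Association rate constant (M^-1 s^-1).
#' @param k_minus1 Dissociation rate constant of the non-covalent complex
#'   (s^-1).
#' @param k2 Rate constant of the irreversible chemical step (s^-1).
#' @export
model2_params <- function(k1, k_minus1, k2) {
  v <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2)
  stopifnot(is.numeric(v), length(v) == 3L, all(is.finite(v)))
  if (any(v < 0)) stop("all model-2 rate constants must be >= 0")
  structure(as.list(as.numeric(v)) |> setNames(names(v)),
            class = c("slk_model2_params", "slk_params"),
            scheme = "model2")
}

#' @rdname model1_params
#' @param kS_app Apparent rate constant of the non-fluorescent competitor
#'   substrate (M^-1 s^-1).
#' @param kI_app Apparent rate constant of the fluorescent reporter
#'   substrate (M^-1 s^-1).
#' @export
competition_params <- function(kS_app, kI_app) {
  v <- c(kS_app = kS_app, kI_app = kI_app)
  stopifnot(is.numeric(v), length(v) == 2L, all(is.finite(v)))
  if (any(v < 0)) stop("all competition rate constants must be >= 0")
  structure(as.list(as.numeric(v)) |> setNames(names(v)),
            class = c("slk_competition_params", "slk_params"),
            scheme = "competition")
}

#' @export
print.slk_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters (%s):\n", attr(x, "scheme")))
  for (nm in names(x)) cat(sprintf("  %-9s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Initial concentrations for a kinetics simulation
#'
#' @param P0 Protein concentration at t = 0 (M).
#' @param S0 Substrate concentration at t = 0 (M). In the competition
#'   scheme, `S0` is the non-fluorescent competitor.
#' @param I0 Fluorescent reporter concentration at t = 0 (M); only used by
#'   the competition scheme.
#' @return A list of class `slk_ic`.
#' @examples
#' initial_conditions(P0 = 100e-9, S0 = 20e-9)
#' @export
initial_conditions <- function(P0, S0, I0 = 0) {
  v <- c(P0 = P0, S0 = S0, I0 = I0)
  stopifnot(is.numeric(v), all(is.finite(v)))
  if (any(v < 0)) stop("initial concentrations must be >= 0")
  structure(as.list(as.numeric(v)) |> setNames(names(v)), class = "slk_ic")
}

#' Composite apparent rate constant of the two-step scheme
#'
#' The two-step scheme P + S <-> PS* -> PS behaves, at concentrations well
#' below `(k_minus1 + k2)/k1`, like a direct second-order reaction with
#' apparent rate constant `k_app = k1 * k2 / (k2 + k_minus1)`.
#'
#' @param params A [model2_params()] object.
#' @return The composite `k_app` (M^-1 s^-1).
#' @examples
#' derive_kapp(model2_params(1e7, 100, 100)) # 5e6
#' @export
derive_kapp <- function(params) {
  stopifnot(inherits(params, "slk_model2_params"))
  if (params$k2 + params$k_minus1 == 0)
    stop("k_app is undefined when k2 + k_minus1 = 0")
  params$k1 * params$k2 / (params$k2 + params$k_minus1)
}

#' Dissociation constant of the non-covalent complex
#'
#' `K_d = k_minus1 / k1`, the affinity of the protein for the substrate in
#' the two-step scheme.
#'
#' @param params A [model2_params()] object.
#' @return `K_d` in M.
#' @examples
#' derive_kd(model2_params(1e7, 10, 50)) # 1e-6 M
#' @export
derive_kd <- function(params) {
  stopifnot(inherits(params, "slk_model2_params"))
  if (params$k1 <= 0) stop("K_d is undefined when k1 = 0")
  params$k_minus1 / params$k1
}
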