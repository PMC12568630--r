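# Numerical integration of the three mass-action schemes.
# Internally everything is molar and seconds. The integrator is lsoda
# (stiffness-switching); the two-step scheme at stopped-flow concentrations
# can be stiff (k2, k_minus1 >> 1/s).

.slk_rtol <- 1e-12
.slk_atol <- 1e-20

.check_grid <- function(grid) {
  stopifnot(is.numeric(grid), length(grid) >= 2L, all(is.finite(grid)))
  if (grid[1] != 0) stop("time grid must start at 0")
  if (any(diff(grid) <= 0)) stop("time grid must be strictly increasing")
  as.numeric(grid)
}

.new_trajectory <- function(time, species, params, ic) {
  out <- data.frame(time = time, species, check.names = FALSE)
  structure(out, class = c("slk_trajectory", "data.frame"),
            params = params, ic = ic)
}

#' Simulate the direct labeling scheme (model 1)
#'
#' Integrates the irreversible second-order scheme P + S -> PS:
#' `d[PS]/dt = k_app [P][S]`, with `[PS](0) = 0`. The closed-form solution
#' [model1_closed_form()] is used to evaluate the trajectory; a purely
#' numerical integration is available with `method = "ode"` and serves as a
#' cross-check of the closed form.
#'
#' @param params A [model1_params()] object.
#' @param ic An [initial_conditions()] object (`I0` must be 0).
#' @param grid Strictly increasing time grid in seconds, starting at 0.
#' @param method `"closed_form"` (default) or `"ode"` (lsoda).
#' @return A data frame of class `slk_trajectory` with columns `time`,
#'   `P`, `S`, `PS` (concentrations in M).
#' @examples
#' tr <- simulate_model1(model1_params(1.51e5),
#'                       initial_conditions(100e-9, 20e-9), seq(0, 600, 5))
#' tail(tr)
#' @export
simulate_model1 <- function(params, ic, grid,
                            method = c("closed_form", "ode")) {
  stopifnot(inherits(params, "slk_model1_params"), inherits(ic, "slk_ic"))
  method <- match.arg(method)
  grid <- .check_grid(grid)
  if (ic$I0 != 0) stop("model 1 has no competitor species; I0 must be 0")
  if (method == "closed_form") {
    ps <- model1_closed_form(params, ic, grid)
  } else {
    rhs <- function(t, y, p) {
      v <- p[["k_app"]] * y[["P"]] * y[["S"]]
      list(c(-v, -v, v))
    }
    y0 <- c(P = ic$P0, S = ic$S0, PS = 0)
    sol <- deSolve::lsoda(y0, grid, rhs, c(k_app = params$k_app),
                          rtol = .slk_rtol, atol = .slk_atol, maxsteps = 100000)
    ps <- sol[, "PS"]
  }
  .new_trajectory(grid,
                  data.frame(P = ic$P0 - ps, S = ic$S0 - ps, PS = ps),
                  params, ic)
}

#' Closed-form product concentration of the direct labeling scheme
#'
#' Analytic solution of the second-order reaction P + S -> PS with product
#' `x(t) = [PS](t)`:
#' unequal concentrations,
#' `x(t) = P0 S0 (1 - exp(-k (P0 - S0) t)) / (P0 - S0 exp(-k (P0 - S0) t))`;
#' equal concentrations, `x(t) = P0^2 k t / (1 + P0 k t)`.
#'
#' @inheritParams simulate_model1
#' @param t Time(s) in seconds (vectorized).
#' @return `[PS](t)` in M.
#' @export
model1_closed_form <- function(params, ic, t) {
  stopifnot(inherits(params, "slk_model1_params"), inherits(ic, "slk_ic"))
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0))
  k <- params$k_app; P0 <- ic$P0; S0 <- ic$S0
  if (P0 == 0 || S0 == 0 || k == 0) return(rep(0, length(t)))
  # switch to the equal-concentration branch when the exponent would lose
  # all precision; expm1 keeps the unequal branch accurate nearby
  if (abs(P0 - S0) <= 1e-12 * max(P0, S0)) {
    P0^2 * k * t / (1 + P0 * k * t)
  } else {
    z <- -k * (P0 - S0) * t
    # when P0 < S0 the exponent grows with t; past ~700 exp() overflows,
    # and the solution has converged to the limiting-reagent plateau
    x <- ifelse(z > 700, min(P0, S0),
                P0 * S0 * -expm1(pmin(z, 700)) /
                  (P0 - S0 * exp(pmin(z, 700))))
    as.numeric(x)
  }
}

#' Simulate the two-step labeling scheme (model 2)
#'
#' Integrates P + S <-> PS* -> PS (reversible binding with rates `k1`,
#' `k_minus1`, then irreversible chemistry with rate `k2`):
#' \deqn{d[P]/dt = -k_1 [P][S] + k_{-1} [PS^*]}
#' \deqn{d[PS^*]/dt = k_1 [P][S] - (k_{-1} + k_2)[PS^*]}
#' \deqn{d[PS]/dt = k_2 [PS^*]}
#'
#' @param params A [model2_params()] object.
#' @inheritParams simulate_model1
#' @return An `slk_trajectory` with columns `time`, `P`, `S`, `PSstar`,
#'   `PS`.
#' @export
simulate_model2 <- function(params, ic, grid) {
  stopifnot(inherits(params, "slk_model2_params"), inherits(ic, "slk_ic"))
  grid <- .check_grid(grid)
  if (ic$I0 != 0) stop("model 2 has no competitor species; I0 must be 0")
  rhs <- function(t, y, p) {
    bind <- p[["k1"]] * y[["P"]] * y[["S"]] - p[["k_minus1"]] * y[["PSstar"]]
    chem <- p[["k2"]] * y[["PSstar"]]
    list(c(-bind, -bind, bind - chem, chem))
  }
  y0 <- c(P = ic$P0, S = ic$S0, PSstar = 0, PS = 0)
  sol <- deSolve::lsoda(y0, grid, rhs, unlist(params),
                        rtol = .slk_rtol, atol = .slk_atol, maxsteps = 100000)
  .new_trajectory(grid, as.data.frame(sol[, c("P", "S", "PSstar", "PS")]),
                  params, ic)
}

#' Simulate the two-substrate competition scheme
#'
#' Integrates the parallel irreversible labeling by a non-fluorescent
#' competitor S and a fluorescent reporter I:
#' `d[PS]/dt = kS_app [P][S]`, `d[PI]/dt = kI_app [P][I]`, with the protein
#' consumed by both channels. Both product fluxes are mass-action in the
#' free protein and the respective free substrate, which is the only form
#' that conserves protein and substrate mass for the scheme
#' P + S -> PS, P + I -> PI.
#'
#' @param params A [competition_params()] object.
#' @inheritParams simulate_model1
#' @return An `slk_trajectory` with columns `time`, `P`, `S`, `I`, `PS`,
#'   `PI`.
#' @export
simulate_competition <- function(params, ic, grid) {
  stopifnot(inherits(params, "slk_competition_params"), inherits(ic, "slk_ic"))
  grid <- .check_grid(grid)
  rhs <- function(t, y, p) {
    vs <- p[["kS_app"]] * y[["P"]] * y[["S"]]
    vi <- p[["kI_app"]] * y[["P"]] * y[["I"]]
    list(c(-vs - vi, -vs, -vi, vs, vi))
  }
  y0 <- c(P = ic$P0, S = ic$S0, I = ic$I0, PS = 0, PI = 0)
  sol <- deSolve::lsoda(y0, grid, rhs, unlist(params),
                        rtol = .slk_rtol, atol = .slk_atol, maxsteps = 100000)
  .new_trajectory(grid, as.data.frame(sol[, c("P", "S", "I", "PS", "PI")]),
                  params, ic)
}
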