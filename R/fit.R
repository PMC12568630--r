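# Global fitting of concentration series to the mass-action schemes.
#
# Conventions mirrored from the assay workflow: the free-fluorophore
# baseline (r_free) and the per-trace protein concentrations are fixed;
# the shared fluorophore substrate concentration is adjustable within
# relative bounds to absorb quantification errors; rate constants are
# optimized on a log10 scale by bounded Levenberg-Marquardt least squares
# with multi-start.

.rate_names <- list(model1 = "k_app",
                    model2 = c("k1", "k_minus1", "k2"),
                    competition = c("kS_app", "kI_app"))

# second-order rates (M^-1 s^-1) vs first-order (s^-1) bounds, log10
.rate_log_bounds <- function(name) {
  if (name %in% c("k_app", "k1", "kS_app", "kI_app")) c(0, 10) else c(-6, 6)
}

#' Specify a global kinetic fit
#'
#' Collects the scheme, the fixed-parameter conventions and the optimizer
#' settings of a global fit. Defaults follow the assay conventions: the
#' baseline `r_free` and per-trace protein concentrations are fixed, the
#' shared fluorophore concentration is adjustable within `s0_rel_bound`
#' of nominal, and rate constants are free within wide bounds
#' (second-order rates 1–1e10 M^-1 s^-1, first-order rates 1e-6–1e6 s^-1).
#'
#' @param scheme `"model1"`, `"model2"` or `"competition"`.
#' @param fixed Named list of parameters to fix (e.g.
#'   `list(kI_app = 1e6)` to fix the reporter rate of a competition fit,
#'   or any rate constant of the scheme).
#' @param s0_adjustable Should the shared fluorophore concentration be
#'   co-fitted?
#' @param s0_rel_bound Relative bound on the adjustable concentration
#'   (0.5 means within ±50% of nominal).
#' @param delay Fixed instrument delay (mixing dead time) in seconds,
#'   added to the data times when evaluating the model.
#' @param n_starts Number of multi-start initializations (log-spaced over
#'   the free rates).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return A list of class `slk_fit_spec`.
#' @export
fit_spec <- function(scheme = c("model1", "model2", "competition"),
                     fixed = list(), s0_adjustable = TRUE,
                     s0_rel_bound = 0.5, delay = 0, n_starts = 5L,
                     maxiter = 200L) {
  scheme <- match.arg(scheme)
  stopifnot(is.list(fixed), s0_rel_bound > 0, s0_rel_bound < 1,
            delay >= 0, n_starts >= 1L)
  bad <- setdiff(names(fixed), c(.rate_names[[scheme]], "r_bound"))
  if (length(bad))
    stop("fixed parameter(s) not in scheme '", scheme, "': ",
         paste(bad, collapse = ", "))
  structure(list(scheme = scheme, fixed = fixed,
                 s0_adjustable = isTRUE(s0_adjustable),
                 s0_rel_bound = s0_rel_bound, delay = delay,
                 n_starts = as.integer(n_starts),
                 maxiter = as.integer(maxiter)),
            class = "slk_fit_spec")
}

# model signal for one trace given natural-scale parameters
.trace_model_signal <- function(scheme, rates, P0, S0, I0, times, map,
                                r_bound, delay) {
  tt <- times + delay
  grid <- if (tt[1] == 0) tt else c(0, tt)
  bound <- switch(scheme,
    model1 = model1_closed_form(model1_params(rates[["k_app"]]),
                                initial_conditions(P0, S0), tt),
    model2 = {
      traj <- simulate_model2(
        model2_params(rates[["k1"]], rates[["k_minus1"]], rates[["k2"]]),
        initial_conditions(P0, S0), grid)
      b <- rowSums(as.data.frame(traj)[, map$bound_species, drop = FALSE])
      if (tt[1] == 0) b else b[-1]
    },
    competition = {
      traj <- simulate_competition(
        competition_params(rates[["kS_app"]], rates[["kI_app"]]),
        initial_conditions(P0, S0 = I0, I0 = S0), grid)
      # here S0 argument of the scheme holds the competitor, I0 the
      # fluorescent reporter (the trace's substrate)
      b <- traj$PI
      if (tt[1] == 0) b else b[-1]
    })
  fl_total <- S0
  map$r_free + (r_bound - map$r_free) * bound / fl_total
}

# assemble free-parameter vector (transformed), bounds and inverse
.build_parameterization <- function(spec, map, s0_nominal, sig_range,
                                    k_guess) {
  free <- list()   # each: list(name, lower, upper, start_fun(i))
  rates <- .rate_names[[spec$scheme]]
  for (r in setdiff(rates, names(spec$fixed))) {
    lb <- .rate_log_bounds(r)
    free[[paste0("log10_", r)]] <- list(lower = lb[1], upper = lb[2])
  }
  if (spec$s0_adjustable)
    free$s0_mult <- list(lower = 1 - spec$s0_rel_bound,
                         upper = 1 + spec$s0_rel_bound)
  if (!("r_bound" %in% names(spec$fixed)))
    free$r_bound <- list(lower = sig_range[1] - 0.5 * diff(sig_range),
                         upper = sig_range[2] + 3 * diff(sig_range))
  if (!map$r_free_fixed)
    free$r_free <- list(lower = sig_range[1] - diff(sig_range),
                        upper = sig_range[2])
  free
}

# decode transformed vector into natural-scale parameter list
.decode_par <- function(p, spec, map, s0_nominal) {
  rates <- numeric(0)
  for (r in .rate_names[[spec$scheme]]) {
    rates[r] <- if (r %in% names(spec$fixed)) spec$fixed[[r]]
                else 10^p[[paste0("log10_", r)]]
  }
  list(rates = rates,
       S0 = if (spec$s0_adjustable) s0_nominal * p[["s0_mult"]]
            else s0_nominal,
       r_bound = if ("r_bound" %in% names(spec$fixed)) spec$fixed$r_bound
                 else p[["r_bound"]],
       r_free = if (map$r_free_fixed) map$r_free else p[["r_free"]])
}

#' Global fit of a concentration series to a kinetic scheme
#'
#' Fits a single shared parameter vector to all traces of a set
#' simultaneously by minimizing the summed squared residuals. Per-trace
#' protein concentrations are fixed at their nominal values; the baseline
#' `r_free` is fixed at the value extracted from the zero-protein traces
#' (unless the map says otherwise); the shared fluorophore concentration
#' is co-fitted within relative bounds. Zero-protein baseline traces do
#' not enter the objective — they inform the fit only through `r_free`.
#'
#' For the competition scheme the free rate is `kS_app` of the
#' non-fluorescent competitor; the reporter rate `kI_app` is either fixed
#' via `spec$fixed` or co-fitted, which requires a zero-competitor trace
#' in the set.
#'
#' @param set An `slk_traceset` of preprocessed traces (replicates
#'   averaged, times starting at zero).
#' @param spec A [fit_spec()]; defaults to the scheme's conventions.
#' @param map An [observable_map()]; defaults to
#'   [extract_baseline()] applied to `set` with the scheme's default bound
#'   species.
#' @param start Optional named vector on the optimizer's (transformed)
#'   scale, used as the first of the `n_starts` initializations. Names
#'   must match the free parameters; values are clamped into bounds.
#'   Mainly for warm-started refits, e.g. [monte_carlo_ci()].
#' @return An object of class `slk_fit` with components `estimates`
#'   (named list on natural scale, including derived `k_app` and `K_d`
#'   for model 2), `adjusted_S0`, `objective`, `residual_sd`, `converged`,
#'   `n_points`, plus the data and settings needed by the methods
#'   ([predict.slk_fit()], [residuals.slk_fit()], [simulate.slk_fit()],
#'   [plot.slk_fit()]).
#' @examples
#' \donttest{
#' truth <- model1_params(1.51e5)
#' set <- generate_traces(design_template("platereader_std", noise_sd = 0),
#'                        truth, observable_map(60, 220))
#' fit <- slk_fit(set)
#' coef(fit)["k_app"]
#' }
#' @export
slk_fit <- function(set, spec = fit_spec(), map = NULL, start = NULL) {
  stopifnot(inherits(set, "slk_traceset"), inherits(spec, "slk_fit_spec"))
  bound_default <- switch(spec$scheme, model1 = "PS",
                          model2 = c("PSstar", "PS"), competition = "PI")
  if (is.null(map)) map <- extract_baseline(set, bound_default)
  stopifnot(inherits(map, "slk_observable_map"))

  pc <- protein_concs(set)
  fit_idx <- which(pc > 0)
  if (!length(fit_idx)) stop("no traces with protein in set")
  if (spec$scheme == "competition") {
    cc <- vapply(set$traces[fit_idx], function(tr)
      attr(tr, "competitor_conc"), numeric(1))
    if (length(unique(cc)) < 2L)
      warning("fewer than 2 distinct competitor concentrations; ",
              "competition fit may be under-identified")
  } else if (length(unique(pc[fit_idx])) < 2L) {
    warning("fewer than 2 distinct protein concentrations; ",
            "global fit may be under-identified")
  }
  traces <- set$traces[fit_idx]
  s0_nominal <- unique(vapply(traces, function(tr)
    attr(tr, "substrate_conc"), numeric(1)))
  if (length(s0_nominal) != 1L)
    stop("traces do not share a nominal substrate concentration")

  if (spec$scheme == "competition" &&
      !("kI_app" %in% names(spec$fixed))) {
    comp0 <- vapply(traces, function(tr) attr(tr, "competitor_conc"),
                    numeric(1))
    if (!any(comp0 == 0))
      stop("competition fit with free kI_app requires a zero-competitor ",
           "trace")
  }

  all_sig <- unlist(lapply(traces, function(tr) tr$signal))
  sig_range <- range(all_sig)
  free <- .build_parameterization(spec, map, s0_nominal, sig_range, NULL)
  n_points <- sum(vapply(traces, nrow, integer(1)))
  n_free <- length(free)
  lower <- vapply(free, `[[`, numeric(1), "lower")
  upper <- vapply(free, `[[`, numeric(1), "upper")

  resid_fun <- function(p) {
    p <- setNames(as.numeric(p), names(free))
    nat <- .decode_par(p, spec, map, s0_nominal)
    m <- map; m$r_free <- nat$r_free
    unlist(lapply(traces, function(tr) {
      mu <- tryCatch(
        .trace_model_signal(spec$scheme, nat$rates,
                            P0 = attr(tr, "protein_conc"),
                            S0 = nat$S0,
                            I0 = attr(tr, "competitor_conc"),
                            times = tr$time, map = m,
                            r_bound = nat$r_bound, delay = spec$delay),
        error = function(e) NULL)
      # a trial point where the integrator breaks down gets a large
      # finite penalty so the optimizer backs away instead of aborting
      if (is.null(mu) || length(mu) != nrow(tr) || any(!is.finite(mu)))
        return(rep(1e3 * max(1, diff(range(tr$signal))), nrow(tr)))
      tr$signal - mu
    }))
  }

  starts <- .make_starts(spec, free, traces, map, s0_nominal, sig_range)
  if (!is.null(start)) {
    if (!setequal(names(start), names(free)))
      stop("'start' must name exactly the free parameters: ",
           paste(names(free), collapse = ", "))
    st0 <- pmin(pmax(as.numeric(start[names(free)]), lower), upper)
    starts <- c(list(setNames(st0, names(free))), starts)
    starts <- starts[seq_len(spec$n_starts)]
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = spec$maxiter, ftol = 1e-13,
                           ptol = 1e-13, gtol = 0)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("global fit failed to converge from any start")

  p_hat <- setNames(as.numeric(best$par), names(free))
  nat <- .decode_par(p_hat, spec, map, s0_nominal)
  estimates <- as.list(nat$rates)
  if (spec$scheme == "model2") {
    m2 <- model2_params(nat$rates[["k1"]], nat$rates[["k_minus1"]],
                        nat$rates[["k2"]])
    estimates$k_app <- derive_kapp(m2)
    estimates$K_d <- derive_kd(m2)
  }
  estimates$S0 <- nat$S0
  estimates$r_bound <- nat$r_bound
  estimates$r_free <- nat$r_free
  obj <- best$deviance
  structure(list(
    estimates = estimates, adjusted_S0 = nat$S0, objective = obj,
    residual_sd = sqrt(obj / max(1, n_points - n_free)),
    converged = best$info %in% 1:4, n_points = n_points,
    n_free = n_free, free_names = names(free), par = p_hat,
    spec = spec, map = map, set = set, fit_idx = fit_idx,
    s0_nominal = s0_nominal, info = best$info), class = "slk_fit")
}

# data-driven multi-start vectors: rate starts log-spaced around a crude
# half-rise estimate from the highest-protein trace
.make_starts <- function(spec, free, traces, map, s0_nominal, sig_range) {
  pc <- vapply(traces, function(tr) attr(tr, "protein_conc"), numeric(1))
  hi <- traces[[which.max(pc)]]
  sig <- hi$signal
  mid <- (sig[1] + max(sig)) / 2
  idx <- which(sig >= mid)[1]
  t_half <- if (is.na(idx) || idx <= 1L) max(hi$time) / 4 else hi$time[idx]
  k_obs <- log(2) / max(t_half, .Machine$double.eps)
  k2nd_guess <- max(1, min(1e10, k_obs / max(pc)))
  n <- spec$n_starts
  # with a single start, use the central guess, not a grid endpoint
  spread <- function(lo, hi) {
    if (n == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = n)
  }
  grid1 <- function(center, span) {
    v <- log10(center) + spread(-span, span)
    pmin(pmax(v, 0), 10)
  }
  lapply(seq_len(n), function(i) {
    st <- numeric(0)
    for (nm in names(free)) {
      st[nm] <- switch(nm,
        log10_k_app = grid1(k2nd_guess, 2)[i],
        log10_kI_app = grid1(k2nd_guess, 2)[i],
        log10_kS_app = grid1(k2nd_guess, 2)[i],
        log10_k1 = grid1(k2nd_guess * 10, 2)[i],
        log10_k_minus1 = spread(-1, 4)[i],
        log10_k2 = rev(spread(-1, 4))[i],
        s0_mult = 1,
        r_bound = sig_range[2] + 0.1 * diff(sig_range),
        r_free = sig_range[1])
    }
    st
  })
}

#' Global competition fit
#'
#' Convenience wrapper around [slk_fit()] with `scheme = "competition"`:
#' estimates the non-fluorescent competitor rate `kS_app` from the
#' suppression of reporter labeling across competitor concentrations. The
#' reporter rate `kI_app` is fixed if supplied, otherwise co-fitted using
#' the zero-competitor trace.
#'
#' @inheritParams slk_fit
#' @param kI_app Optional known reporter rate constant (M^-1 s^-1).
#' @export
fit_competition <- function(set, kI_app = NULL, spec = NULL, map = NULL) {
  if (is.null(spec))
    spec <- fit_spec("competition",
                     fixed = if (is.null(kI_app)) list()
                             else list(kI_app = kI_app))
  slk_fit(set, spec, map)
}

#' @export
print.slk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Global kinetic fit (%s), %d traces, %d points\n",
              x$spec$scheme, length(x$fit_idx), x$n_points))
  est <- unlist(x$estimates)
  cat("Estimates:\n")
  print(signif(est, digits))
  cat(sprintf("SSR: %.6g   residual sd: %.4g   converged: %s\n",
              x$objective, x$residual_sd, x$converged))
  invisible(x)
}

#' @export
summary.slk_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.slk_fit")
}

#' @export
print.summary.slk_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("Adjusted substrate concentration: %.6g M (nominal %.6g M, %+.2f%%)\n",
              f$adjusted_S0, f$s0_nominal,
              100 * (f$adjusted_S0 / f$s0_nominal - 1)))
  if (f$spec$scheme == "model2")
    cat(sprintf("Composite k_app = %.4g M^-1 s^-1, K_d = %.4g M\n",
                f$estimates$k_app, f$estimates$K_d))
  invisible(x)
}

#' @export
coef.slk_fit <- function(object, ...) unlist(object$estimates)

#' Model predictions for the fitted traces
#'
#' @param object An `slk_fit`.
#' @param ... Unused.
#' @return A list of numeric vectors, one per fitted (non-baseline) trace,
#'   in the order of `object$fit_idx`.
#' @export
predict.slk_fit <- function(object, ...) {
  nat <- .decode_par(object$par, object$spec, object$map,
                     object$s0_nominal)
  m <- object$map; m$r_free <- nat$r_free
  lapply(object$set$traces[object$fit_idx], function(tr)
    .trace_model_signal(object$spec$scheme, nat$rates,
                        P0 = attr(tr, "protein_conc"), S0 = nat$S0,
                        I0 = attr(tr, "competitor_conc"),
                        times = tr$time, map = m, r_bound = nat$r_bound,
                        delay = object$spec$delay))
}

#' @export
residuals.slk_fit <- function(object, ...) {
  pred <- predict(object)
  unlist(Map(function(tr, mu) tr$signal - mu,
             object$set$traces[object$fit_idx], pred))
}

# residual vector at an arbitrary transformed parameter vector; used by
# vcov and kept consistent with the objective minimized in slk_fit
.fit_residuals_at <- function(object, p) {
  p <- setNames(as.numeric(p), object$free_names)
  nat <- .decode_par(p, object$spec, object$map, object$s0_nominal)
  m <- object$map; m$r_free <- nat$r_free
  unlist(lapply(object$set$traces[object$fit_idx], function(tr)
    tr$signal - .trace_model_signal(object$spec$scheme, nat$rates,
                                    P0 = attr(tr, "protein_conc"),
                                    S0 = nat$S0,
                                    I0 = attr(tr, "competitor_conc"),
                                    times = tr$time, map = m,
                                    r_bound = nat$r_bound,
                                    delay = object$spec$delay)))
}

#' Asymptotic covariance of the free parameters
#'
#' Gauss-Newton approximation `sigma^2 (J'J)^-1` with the Jacobian `J`
#' of the residual vector evaluated numerically (central differences) at
#' the optimum. Rows/columns are on the optimizer's scale: rate constants
#' as log10, the shared substrate concentration as a multiple of nominal
#' (`s0_mult`), signal levels in signal units.
#'
#' @param object An `slk_fit`.
#' @param ... Unused.
#' @return Covariance matrix of the transformed free parameters.
#' @export
vcov.slk_fit <- function(object, ...) {
  p <- object$par
  n <- length(p)
  r0 <- .fit_residuals_at(object, p)
  J <- matrix(0, length(r0), n, dimnames = list(NULL, names(p)))
  for (j in seq_len(n)) {
    h <- 1e-6 * max(1, abs(p[j]))
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- p[j] - h
    J[, j] <- (.fit_residuals_at(object, pp) -
                 .fit_residuals_at(object, pm)) / (2 * h)
  }
  object$residual_sd^2 * solve(crossprod(J))
}

#' Simulate datasets from a fitted model
#'
#' Parametric-bootstrap simulator: every trace of the original set
#' (including zero-protein baselines) is replaced by its fitted/model
#' signal plus i.i.d. Gaussian noise at the fit's residual standard
#' deviation. Used by [monte_carlo_ci()].
#'
#' @param object An `slk_fit`.
#' @param nsim Number of simulated trace sets.
#' @param seed Optional integer seed.
#' @param noise_sd Noise level; defaults to `object$residual_sd`.
#' @param ... Unused.
#' @return A list of `nsim` trace sets.
#' @export
simulate.slk_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- object$residual_sd
  pred <- predict(object)
  nat <- .decode_par(object$par, object$spec, object$map,
                     object$s0_nominal)
  mu_all <- vector("list", length(object$set$traces))
  for (j in seq_along(object$set$traces)) {
    k <- match(j, object$fit_idx)
    mu_all[[j]] <- if (!is.na(k)) pred[[k]]
                   else rep(nat$r_free, nrow(object$set$traces[[j]]))
  }
  replicate(nsim, {
    out <- object$set
    out$traces <- Map(function(tr, mu) {
      tr$signal <- mu + rnorm(length(mu), 0, noise_sd)
      tr
    }, object$set$traces, mu_all)
    out
  }, simplify = FALSE)
}

#' Plot a global fit
#'
#' Data points and fitted curves for every fitted trace, on one panel.
#'
#' @param x An `slk_fit`.
#' @param ... Passed to [graphics::matplot()]-style base plotting.
#' @export
plot.slk_fit <- function(x, ...) {
  traces <- x$set$traces[x$fit_idx]
  pred <- predict(x)
  xr <- range(unlist(lapply(traces, function(tr) tr$time)))
  yr <- range(unlist(lapply(traces, function(tr) tr$signal)))
  plot(NA, xlim = xr, ylim = yr, xlab = "time (s)", ylab = "signal", ...)
  cols <- seq_along(traces)
  for (i in seq_along(traces)) {
    points(traces[[i]]$time, traces[[i]]$signal, col = cols[i], pch = 16,
           cex = 0.3)
    lines(traces[[i]]$time, pred[[i]], col = cols[i], lwd = 2)
  }
  legend("bottomright", bty = "n", lwd = 2, col = cols,
         legend = sprintf("[P]0 = %.3g M",
                          vapply(traces, function(tr)
                            attr(tr, "protein_conc"), numeric(1))))
  invisible(x)
}
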