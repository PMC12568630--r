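#' Monte Carlo confidence intervals for a global fit
#'
#' Parametric bootstrap in the style of kinetics-fitting software: `n`
#' synthetic datasets are simulated from the fitted model with Gaussian
#' noise at the fit's residual standard deviation, each is refit (baseline
#' re-extracted from the simulated zero-protein traces, single start at
#' the point estimate), the fraction `drop_frac` of replicates with the
#' highest final objective is excluded ("worst fits"; ties broken by
#' replicate index), and per-parameter standard deviations and percentile
#' 95% intervals are reported from the kept replicates. With
#' `method = "residual"` the noise is instead resampled (with replacement)
#' from the observed residuals.
#'
#' @param fit A converged [slk_fit()].
#' @param n Number of Monte Carlo replicates (>= 100; the conventional
#'   setting is `n = 1000` with 5% of the worst fits excluded, keeping
#'   950).
#' @param drop_frac Fraction of worst refits to exclude.
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param method `"parametric"` (default) or `"residual"`.
#' @return A list of class `slk_mc` with `samples` (matrix, kept
#'   replicates by parameter), `n_requested`, `n_kept`, `sd`, `ci`
#'   (2.5/97.5 percentiles, matrix with rows `low`/`high`).
#' @export
monte_carlo_ci <- function(fit, n = 1000L, drop_frac = 0.05, seed = NULL,
                           method = c("parametric", "residual")) {
  stopifnot(inherits(fit, "slk_fit"), n >= 100L,
            drop_frac >= 0, drop_frac < 1)
  method <- match.arg(method)
  if (!isTRUE(fit$converged))
    stop("Monte Carlo requires a converged fit")
  if (!is.null(seed)) set.seed(seed)

  res <- residuals(fit)
  sets <- if (method == "parametric") {
    simulate(fit, nsim = n)
  } else {
    pred <- predict(fit)
    nat_rf <- fit$estimates$r_free
    replicate(n, {
      out <- fit$set
      for (j in seq_along(out$traces)) {
        k <- match(j, fit$fit_idx)
        mu <- if (!is.na(k)) pred[[k]]
              else rep(nat_rf, nrow(out$traces[[j]]))
        out$traces[[j]]$signal <-
          mu + sample(res, length(mu), replace = TRUE)
      }
      out
    }, simplify = FALSE)
  }

  refit_spec <- fit$spec
  refit_spec$n_starts <- 1L
  start <- fit$par
  param_names <- names(coef(fit))
  samples <- matrix(NA_real_, n, length(param_names),
                    dimnames = list(NULL, param_names))
  objectives <- rep(NA_real_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    rf <- tryCatch(
      .refit_from(sets[[i]], refit_spec, fit, start),
      error = function(e) NULL)
    if (is.null(rf) || !rf$converged) { failed <- failed + 1L; next }
    samples[i, ] <- coef(rf)[param_names]
    objectives[i] <- rf$objective
  }
  if (failed > 0.2 * n)
    stop(sprintf("Monte Carlo unstable: %d/%d replicate fits failed",
                 failed, n))
  ok <- which(!is.na(objectives))
  n_keep <- round(n * (1 - drop_frac))
  # order kept fits by objective; ties resolved by replicate index
  kept <- ok[order(objectives[ok], ok)][seq_len(min(n_keep, length(ok)))]
  samp <- samples[kept, , drop = FALSE]
  cis <- apply(samp, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  rownames(cis) <- c("low", "high")
  structure(list(samples = samp, n_requested = as.integer(n),
                 n_kept = nrow(samp), drop_frac = drop_frac,
                 sd = apply(samp, 2, sd), ci = cis,
                 point = coef(fit), method = method), class = "slk_mc")
}

# single-start refit reusing the parameterization of the reference fit
.refit_from <- function(set, spec, ref_fit, start) {
  bound_default <- switch(spec$scheme, model1 = "PS",
                          model2 = c("PSstar", "PS"), competition = "PI")
  map <- if (ref_fit$map$r_free_fixed)
    extract_baseline(set, bound_default) else ref_fit$map
  map$bound_species <- ref_fit$map$bound_species
  slk_fit(set, spec, map, start = start)
}

#' @export
print.slk_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo CI (%s bootstrap): %d requested, %d kept\n",
              x$method, x$n_requested, x$n_kept))
  tab <- rbind(estimate = x$point[colnames(x$samples)], sd = x$sd, x$ci)
  print(signif(tab, 4))
  invisible(x)
}

#' Propagate duplicate confidence intervals for t_half
#'
#' Combines the half-labeling times of a biological duplicate: the mean
#' `(t1 + t2)/2`; per-replicate standard errors
#' `SE_i = (CI_high - CI_low) / (2 * 1.96)`; the combined standard error
#' `SE_mean = sqrt((SE1^2 + SE2^2) / 2)`; and the 95% interval
#' `mean +/- 1.96 SE_mean`. Note the combined-SE formula divides the sum
#' of squared SEs by 2 under the square root (not by 4, as the textbook
#' standard error of a duplicate mean would); this convention is the
#' default, with `textbook = TRUE` switching to
#' `sqrt(SE1^2 + SE2^2) / 2`.
#'
#' @param t1,t2 Replicate half-labeling times (minutes).
#' @param ci1,ci2 Length-2 95% confidence intervals `(low, high)` for the
#'   replicates.
#' @param textbook Use the textbook standard error of the mean instead of
#'   the conventional form (default `FALSE`).
#' @return A list of class `slk_replicate_summary` with `mean_thalf`,
#'   `se_each`, `se_mean`, `ci`.
#' @examples
#' propagate_duplicate_ci(10, c(8.04, 11.96), 20, c(16.08, 23.92))
#' @export
propagate_duplicate_ci <- function(t1, ci1, t2, ci2, textbook = FALSE) {
  stopifnot(is.numeric(ci1), is.numeric(ci2),
            length(ci1) == 2L, length(ci2) == 2L)
  if (ci1[2] <= ci1[1] || ci2[2] <= ci2[1])
    stop("confidence intervals must satisfy high > low")
  m <- (t1 + t2) / 2
  se1 <- (ci1[2] - ci1[1]) / (2 * 1.96)
  se2 <- (ci2[2] - ci2[1]) / (2 * 1.96)
  se_mean <- if (textbook) sqrt(se1^2 + se2^2) / 2
             else sqrt((se1^2 + se2^2) / 2)
  structure(list(mean_thalf = m, se_each = c(se1, se2), se_mean = se_mean,
                 ci = m + c(-1, 1) * 1.96 * se_mean),
            class = "slk_replicate_summary")
}

#' @export
print.slk_replicate_summary <- function(x, ...) {
  cat(sprintf("Duplicate t1/2: %.4g (95%% CI %.4g - %.4g)\n",
              x$mean_thalf, x$ci[1], x$ci[2]))
  invisible(x)
}
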