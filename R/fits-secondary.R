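# Closed-form secondary analyses used around the global kinetic fits:
# one-phase association (screening k_app), sigmoidal in-cell labeling
# curves, Gaussian line profiles (STED FWHM) and Beer-Lambert extinction
# coefficients.

#' One-phase association fit
#'
#' Fits `Y = Y0 + (Ymax - Y0) (1 - exp(-k x))` to an FP trace, the
#' screening-mode analysis under pseudo-first-order conditions (protein in
#' excess over substrate). The apparent second-order constant follows from
#' [kapp_from_rate()].
#'
#' @param tr A [trace()] with at least 4 points.
#' @return A list of class `slk_one_phase` with `Y0`, `Ymax`, `k` (s^-1)
#'   and the underlying `nls` fit.
#' @examples
#' tt <- seq(0, 600, 10)
#' tr <- trace(tt, 20 + 200 * (1 - exp(-0.01 * tt)))
#' fit_one_phase(tr)$k
#' @export
fit_one_phase <- function(tr) {
  stopifnot(inherits(tr, "slk_trace"), nrow(tr) >= 4L)
  y <- tr$signal; x <- tr$time
  span <- diff(range(y))
  if (span <= 1e-8 * max(abs(y), 1) || span <= 2e-12)
    stop("degenerate fit: trace is flat")
  mid <- y[1] + 0.5 * (y[length(y)] - y[1])
  i <- which((y - mid) * (y[length(y)] - y[1]) >= 0)[1]
  k0 <- log(2) / max(x[max(i, 2L)], diff(range(x)) / 20)
  # nlsLM rather than nls: noiseless traces have zero residual at the
  # optimum, which stats::nls cannot converge on
  fit <- minpack.lm::nlsLM(
    signal ~ Y0 + (Ymax - Y0) * (1 - exp(-k * time)),
    data = as.data.frame(tr),
    start = list(Y0 = y[1], Ymax = y[length(y)], k = k0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  if (abs(cf[["Ymax"]] - cf[["Y0"]]) <= 1e-6 * max(abs(cf), 1))
    stop("degenerate fit: no amplitude")
  structure(list(Y0 = cf[["Y0"]], Ymax = cf[["Ymax"]], k = cf[["k"]],
                 fit = fit), class = "slk_one_phase")
}

#' Apparent second-order rate constant from a pseudo-first-order rate
#'
#' Under excess protein the observed exponential rate is
#' `k = k_app * [protein]`, so `k_app = k / [protein]`.
#'
#' @param k First-order labeling rate (s^-1).
#' @param protein_conc Protein concentration (M), > 0.
#' @return `k_app` in M^-1 s^-1.
#' @examples
#' kapp_from_rate(0.01, 50e-9) # 2e5
#' @export
kapp_from_rate <- function(k, protein_conc) {
  stopifnot(is.numeric(k), is.numeric(protein_conc))
  if (any(protein_conc <= 0)) stop("'protein_conc' must be > 0")
  if (any(k < 0)) stop("'k' must be >= 0")
  k / protein_conc
}

#' Sigmoidal (Hill-type) fit of an in-cell labeling curve
#'
#' Fits `Y = Y0 + (Ymax - Y0) / (1 + (t_half / x)^H)` to a ratiometric
#' in-cell labeling time course. By construction `Y(t_half)` is the
#' midpoint between `Y0` and `Ymax` for any Hill slope `H`. The 95%
#' confidence interval on `t_half` is asymptotic, from the parameter
#' covariance at the optimum.
#'
#' @param tr A [trace()]; time in the units `t_half` is wanted in
#'   (typically minutes), at least 6 points spanning the transition.
#' @return A list of class `slk_sigmoidal` with `Y0`, `Ymax`, `t_half`,
#'   `H`, `ci_thalf` (length-2) and the `nls` fit.
#' @export
fit_sigmoidal <- function(tr) {
  stopifnot(inherits(tr, "slk_trace"), nrow(tr) >= 6L)
  y <- tr$signal; x <- tr$time
  if (diff(range(y)) <= 1e-8 * max(abs(y), 1) || diff(range(y)) <= 2e-12)
    stop("degenerate fit: trace is flat")
  mid <- min(y) + 0.5 * diff(range(y))
  t0 <- x[which(y >= mid)[1]]
  if (is.na(t0) || t0 <= 0) t0 <- median(x[x > 0])
  dat <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ Y0 + (Ymax - Y0) / (1 + (t_half / x)^H),
    data = dat[dat$x > 0, ],
    start = list(Y0 = min(y), Ymax = max(y), t_half = t0, H = 1.5),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))[["t_half"]]
  ci <- cf[["t_half"]] + c(-1, 1) * 1.96 * se
  structure(list(Y0 = cf[["Y0"]], Ymax = cf[["Ymax"]],
                 t_half = cf[["t_half"]], H = cf[["H"]],
                 ci_thalf = ci, fit = fit), class = "slk_sigmoidal")
}

#' Gaussian fit of a 1-D intensity line profile
#'
#' Fits `y = y0 + A / (omega sqrt(pi/2)) exp(-2 (x - xc)^2 / omega^2)` to
#' an intensity profile extracted perpendicular to a filament, and reports
#' the full width at half maximum `FWHM = omega sqrt(2 ln 2)`.
#'
#' @param tr A [trace()] of kind `"intensity"`; `time` holds the spatial
#'   coordinate (nm or um — FWHM comes out in the same units).
#' @return A list of class `slk_gaussian_profile` with `y0`, `A`, `omega`,
#'   `xc`, `fwhm` and the underlying `nls.lm` optimizer result.
#' @examples
#' x <- seq(-300, 300, 25)
#' om <- 108 / sqrt(2 * log(2))
#' tr <- trace(x, 0.1 + exp(-2 * x^2 / om^2), kind = "intensity")
#' fit_gaussian_profile(tr)$fwhm
#' @export
fit_gaussian_profile <- function(tr) {
  stopifnot(inherits(tr, "slk_trace"), nrow(tr) >= 5L)
  x <- tr$time; y <- tr$signal
  base <- min(y)
  amp <- max(y) - base
  if (amp <= 1e-8 * max(abs(y), 1) || amp <= 2e-12)
    stop("degenerate fit: no peak above offset")
  xc0 <- x[which.max(y)]
  # crude width from points above half maximum
  above <- x[y >= base + amp / 2]
  w0 <- max(diff(range(above)), median(diff(x)))
  om0 <- w0 / sqrt(2 * log(2))
  # raw nls.lm rather than nlsLM: a fitted center very close to (but not
  # exactly) zero defeats nlsModel's relative-step numeric gradient
  model <- function(p) p[1] + p[2] / (p[4] * sqrt(pi / 2)) *
    exp(-2 * (x - p[3])^2 / p[4]^2)
  fit <- minpack.lm::nls.lm(
    par = c(y0 = base, A = amp * om0 * sqrt(pi / 2), xc = xc0,
            omega = om0),
    fn = function(p) y - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0L, 9L))
    stop("Gaussian profile fit did not converge: ", fit$message)
  cf <- fit$par
  omega <- abs(cf[["omega"]])
  structure(list(y0 = cf[["y0"]], A = cf[["A"]], omega = omega,
                 xc = cf[["xc"]], fwhm = omega * sqrt(2 * log(2)),
                 fit = fit), class = "slk_gaussian_profile")
}

#' Extinction coefficient from an absorbance dilution series
#'
#' Ordinary least squares of peak absorbance against concentration,
#' `y = a + b x`; Beer-Lambert gives the molar extinction coefficient
#' `epsilon = b / path_length`.
#'
#' @param conc Concentrations (M) of the dilution series, >= 3 distinct
#'   values.
#' @param absorbance Matching absorbance values.
#' @param path_length Cuvette path length in cm (default 0.3).
#' @return A list of class `slk_extinction` with `a`, `b`, `path_length`,
#'   `epsilon` (M^-1 cm^-1) and the `lm` fit.
#' @examples
#' conc <- c(7.5, 5, 3.33, 2.22) * 1e-6
#' fit_extinction(conc, 1e5 * 0.3 * conc)$epsilon # 1e5
#' @export
fit_extinction <- function(conc, absorbance, path_length = 0.3) {
  stopifnot(is.numeric(conc), is.numeric(absorbance),
            length(conc) == length(absorbance), length(conc) >= 3L,
            path_length > 0)
  if (sd(conc) == 0) stop("concentrations have zero variance")
  fit <- lm(absorbance ~ conc)
  b <- unname(coef(fit)[2])
  if (max(abs(absorbance)) == 0)
    warning("all absorbances are zero; epsilon = 0")
  structure(list(a = unname(coef(fit)[1]), b = b,
                 path_length = path_length, epsilon = b / path_length,
                 fit = fit), class = "slk_extinction")
}
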