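#' Absorbance-vs-time decantation series
#'
#' Validates a gravity-decantation time course: optical absorbance of the
#' supernatant (OD 595 nm) at strictly increasing times, at least 5 points.
#'
#' @param times_min sampling times in minutes, strictly increasing, >= 0.
#' @param absorbance optical densities.
#' @return object of class `decay_series`.
#' @export
decay_series <- function(times_min, absorbance) {
  if (length(times_min) != length(absorbance))
    stop("times and absorbance must have equal length")
  if (length(times_min) < 5) stop("need at least 5 time points")
  if (any(times_min < 0) || any(diff(times_min) <= 0))
    stop("times must be non-negative and strictly increasing")
  structure(list(times_min = as.numeric(times_min),
                 absorbance = as.numeric(absorbance)),
            class = "decay_series")
}

decay_curve <- function(X, X0, Y0, Plateau, k)
  ifelse(X < X0, Y0, Plateau + (Y0 - Plateau) * exp(-k * (X - X0)))

#' Simulate a plateau-then-decay series
#'
#' Forward model used in recovery tests: constant `Y0` until `X0`, then
#' exponential decay to `Plateau` with rate `k`, plus optional Gaussian
#' noise. Default times are the 8-point decantation schedule (0-40 min).
#'
#' @param X0,Y0,Plateau,k model parameters (`k` in 1/min).
#' @param times_min sampling times.
#' @param noise_sd additive noise sd.
#' @param seed RNG seed.
#' @return a [decay_series()].
#' @export
simulate_decay <- function(X0 = 0, Y0 = 1.0, Plateau = 0.1, k = 0.2,
                           times_min = c(0, 5, 10, 15, 20, 25, 30, 40),
                           noise_sd = 0, seed = 1L) {
  y <- decay_curve(times_min, X0, Y0, Plateau, k)
  if (noise_sd > 0)
    y <- with_seed(seed, y + rnorm(length(y), 0, noise_sd))
  decay_series(times_min, y)
}

#' Fit the "plateau followed by one phase decay" model
#'
#' Least-squares fit of `Y(X) = Y0` for `X < X0` and
#' `Y(X) = Plateau + (Y0 - Plateau) exp(-k (X - X0))` for `X >= X0`,
#' with `X0 >= 0` and `k > 0`, by Levenberg-Marquardt from a deterministic
#' grid of starting values. The minimal decantation time at the default
#' 0.5% band is attached (see [solve_plateau_time()]).
#'
#' @param series a [decay_series()].
#' @param fix_x0 optional fixed value for `X0` (e.g. 0 for sparse series).
#' @return object of class `decay_fit`: `X0`, `Y0`, `Plateau`, `k`,
#'   `residual_sse`, `t_min`.
#' @examples
#' s <- simulate_decay(X0 = 0, Y0 = 1, Plateau = 0.1, k = 0.2)
#' f <- fit_decay(s)
#' c(f$k, f$t_min)
#' @export
fit_decay <- function(series, fix_x0 = NULL) {
  stopifnot(inherits(series, "decay_series"))
  t <- series$times_min; y <- series$absorbance
  if (stats::sd(y) == 0) stop("constant series: no decay to fit")
  if (y[length(y)] > y[1] && stats::cor(t, y) > 0)
    stop("series increases over time: not a decay")
  span <- max(y) - min(y)
  starts_k <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1)
  starts_x0 <- if (!is.null(fix_x0)) fix_x0
               else unique(pmax(0, t[seq_len(min(4, length(t) - 2))]))
  best <- NULL
  for (x0s in starts_x0) for (ks in starts_k) {
    fit <- tryCatch({
      if (is.null(fix_x0)) {
        minpack.lm::nlsLM(
          y ~ decay_curve(t, X0, Y0, Plateau, k),
          start = list(X0 = x0s, Y0 = y[1], Plateau = min(y), k = ks),
          lower = c(X0 = 0, Y0 = -Inf, Plateau = -Inf, k = 1e-6),
          upper = c(X0 = max(t), Y0 = Inf, Plateau = Inf, k = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500,
                                               ftol = 1e-12, ptol = 1e-12))
      } else {
        X0f <- fix_x0
        minpack.lm::nlsLM(
          y ~ decay_curve(t, X0f, Y0, Plateau, k),
          start = list(Y0 = y[1], Plateau = min(y), k = ks),
          lower = c(Y0 = -Inf, Plateau = -Inf, k = 1e-6),
          control = minpack.lm::nls.lm.control(maxiter = 500,
                                               ftol = 1e-12, ptol = 1e-12))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("decay fit did not converge from any start; data span = ", span)
  p <- as.list(coef(best$fit))
  if (!is.null(fix_x0)) p$X0 <- fix_x0
  out <- structure(
    list(X0 = p$X0, Y0 = p$Y0, Plateau = p$Plateau, k = p$k,
         residual_sse = best$sse,
         times_min = t, absorbance = y),
    class = "decay_fit")
  out$t_min <- solve_plateau_time(out)
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(paste0("<decay_fit> X0 = %.4g min, Y0 = %.4g, Plateau = ",
                     "%.4g, k = %.4g /min (SSE %.3g)\n  minimal ",
                     "decantation time (0.5%% band): %.2f min\n"),
              x$X0, x$Y0, x$Plateau, x$k, x$residual_sse, x$t_min))
  invisible(x)
}

#' Solve for the minimal decantation time
#'
#' Inverts the decay curve at the point where the signal is deemed to have
#' reached the plateau: `Xt = X0 - (1/k) ln((Yt - Plateau)/(Y0 - Plateau))`.
#' Under the default span convention the band is relative to the decay
#' span, `Yt = Plateau + band_fraction (Y0 - Plateau)`, which reduces to
#' `Xt = X0 + ln(1/band_fraction)/k` and remains well defined as the
#' plateau approaches zero. The plateau-relative convention
#' `Yt = Plateau (1 + band_fraction)` is available for a literal
#' "within 0.5% of the plateau value" reading.
#'
#' @param fit a [fit_decay()] result (or any list with `X0`, `Y0`,
#'   `Plateau`, `k`).
#' @param band_fraction the band, as a fraction (default 0.005 = 0.5%).
#' @param convention `"span"` (default) or `"plateau"`.
#' @return time in minutes.
#' @examples
#' f <- list(X0 = 0, Y0 = 1, Plateau = 0.1, k = 0.2)
#' solve_plateau_time(f)            # ln(200)/0.2
#' @export
solve_plateau_time <- function(fit, band_fraction = 0.005,
                               convention = c("span", "plateau")) {
  convention <- match.arg(convention)
  if (band_fraction <= 0 || band_fraction >= 1 + 1e-12)
    stop("band_fraction must be in (0, 1]")
  span <- fit$Y0 - fit$Plateau
  if (abs(span) < .Machine$double.eps)
    stop("degenerate fit: Y0 equals Plateau")
  Yt <- if (convention == "span") fit$Plateau + band_fraction * span
        else fit$Plateau * (1 + band_fraction)
  ratio <- (Yt - fit$Plateau) / span
  if (ratio <= 0 || ratio > 1)
    stop("band level lies outside the decay range (ratio = ",
         signif(ratio, 4), ")")
  fit$X0 - log(ratio) / fit$k
}

#' Read a decantation CSV (time_min, od595)
#'
#' @param path two-column CSV.
#' @return a [decay_series()].
#' @export
read_decay_csv <- function(path) {
  d <- read.csv(path)
  if (ncol(d) < 2) stop("expected two columns: time_min, od595")
  decay_series(d[[1]], d[[2]])
}
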