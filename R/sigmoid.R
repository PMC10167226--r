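#' Fit the empirical aggregation sigmoid
#'
#' Least-squares fit of a thioflavin-T (or other) aggregation trace to the
#' empirical logistic
#' \deqn{F(t) = F_0 + A / (1 + \exp[r_{max}(\tau_{1/2} - t)])}
#' where `F0` is the base value, `A` the amplitude, `r_max` the maximal
#' growth rate (1/s) and `tau_half` the aggregation half-time (s): the
#' fitted curve equals `F0 + A/2` at `t = tau_half`.
#'
#' Fitting uses Levenberg–Marquardt ([minpack.lm::nlsLM]) from a
#' deterministic start (data-driven: baseline/plateau from signal quantiles,
#' `tau_half` from the half-rise crossing, `r_max` from the steepest local
#' slope), falling back to a fixed grid of `r_max`/`tau_half` starts if the
#' first attempt fails; the procedure involves no randomness, so refits are
#' reproducible.
#'
#' @param trace An [aggregation_trace()] or a list/data frame with `times`
#'   and `signal`.
#' @return Object of class `sigmoid_fit`: `F0`, `A`, `r_max`, `tau_half`,
#'   `cov` (estimate covariance), `rss`, `n`, `tau_in_range` (flag: fitted
#'   half-time inside the observed time span) and the data.
#' @examples
#' tt <- seq(0, 2e4, by = 200)
#' y <- 1 / (1 + exp(0.001 * (8000 - tt)))
#' fit <- fit_sigmoid(aggregation_trace(tt, y))
#' coef(fit)
#' @export
fit_sigmoid <- function(trace) {
  tt <- trace$times
  y <- trace$signal
  stopifnot(length(tt) >= 5L)
  rng <- diff(range(y))
  if (rng <= 0) stop("flat trace: sigmoid fit undefined", call. = FALSE)
  if (stats::cor(tt, y) < 0) {
    stop("trace is not increasing overall: sigmoid fit not attempted",
         call. = FALSE)
  }
  d <- data.frame(t = tt, y = y)
  f0_0 <- stats::quantile(y, 0.02, names = FALSE)
  a_0 <- stats::quantile(y, 0.98, names = FALSE) - f0_0
  half <- f0_0 + a_0 / 2
  above <- which(y >= half)
  tau_0 <- if (length(above)) tt[above[1L]] else stats::median(tt)
  slope <- max(diff(y) / diff(tt))
  r_0 <- max(4 * slope / a_0, 1 / diff(range(tt)))

  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ F0 + A / (1 + exp(r_max * (tau - t))),
        data = d, start = start,
        lower = c(F0 = -Inf, A = rng * 1e-6, r_max = 1e-12, tau = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- try_fit(list(F0 = f0_0, A = a_0, r_max = r_0, tau = tau_0))
  if (is.null(fit)) {  # fixed fallback grid, deterministic
    span <- diff(range(tt))
    for (rf in c(0.3, 3, 30) / span) {
      for (tf in stats::quantile(tt, c(0.25, 0.5, 0.75), names = FALSE)) {
        fit <- try_fit(list(F0 = f0_0, A = a_0, r_max = rf, tau = tf))
        if (!is.null(fit)) break
      }
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) stop("sigmoid fit did not converge", call. = FALSE)
  est <- stats::coef(fit)
  if (est[["A"]] <= 0 || est[["r_max"]] <= 0) {
    stop("sigmoid fit rejected: non-positive amplitude or growth rate",
         call. = FALSE)
  }
  cov <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(
    list(F0 = est[["F0"]], A = est[["A"]], r_max = est[["r_max"]],
         tau_half = est[["tau"]], cov = cov,
         rss = sum(stats::residuals(fit)^2), n = length(tt),
         tau_in_range = est[["tau"]] >= min(tt) && est[["tau"]] <= max(tt),
         data = d),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Empirical sigmoid fit F(t) = F0 + A / (1 + exp[r_max (tau_1/2 - t)])\n")
  cat(sprintf("  F0 = %.4g | A = %.4g | r_max = %.4g /s | tau_1/2 = %.4g s%s\n",
              x$F0, x$A, x$r_max, x$tau_half,
              if (x$tau_in_range) "" else "  [outside observed range!]"))
  cat(sprintf("  n = %d points, RSS = %.3g\n", x$n, x$rss))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(F0 = object$F0, A = object$A, r_max = object$r_max,
    tau_half = object$tau_half)
}

#' @export
predict.sigmoid_fit <- function(object, times = object$data$t, ...) {
  object$F0 + object$A /
    (1 + exp(object$r_max * (object$tau_half - times)))
}

#' @export
plot.sigmoid_fit <- function(x, ...) {
  plot(x$data$t, x$data$y, xlab = "time (s)", ylab = "signal (AU)", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(v = x$tau_half, lty = 3)
  invisible(x)
}

#' @export
residuals.sigmoid_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' Normalize and average replicate traces
#'
#' Maps each replicate to `[0, 1]` using the baseline and plateau of its own
#' sigmoid fit (`(F - F0)/A`) and averages the normalized replicates
#' pointwise on the first replicate's time grid (others are linearly
#' interpolated onto it). If the sigmoid fit fails for any replicate — or
#' `method = "minmax"` is requested — min/max normalization is used for all
#' replicates and the result is flagged.
#'
#' @param traces List of replicate [aggregation_trace()]s (>= 1).
#' @param method `"sigmoid"` (default) or `"minmax"`.
#' @return List with `times`, `mean` (averaged normalized signal),
#'   `n_replicates`, `method` (method actually used) and `fallback` (flag:
#'   sigmoid normalization requested but min/max used).
#' @export
normalize_tht <- function(traces, method = c("sigmoid", "minmax")) {
  method <- match.arg(method)
  if (inherits(traces, "aggregation_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  grid <- traces[[1L]]$times
  fallback <- FALSE
  norm_one <- function(tr) {
    if (method == "sigmoid" && !fallback) {
      fit <- tryCatch(fit_sigmoid(tr), error = function(e) NULL)
      if (is.null(fit)) {
        fallback <<- TRUE
      } else {
        return((tr$signal - fit$F0) / fit$A)
      }
    }
    (tr$signal - min(tr$signal)) / diff(range(tr$signal))
  }
  normed <- lapply(traces, norm_one)
  if (fallback) {
    warning("sigmoid normalization failed for a replicate; ",
            "using min/max for all replicates")
    normed <- lapply(traces, function(tr)
      (tr$signal - min(tr$signal)) / diff(range(tr$signal)))
  }
  on_grid <- mapply(function(tr, v) {
    stats::approx(tr$times, v, xout = grid, rule = 2)$y
  }, traces, normed, SIMPLIFY = FALSE)
  list(times = grid, mean = Reduce(`+`, on_grid) / length(on_grid),
       n_replicates = length(traces),
       method = if (fallback) "minmax" else method,
       fallback = fallback)
}

#' Normalize a mapped plate into per-ratio averaged curves
#'
#' Groups a list of mapped [aggregation_trace()]s by their `ratio` label and
#' applies [normalize_tht()] per group: the input format expected by
#' [global_fit()].
#'
#' @param traces Named list of `aggregation_trace`s (e.g. from
#'   [read_plate()] or [traces_from_plate()]).
#' @param method Passed to [normalize_tht()].
#' @return Named list (ratio label -> normalized curve).
#' @export
normalize_panel <- function(traces, method = "sigmoid") {
  ratios <- vapply(traces, function(x) as.character(x$ratio), character(1))
  lapply(split(traces, ratios), normalize_tht, method = method)
}

#' Half-time delay relative to the chaperone-free control
#'
#' Tabulates the fold-delay of the aggregation half-time,
#' `tau_half(ratio) / tau_half(0)`, across a panel of per-ratio sigmoid
#' fits. The 0% (chaperone-free) condition must be present.
#'
#' @param fits Named list of [fit_sigmoid()] objects; names are chaperone
#'   molar-ratio percentages (`"0"`, `"10"`, `"50"`, `"100"`, ...).
#' @return Data frame with `ratio_pct`, `tau_half_s`, `delay` (fold change
#'   vs the 0% condition).
#' @export
halftime_delay <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (is.null(names(fits)) || !"0" %in% names(fits)) {
    stop("control condition (ratio '0') absent", call. = FALSE)
  }
  tau <- vapply(fits, `[[`, numeric(1), "tau_half")
  data.frame(ratio_pct = as.numeric(names(fits)),
             tau_half_s = unname(tau),
             delay = unname(tau / tau[["0"]]))
}
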