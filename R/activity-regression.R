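#' Fit the hydropathy–activity linear regression
#'
#' Ordinary least-squares fit of normalized aggregation mass (percent of the
#' substrate-alone control) on combined loop-motif hydropathy, one point per
#' variant at a single substrate:chaperone ratio. This is the model used to
#' predict the anti-amorphous chaperone activity of new variants from their
#' motif hydropathy alone.
#'
#' @param scores Data frame of hydropathy scores (from [score_panel()]):
#'   columns `variant_id`, `combined`, optionally `scale_name`.
#' @param masses Data frame of aggregation-mass results (columns
#'   `variant_id`, `mass_pct`, optionally `ratio`), matched to `scores` on
#'   `variant_id`. Control rows (`variant_id` `NA`) are ignored.
#' @param ratio Optional ratio label to select from `masses` when it holds
#'   several ratios.
#' @return An object of class `activity_reg`: the underlying [stats::lm]
#'   fit plus `slope`, `intercept`, `r_squared`, `p_value` (two-sided t-test
#'   on the slope), `residual_sd`, `n`, `x_mean`, `x_sumsq` (centred sum of
#'   squares, for confidence bands), `x_scale_name`, `ratio` and the fitted
#'   `data`.
#' @seealso [predict.activity_reg()], [correlate()]
#' @export
fit_activity_regression <- function(scores, masses, ratio = NULL) {
  stopifnot(is.data.frame(scores), is.data.frame(masses))
  masses <- masses[!is.na(masses$variant_id), , drop = FALSE]
  if (!is.null(ratio)) {
    masses <- masses[masses$ratio == ratio, , drop = FALSE]
  } else if ("ratio" %in% names(masses) &&
             length(unique(masses$ratio)) > 1L) {
    stop("masses span several ratios; pick one with `ratio`", call. = FALSE)
  }
  d <- merge(scores[, c("variant_id", "combined")],
             masses[, c("variant_id", "mass_pct")], by = "variant_id")
  if (nrow(d) < 3L) {
    stop("need at least 3 matched variants, got ", nrow(d), call. = FALSE)
  }
  if (stats::sd(d$combined) == 0) {
    stop("zero variance in hydropathy scores", call. = FALSE)
  }
  fit <- stats::lm(mass_pct ~ combined, data = d)
  sm <- summary(fit)
  structure(
    list(
      lm = fit,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = sm$r.squared,
      p_value = unname(sm$coefficients["combined", "Pr(>|t|)"]),
      residual_sd = sm$sigma,
      n = nrow(d),
      x_mean = mean(d$combined),
      x_sumsq = sum((d$combined - mean(d$combined))^2),
      x_scale_name = if ("scale_name" %in% names(scores))
        scores$scale_name[1L] else NA_character_,
      ratio = if (!is.null(ratio)) ratio
        else if ("ratio" %in% names(masses) && nrow(masses))
          masses$ratio[1L] else NA,
      data = d
    ),
    class = "activity_reg"
  )
}

#' @export
print.activity_reg <- function(x, ...) {
  cat("Hydropathy-activity regression (aggregation mass % ~ combined hydropathy)\n")
  if (!is.na(x$x_scale_name)) cat("  hydropathy scale:", x$x_scale_name, "\n")
  if (!is.na(x$ratio)) cat("  substrate:chaperone ratio:", x$ratio, "\n")
  cat(sprintf("  n = %d variants | slope = %.3f %%/unit | intercept = %.2f %%\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  R^2 = %.3f | p(slope) = %.3g | residual sd = %.2f %%\n",
              x$r_squared, x$p_value, x$residual_sd))
  invisible(x)
}

#' @export
coef.activity_reg <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.activity_reg <- function(object, ...) summary(object$lm, ...)

#' @export
residuals.activity_reg <- function(object, ...) stats::residuals(object$lm)

#' Predict chaperone activity from motif hydropathy
#'
#' Point prediction with a confidence interval for the *mean response* at
#' the given hydropathy, using the t distribution with n − 2 degrees of
#' freedom:
#' `se(x) = s * sqrt(1/n + (x - x_mean)^2 / Sxx)`.
#' A mean-response band (not a prediction interval) is what a regression
#' plot's "95% confidence band" shows, and what gives the narrow intervals
#' appropriate for predicting a variant's expected activity.
#'
#' @param object An [fit_activity_regression()] model.
#' @param newdata Numeric vector of combined hydropathy values, or a data
#'   frame with a `combined` column (e.g. [score_panel()] output).
#' @param level Confidence level (default 0.95).
#' @param clamp If `TRUE`, truncate point predictions and interval bounds
#'   to the physically meaningful `[0, 100]` percent range.
#' @param ... Unused.
#' @return Data frame with `combined`, `fit`, `lwr`, `upr` (percent of the
#'   substrate-alone aggregation mass) and, when `newdata` carries
#'   `variant_id`, that column first.
#' @export
predict.activity_reg <- function(object, newdata, level = 0.95,
                                 clamp = FALSE, ...) {
  ids <- NULL
  if (is.data.frame(newdata)) {
    if ("variant_id" %in% names(newdata)) ids <- newdata$variant_id
    x <- newdata$combined
  } else {
    x <- as.numeric(newdata)
  }
  stopifnot(length(x) >= 1L, all(is.finite(x)), level > 0, level < 1)
  df <- object$n - 2L
  if (df < 1L && object$residual_sd > 0) {
    stop("no residual degrees of freedom for a confidence interval",
         call. = FALSE)
  }
  fit <- object$intercept + object$slope * x
  se <- object$residual_sd *
    sqrt(1 / object$n + (x - object$x_mean)^2 / object$x_sumsq)
  tq <- if (df >= 1L) stats::qt(1 - (1 - level) / 2, df) else 0
  out <- data.frame(combined = x, fit = fit,
                    lwr = fit - tq * se, upr = fit + tq * se)
  if (clamp) {
    out$fit <- pmin(pmax(out$fit, 0), 100)
    out$lwr <- pmin(pmax(out$lwr, 0), 100)
    out$upr <- pmin(pmax(out$upr, 0), 100)
  }
  if (!is.null(ids)) out <- cbind(variant_id = ids, out)
  out
}

#' @export
plot.activity_reg <- function(x, level = 0.95, ...) {
  d <- x$data
  xx <- seq(min(d$combined), max(d$combined), length.out = 100)
  band <- predict(x, xx, level = level)
  plot(d$combined, d$mass_pct,
       xlab = sprintf("combined motif hydropathy (%s)",
                      if (is.na(x$x_scale_name)) "a.u." else x$x_scale_name),
       ylab = "aggregation mass (% of control)", ...)
  graphics::lines(xx, band$fit)
  graphics::lines(xx, band$lwr, lty = 2)
  graphics::lines(xx, band$upr, lty = 2)
  invisible(x)
}

#' Pearson correlation with slope test
#'
#' Convenience wrapper returning the squared Pearson correlation and the
#' two-sided p-value of the regression slope t-test — identical statistics
#' to [fit_activity_regression()] on the same pairs.
#'
#' @param x,y Paired numeric vectors (at least 3 finite pairs).
#' @return A list with `r_squared` and `p_value`.
#' @examples
#' correlate(1:5, -(1:5))$r_squared  # 1
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value)
}
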