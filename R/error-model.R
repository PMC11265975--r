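#' Regression of reconstruction error on trajectory length
#'
#' Models the dependence of reconstruction RMSE on sampling-trajectory
#' length with either an exponential decay `f(x) = a * exp(b * x) + c`
#' (fitted by Levenberg-Marquardt nonlinear least squares with multiple
#' starting points) or a polynomial of degree 3-7 (ordinary least squares).
#' The goodness of fit is summarized by the Pearson chi-squared statistic
#' of the 200 mm-binned mean RMSE against the model prediction at the bin
#' centers ([pearson_chi_squared()]); a lower statistic means the error is
#' more predictable from the trajectory length alone.
#'
#' @param lengths trajectory lengths (mm).
#' @param rmses matching RMSE values (mm).
#' @param family `"exp_decay"` or `"polynomial"`.
#' @param degree polynomial degree (3-7); ignored for `exp_decay`.
#' @param bin_width bin width (mm) for the chi-squared statistic.
#' @param n_starts number of extra randomized starts for the nonlinear fit.
#' @return object of class `error_model` with `coefficients`,
#'   `chi_squared`, `family`, `degree`, `n_points` and the fitted binning.
#' @export
fit_error_model <- function(lengths, rmses,
                            family = c("exp_decay", "polynomial"),
                            degree = 3L, bin_width = 200, n_starts = 8L) {
  family <- match.arg(family)
  x <- as.numeric(lengths)
  y <- as.numeric(rmses)
  if (length(x) != length(y)) stop("length mismatch")
  if (family == "polynomial") {
    if (degree < 3L || degree > 7L) stop("polynomial degree must be in 3..7")
    if (length(x) <= degree + 1L) stop("not enough points for the degree")
    fit <- lm(y ~ poly(x, degree, raw = TRUE))
    cf <- unname(coef(fit))
    names(cf) <- paste0("a", 0:degree)
    predict_fn <- function(newx)
      drop(outer(newx, 0:degree, `^`) %*% cf)
  } else {
    if (length(x) <= 3L) stop("not enough points for the 3-parameter fit")
    # starts: decay rate spanning the data range, offset near the tail level
    xr <- diff(range(x))
    if (xr <= 0) stop("degenerate length range")
    starts <- list(c(a = max(y) - min(y), b = -2 / xr, c = min(y)))
    extra <- with_seed(77L, replicate(n_starts, c(
      a = (max(y) - min(y)) * stats::runif(1, 0.3, 3),
      b = -stats::runif(1, 0.2, 10) / xr,
      c = min(y) * stats::runif(1, 0, 1.5)), simplify = FALSE))
    starts <- c(starts, extra)
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(b * x) + c,
                          start = as.list(st),
                          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
    if (is.null(best))
      stop("exponential-decay fit did not converge from any start")
    cf <- coef(best$fit)[c("a", "b", "c")]
    predict_fn <- function(newx) cf[["a"]] * exp(cf[["b"]] * newx) + cf[["c"]]
  }
  bins <- binned_confidence_intervals(x, y, bin_width = bin_width)
  expected <- predict_fn(bins$bin_centers)
  chi2 <- if (any(expected <= 0)) NA_real_
          else pearson_chi_squared(bins$means, expected)
  structure(list(family = family,
                 degree = if (family == "polynomial") degree else NA_integer_,
                 coefficients = cf, chi_squared = chi2,
                 n_points = length(x), bins = bins,
                 predict_fn = predict_fn),
            class = "error_model")
}

#' @export
coef.error_model <- function(object, ...) object$coefficients

#' @export
print.error_model <- function(x, ...) {
  lbl <- if (x$family == "exp_decay") "a * exp(b * x) + c"
         else sprintf("polynomial, degree %d", x$degree)
  cat(sprintf("error_model (%s): %s\n", x$family, lbl))
  print(signif(x$coefficients, 6))
  cat(sprintf("  Pearson chi-squared over %d-mm bins: %.4g (n = %d)\n",
              x$bins$bin_width, x$chi_squared, x$n_points))
  invisible(x)
}

#' Predict expected RMSE at given trajectory lengths
#'
#' @param object an `error_model`.
#' @param newdata lengths (mm); defaults to the fitted bin centers.
#' @param ... unused.
#' @export
predict.error_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$bins$bin_centers
  object$predict_fn(as.numeric(newdata))
}

#' Expected-error plot with binned confidence intervals
#'
#' @param x an `error_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.error_model <- function(x, ...) {
  b <- x$bins
  graphics::plot(b$bin_centers, b$means, pch = 19,
                 xlab = "trajectory length (mm)", ylab = "RMSE (mm)", ...)
  graphics::arrows(b$bin_centers, b$means - b$ci95, b$bin_centers,
                   b$means + b$ci95, angle = 90, code = 3, length = 0.03)
  xs <- seq(min(b$bin_centers), max(b$bin_centers), length.out = 200)
  graphics::lines(xs, x$predict_fn(xs), col = "steelblue")
  invisible(x)
}
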