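#' Position-displacement RMSE
#'
#' Root-mean-square of the Euclidean distances from each ground-truth point
#' to its closest neighbor in the reconstructed shape (one-sided, ground
#' truth towards reconstruction) — the accuracy measure used throughout the
#' virtual and lab studies. The default measures vertex-to-vertex (point
#' set against point set); `to_surface = TRUE` measures exact
#' point-to-triangle distances against a reconstructed mesh surface.
#'
#' @param ground_truth,reconstructed point sets (matrix, [point_cloud()] or
#'   [trimesh()]).
#' @param to_surface measure against the reconstructed triangle surface
#'   (requires a [trimesh()]).
#' @return RMSE in the coordinate units.
#' @export
position_rmse <- function(ground_truth, reconstructed, to_surface = FALSE) {
  gt <- as_points(ground_truth)
  if (to_surface && inherits(reconstructed, "trimesh")) {
    d <- point_to_surface_distance(gt, reconstructed)$distance
  } else {
    d <- nearest_neighbors(gt, as_points(reconstructed))$distance
  }
  sqrt(mean(d^2))
}

#' Pearson chi-squared goodness-of-fit statistic
#'
#' `sum((O - E)^2 / E)` over paired observed/expected values; here the
#' observed values are binned mean RMSEs and the expected values the error
#' model's prediction at the bin centers.
#'
#' @param observed,expected equal-length vectors; `expected` must be
#'   strictly positive.
#' @return the statistic.
#' @export
pearson_chi_squared <- function(observed, expected) {
  if (length(observed) != length(expected)) stop("length mismatch")
  if (any(expected <= 0)) stop("expected values must be positive")
  sum((observed - expected)^2 / expected)
}

#' Binned means and 95% confidence intervals of RMSE vs trajectory length
#'
#' Trajectory lengths are grouped into fixed-width bins (200 mm by
#' default); each reported bin carries the mean RMSE and a
#' normal-approximation 95% half-width `1.96 * sd / sqrt(count)`
#' (0 by convention, and flagged, for single-observation bins). Empty bins
#' are dropped with a warning.
#'
#' @param lengths trajectory lengths (mm).
#' @param rmses matching RMSE values (mm).
#' @param bin_width bin width in mm.
#' @return object of class `binned_errors`: `bin_centers`, `means`, `ci95`
#'   half-widths and `counts`.
#' @export
binned_confidence_intervals <- function(lengths, rmses, bin_width = 200) {
  if (length(lengths) != length(rmses)) stop("length mismatch")
  bin <- floor(lengths / bin_width)
  centers_all <- (min(bin):max(bin)) * bin_width + bin_width / 2
  present <- sort(unique(bin))
  if (length(present) < length(min(bin):max(bin)))
    warning("empty length bin(s) dropped")
  means <- vapply(present, function(b) mean(rmses[bin == b]), 0)
  counts <- vapply(present, function(b) sum(bin == b), 0L)
  sds <- vapply(present, function(b) {
    x <- rmses[bin == b]
    if (length(x) < 2L) 0 else sd(x)
  }, 0)
  ci95 <- 1.96 * sds / sqrt(counts)
  structure(list(bin_centers = present * bin_width + bin_width / 2,
                 means = means, ci95 = ci95, counts = counts,
                 single = counts == 1L, bin_width = bin_width),
            class = "binned_errors")
}

#' @export
print.binned_errors <- function(x, ...) {
  df <- data.frame(center_mm = x$bin_centers, mean_rmse = x$means,
                   ci95 = x$ci95, n = x$counts)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Segment-wise cross-validation of a reconstruction protocol
#'
#' Emulates the lab protocol: the pooled sampling trajectories are cut into
#' `n_segments` contiguous equal-point-count segments; each repeat fits the
#' reconstruction on a random 75% of the segments and scores the held-out
#' 25% by [position_rmse()]. Held-out selections are stratified so both
#' hemispheres and diverse head regions (front/back arc quartiles) are
#' represented; when stratification is infeasible the split falls back to
#' unstratified and is flagged.
#'
#' @param trajectories list of `trajectory` objects (or point matrices).
#' @param fit_fn function(points) returning a reconstruction (point set or
#'   [trimesh()]) from the training points.
#' @param n_segments number of contiguous segments (default 20).
#' @param train_fraction fraction of segments used for fitting.
#' @param n_repeats number of random splits.
#' @param seed RNG seed; splits and results are reproducible bitwise.
#' @param frame optional [head_frame()] for the stratification labels;
#'   defaults to the canonical frame at the pooled centroid.
#' @return object of class `segment_cv`: per-repeat `rmse`, their
#'   `mean`/`sd`, the held-out segment sets, and a `stratified` flag per
#'   repeat.
#' @export
segment_cross_validation <- function(trajectories, fit_fn, n_segments = 20L,
                                     train_fraction = 0.75, n_repeats = 10L,
                                     seed = 1L, frame = NULL) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  pts <- do.call(rbind, lapply(trajectories, function(t)
    if (inherits(t, "trajectory")) t$points else as_points(t)))
  n <- nrow(pts)
  if (n < n_segments) stop("fewer points than segments")
  segment <- ceiling(seq_len(n) / (n / n_segments))
  segment <- pmin(segment, n_segments)
  if (is.null(frame)) frame <- head_frame(origin = colMeans(pts))
  rel <- sweep(pts, 2, frame$origin)
  hemi <- sign(drop(rel %*% frame$left))
  theta <- atan2(drop(rel %*% frame$up), drop(rel %*% frame$front))
  region <- cut(theta, breaks = quantile(theta, 0:4 / 4), include.lowest = TRUE,
                labels = FALSE)
  n_holdout <- max(1L, round((1 - train_fraction) * n_segments))
  ok_split <- function(held) {
    sel <- segment %in% held
    length(unique(sign(hemi[sel])[sign(hemi[sel]) != 0])) == 2L &&
      length(unique(region[sel])) >= 2L
  }
  with_seed(seed, {
    rmse <- numeric(n_repeats)
    held_sets <- vector("list", n_repeats)
    stratified <- logical(n_repeats)
    for (r in seq_len(n_repeats)) {
      held <- NULL
      for (try in 1:50) {
        cand <- sort(sample.int(n_segments, n_holdout))
        if (ok_split(cand)) { held <- cand; stratified[r] <- TRUE; break }
      }
      if (is.null(held)) {
        held <- sort(sample.int(n_segments, n_holdout))
        warning("stratified split infeasible at repeat ", r,
                "; using unstratified split")
      }
      held_sets[[r]] <- held
      train <- pts[!(segment %in% held), , drop = FALSE]
      test <- pts[segment %in% held, , drop = FALSE]
      recon <- fit_fn(train)
      rmse[r] <- position_rmse(test, recon)
    }
    structure(list(rmse = rmse, mean = mean(rmse), sd = sd(rmse),
                   held_out = held_sets, stratified = stratified,
                   n_segments = n_segments, n_holdout = n_holdout),
              class = "segment_cv")
  })
}

#' @export
print.segment_cv <- function(x, ...) {
  cat(sprintf("segment cross-validation: %d repeats, %d/%d held-out segments\n",
              length(x$rmse), x$n_holdout, x$n_segments))
  cat(sprintf("  RMSE %.3f +/- %.3f mm\n", x$mean, x$sd))
  invisible(x)
}
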