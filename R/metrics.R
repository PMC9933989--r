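#' Mean absolute percentage error on point coordinates
#'
#' `MAPE = (100 / n) * sum(|Y_i - Y_true,i| / |Y_true,i|)` over coordinate
#' scalars. For one image the four scalars (ap_x, ap_y, pp_x, pp_y) enter;
#' for a dataset, scores are averaged over images. Coordinates are expected
#' in a convention where no true coordinate is 0 (the package evaluates in
#' 1-based pixel coordinates for this reason; see [eval_points()]).
#'
#' @param pred,true numeric vectors or matrices of identical shape (rows =
#'   images, columns = coordinate scalars).
#' @return MAPE in percent (scalar).
#' @export
mape <- function(pred, true) {
  if (length(pred) != length(true))
    ml_validation_error("pred and true lengths differ")
  if (any(true == 0))
    ml_validation_error("MAPE undefined: a true coordinate is 0 (use 1-based coordinates)")
  100 * mean(abs(pred - true) / abs(true))
}

#' Per-image MAPE scores
#'
#' @param pred,true matrices with one row per image (columns ap_x, ap_y,
#'   pp_x, pp_y).
#' @return vector of per-image MAPE scores in percent.
#' @export
mape_per_image <- function(pred, true) {
  if (!all(dim(pred) == dim(true)))
    ml_validation_error("pred and true dimensions differ")
  vapply(seq_len(nrow(pred)), function(i) mape(pred[i, ], true[i, ]), numeric(1))
}

#' Shift 0-based point coordinates to the 1-based evaluation convention
#'
#' The MAPE formula divides by the true coordinate, which can be 0 in the
#' 0-based pixel convention; evaluation therefore shifts all coordinates by
#' +1 first.
#'
#' @param pts matrix or vector of coordinates.
#' @return shifted coordinates.
#' @export
eval_points <- function(pts) pts + 1

#' Intersection over union of two binary masks
#'
#' Both masks empty is treated as perfect agreement (IoU 1): frames with a
#' fully closed glottis are correct exactly when nothing is segmented.
#'
#' @param mask_a,mask_b binary arrays of identical shape.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    ml_validation_error("mask dimensions differ")
  a <- mask_a > 0.5
  b <- mask_b > 0.5
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Temporal jitter of predicted points
#'
#' For a video with constant true points, computes per frame the Euclidean
#' distance between prediction and truth and returns the population standard
#' deviation of those distances for the anterior and posterior point.
#'
#' @param pred_traj data frame with columns `ap_x`, `ap_y`, `pp_x`, `pp_y`
#'   (one row per frame, at least 2 frames).
#' @param true_points list with `ap` and `pp`, each `(x, y)`.
#' @return list with `ap_std` and `pp_std` in pixels.
#' @export
trajectory_jitter <- function(pred_traj, true_points) {
  T_ <- nrow(pred_traj)
  if (is.null(T_) || T_ < 2)
    ml_validation_error("jitter needs at least 2 frames")
  pop_sd <- function(d) sqrt(mean((d - mean(d))^2))
  d_ap <- sqrt((pred_traj$ap_x - true_points$ap[1])^2 +
                 (pred_traj$ap_y - true_points$ap[2])^2)
  d_pp <- sqrt((pred_traj$pp_x - true_points$pp[1])^2 +
                 (pred_traj$pp_y - true_points$pp[2])^2)
  list(ap_std = pop_sd(d_ap), pp_std = pop_sd(d_pp))
}

#' Distribution summary of per-image scores
#'
#' Median, first and third quartile (linear interpolation), minimum and
#' maximum.
#'
#' @param scores nonempty numeric vector.
#' @return list with `median`, `q1`, `q3`, `min`, `max`.
#' @export
summarize_scores <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0)
    ml_validation_error("cannot summarize an empty score list")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], min = min(scores), max = max(scores))
}

#' Full evaluation report
#'
#' Combines the per-image MAPE distribution (computed in 1-based pixel
#' coordinates), the mean IoU over frames and, when per-video trajectories
#' are supplied, the per-video temporal jitter.
#'
#' @param pred_points,true_points matrices, one row per image, columns
#'   ap_x, ap_y, pp_x, pp_y, 0-based pixel coordinates.
#' @param pred_masks,true_masks optional lists of binary masks (same length).
#' @param trajectories optional named list of prediction data frames per
#'   video; `true_by_video` the matching named list of `list(ap=, pp=)`.
#' @param true_by_video see above.
#' @return an `eval_report` list: `mape_summary` (median/q1/q3/min/max, %),
#'   `mean_mape`, `mean_iou` (or NULL), `jitter` per video (or NULL).
#' @export
eval_report <- function(pred_points, true_points, pred_masks = NULL,
                        true_masks = NULL, trajectories = NULL,
                        true_by_video = NULL) {
  scores <- mape_per_image(eval_points(pred_points), eval_points(true_points))
  rep <- list(mape_summary = summarize_scores(scores),
              mean_mape = mean(scores[is.finite(scores)]),
              per_image_mape = scores)
  if (!is.null(pred_masks)) {
    ious <- vapply(seq_along(pred_masks),
                   function(i) iou(pred_masks[[i]], true_masks[[i]]), numeric(1))
    rep$mean_iou <- mean(ious)
    rep$per_image_iou <- ious
  }
  if (!is.null(trajectories)) {
    rep$jitter <- lapply(names(trajectories), function(v)
      trajectory_jitter(trajectories[[v]], true_by_video[[v]]))
    names(rep$jitter) <- names(trajectories)
  }
  class(rep) <- "eval_report"
  rep
}
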