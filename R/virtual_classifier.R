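#' Virtual object-detection classifier
#'
#' A stochastic stand-in for the on-chip object-detection model. Each
#' object inside a droplet is detected (recall is fixed at 1) and its
#' class is read correctly with probability `precision`; with probability
#' `1 - precision` it is misread as the other species. The confusion is
#' symmetric unless per-class precisions are given.
#'
#' @param precision Probability in `[0, 1]` that an object's class is read
#'   correctly. Default 0.985, the precision of the detection model this
#'   stub emulates.
#' @param precision_background Optional separate precision for background
#'   objects; defaults to `precision` (symmetric confusion).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(precision = 0.985,
                            precision_background = precision) {
  if (precision < 0 || precision > 1 ||
      precision_background < 0 || precision_background > 1)
    stop("precision must be in [0, 1]")
  structure(list(precision = precision,
                 precision_background = precision_background),
            class = "classifier_spec")
}

#' Simulate droplet read-out by the virtual classifier
#'
#' Reads every object in each droplet independently: a target object is
#' reported as target with probability `precision`, a background object as
#' background with probability `precision_background`. The droplet-level
#' predicted label follows the same rule as [true_label()] applied to the
#' predicted counts, so a truly mixed droplet is predicted `TARGET_ONLY`
#' only when every one of its background objects is misread.
#'
#' @param droplets Integer matrix with columns `n_target`, `n_background`
#'   (one row per droplet), as from [sample_array()].
#' @param spec A [classifier_spec()].
#' @return Data frame with columns `predicted_target`,
#'   `predicted_background`, `predicted_label`. The two predicted counts
#'   always sum to the droplet's true total (no missed or spurious
#'   detections).
#' @export
detect_array <- function(droplets, spec = classifier_spec()) {
  n <- nrow(droplets)
  p <- spec$precision
  q <- spec$precision_background
  # objects read as target: correctly-read targets + misread backgrounds
  t_as_t <- stats::rbinom(n, droplets[, 1], p)
  b_as_t <- stats::rbinom(n, droplets[, 2], 1 - q)
  pred_t <- t_as_t + b_as_t
  pred_b <- droplets[, 1] + droplets[, 2] - pred_t
  data.frame(predicted_target = pred_t,
             predicted_background = pred_b,
             predicted_label = true_label(pred_t, pred_b))
}

#' @rdname detect_array
#' @param n_target,n_background Counts of a single droplet.
#' @export
detect_droplet <- function(n_target, n_background, spec = classifier_spec()) {
  detect_array(cbind(n_target, n_background), spec)
}

#' Probability that a droplet is read as target-only
#'
#' Closed-form collection probability under the symmetric-confusion
#' classifier: a droplet with `h` target and `b` background objects is
#' predicted `TARGET_ONLY` (and hence collected) exactly when all `h`
#' targets are read correctly and all `b` backgrounds are misread,
#' \deqn{P = p^{h} (1-p)^{b},}
#' for `h + b >= 1`; an empty droplet can never be read as target-only.
#' This is the analytic oracle used to validate the Monte-Carlo sorter.
#'
#' @param n_target,n_background Droplet contents (vectors recycle).
#' @param precision Classifier precision.
#' @return Probability vector.
#' @export
collection_probability <- function(n_target, n_background, precision) {
  p <- precision^n_target * (1 - precision)^n_background
  p[n_target + n_background == 0] <- 0
  p
}
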