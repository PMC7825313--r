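# Hybrid segmentation losses: dice + (weighted) binary cross-entropy.
# Predictions are clipped to (eps, 1 - eps) before logs; the dice smoothing
# constant guards the empty-mask / empty-prediction case.

CLIP_EPS <- 1e-7

check_batch <- function(y, k) {
  if (length(y) != length(k))
    stop("ground truth and prediction have different lengths")
  if (length(y) == 0L) stop("empty pixel batch")
  if (any(y != 0 & y != 1)) stop("ground truth must be binary")
  if (any(k < 0 | k > 1)) stop("predictions must lie in [0, 1]")
  invisible(TRUE)
}

#' Loss configuration
#'
#' @param kind `"dice_bce"` (dice + binary cross-entropy, for balanced
#'   foreground/background) or `"dice_wce"` (dice + weighted cross-entropy,
#'   for imbalanced classes). The YAML training configs use the equivalent
#'   labels `"DC+BCE"` / `"DC+WCE"`.
#' @param foreground_weight the class weight `w` of the weighted
#'   cross-entropy, in (0, 1). As written, the weighted loss multiplies the
#'   foreground (y = 1) term by `1 - w` and the background term by `w`, so a
#'   foreground-heavy training set should use its foreground pixel fraction
#'   as `w` to up-weight the rarer background errors (and vice versa); see
#'   [wce_loss()].
#' @param smooth nonnegative dice smoothing constant.
#' @return object of class `tmd_loss_config`.
#' @export
loss_config <- function(kind = c("dice_bce", "dice_wce"),
                        foreground_weight = 0.5, smooth = 1) {
  kind <- if (length(kind) == 1L && kind %in% c("DC+BCE", "DC+WCE")) {
    c("DC+BCE" = "dice_bce", "DC+WCE" = "dice_wce")[[kind]]
  } else match.arg(kind)
  if (foreground_weight <= 0 || foreground_weight >= 1)
    stop("foreground_weight must be in (0, 1)")
  if (smooth < 0) stop("smooth must be nonnegative")
  structure(list(kind = kind, foreground_weight = foreground_weight,
                 smooth = smooth), class = "tmd_loss_config")
}

#' Dice loss
#'
#' `1 - (2 * sum(y*k) + smooth) / (sum(y + k) + smooth)`. Symmetric in its
#' two arguments; lies in `[0, 1)` for `smooth > 0`.
#'
#' @param y binary ground truth (vector or array).
#' @param k predicted probabilities in `[0, 1]`, congruent with `y`.
#' @param smooth nonnegative smoothing constant protecting the empty-empty
#'   case; with `smooth = 0` an all-zero pair is a division by zero and is
#'   rejected.
#' @return scalar loss.
#' @export
dice_loss <- function(y, k, smooth = 1) {
  check_batch(y, k)
  den <- sum(y) + sum(k) + smooth
  if (den == 0) stop("dice loss undefined: empty masks with smooth = 0")
  1 - (2 * sum(y * k) + smooth) / den
}

#' Binary cross-entropy loss
#'
#' `-mean(y*log(k) + (1-y)*log(1-k))` with predictions clipped to
#' `(1e-7, 1 - 1e-7)`.
#'
#' @inheritParams dice_loss
#' @return scalar loss.
#' @export
bce_loss <- function(y, k) {
  check_batch(y, k)
  k <- pmin(pmax(k, CLIP_EPS), 1 - CLIP_EPS)
  -mean(y * log(k) + (1 - y) * log(1 - k))
}

#' Weighted binary cross-entropy loss
#'
#' `-mean((1-w)*y*log(k) + w*(1-y)*log(1-k))`. Note the weighting as
#' written: `w` (nominally the foreground-class weight) multiplies the
#' background term and `1 - w` the foreground term, so `w = 0.5` gives
#' exactly half of [bce_loss()] and a large `w` emphasises background
#' errors. The formula is implemented literally rather than silently
#' swapping the weights.
#'
#' @inheritParams dice_loss
#' @param w class weight in (0, 1).
#' @return scalar loss.
#' @export
wce_loss <- function(y, k, w) {
  check_batch(y, k)
  if (w <= 0 || w >= 1) stop("w must be in (0, 1)")
  k <- pmin(pmax(k, CLIP_EPS), 1 - CLIP_EPS)
  -mean((1 - w) * y * log(k) + w * (1 - y) * log(1 - k))
}

#' Hybrid loss
#'
#' Sum of the dice loss and the configured cross-entropy term.
#'
#' @inheritParams dice_loss
#' @param config a [loss_config()].
#' @return scalar loss.
#' @export
hybrid_loss <- function(y, k, config = loss_config()) {
  stopifnot(inherits(config, "tmd_loss_config"))
  ce <- if (config$kind == "dice_bce") bce_loss(y, k)
        else wce_loss(y, k, config$foreground_weight)
  dice_loss(y, k, config$smooth) + ce
}

# gradient of the hybrid loss wrt the prediction, for training
hybrid_loss_grad <- function(y, k, config) {
  n <- length(y)
  kc <- pmin(pmax(k, CLIP_EPS), 1 - CLIP_EPS)
  clipped <- (k <= CLIP_EPS) | (k >= 1 - CLIP_EPS)
  num <- 2 * sum(y * k) + config$smooth
  den <- sum(y) + sum(k) + config$smooth
  g_dice <- -(2 * y * den - num) / den^2
  g_ce <- if (config$kind == "dice_bce") {
    (-y / kc + (1 - y) / (1 - kc)) / n
  } else {
    w <- config$foreground_weight
    (-(1 - w) * y / kc + w * (1 - y) / (1 - kc)) / n
  }
  g_ce[clipped] <- 0
  g_dice + g_ce
}
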