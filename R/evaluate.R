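#' Brier scores stratified by ground truth state
#'
#' Calibration of probabilistic predictions per true state: within the
#' stratum of targets whose true state is `s`, the score is the mean
#' squared shortfall of the predicted probability of `s` from 1. Under a
#' normal-biased model the normal stratum scores low while the minority
#' strata score high, which is the signature of imbalance-driven bias.
#'
#' @param risks Matrix (n x 3) of predicted risk triples.
#' @param truths Integer vector of true states, length n.
#' @return Named numeric vector of length 3 (`NA` for empty strata).
#' @export
brier_stratified <- function(risks, truths) {
  risks <- as.matrix(risks)
  if (nrow(risks) != length(truths))
    stop("risks and truths are misaligned")
  stopifnot(length(truths) >= 1, ncol(risks) == 3)
  out <- vapply(STATES, function(s) {
    sel <- truths == s
    if (!any(sel)) return(NA_real_)
    mean((risks[sel, s] - 1)^2)
  }, numeric(1))
  names(out) <- STATE_LABELS
  out
}

#' Absolute risk curves over age
#'
#' The absolute risk of each state as a function of age: the age axis is
#' partitioned into consecutive windows of the given width (about 10
#' months by default) and within each window the proportions of the three
#' states among the samples falling in it are recorded. Empty windows are
#' excluded.
#'
#' @param times Ages at the prediction targets, years.
#' @param states Integer state vector aligned with `times`.
#' @param window Window width in years (default 10/12).
#' @param t_min Optional fixed left edge of the first window (so that two
#'   curves can share a grid); defaults to `min(times)`.
#' @return Object of class `risk_curve`: data frame with `center`, `n`,
#'   `p1`, `p2`, `p3`.
#' @export
absolute_risk_curve <- function(times, states, window = 10 / 12,
                                t_min = NULL) {
  stopifnot(window > 0, length(times) == length(states))
  if (!length(times)) stop("no samples to build a risk curve from")
  lo <- if (is.null(t_min)) min(times) else t_min
  idx <- floor((times - lo) / window)
  stopifnot(all(idx >= 0))
  tab <- table(idx, factor(states, levels = STATES))
  counts <- matrix(as.numeric(tab), nrow = nrow(tab))
  n <- rowSums(counts)
  keep <- n > 0
  centers <- lo + (as.numeric(rownames(tab)) + 0.5) * window
  out <- data.frame(center = centers[keep], n = n[keep],
                    p1 = counts[keep, 1] / n[keep],
                    p2 = counts[keep, 2] / n[keep],
                    p3 = counts[keep, 3] / n[keep])
  structure(out, window = window, t_min = lo,
            class = c("risk_curve", "data.frame"))
}

#' Relative deviation between absolute risk curves
#'
#' The performance indicator
#' \deqn{\eta = \frac{\int |r(t) - \hat r(t)|\, dt}{\int r(t)\, dt}}
#' comparing a predicted absolute risk curve against the reference curve
#' observed in hold-out data, evaluated by trapezoidal quadrature on the
#' windows shared by both curves. Zero means the predicted curve tracks
#' the reference exactly; the indicator is invariant to scaling both
#' curves by the same factor.
#'
#' @param reference,predicted `risk_curve` objects on the same window
#'   layout, or plain numeric vectors on a shared grid.
#' @param state State whose curve is compared (1, 2 or 3); ignored for
#'   numeric input.
#' @param centers Grid for numeric input (defaults to the sample index).
#' @return Nonnegative scalar.
#' @export
eta <- function(reference, predicted, state = 1L, centers = NULL) {
  if (inherits(reference, "risk_curve")) {
    stopifnot(inherits(predicted, "risk_curve"))
    common <- intersect(round(reference$center, 9), round(predicted$center, 9))
    if (length(common) < 2)
      stop("curves share fewer than 2 windows; cannot integrate")
    i <- match(common, round(reference$center, 9))
    j <- match(common, round(predicted$center, 9))
    col <- paste0("p", state)
    r <- reference[[col]][i]
    rh <- predicted[[col]][j]
    tt <- reference$center[i]
  } else {
    r <- as.numeric(reference); rh <- as.numeric(predicted)
    stopifnot(length(r) == length(rh), length(r) >= 2)
    tt <- if (is.null(centers)) seq_along(r) else centers
  }
  denom <- pracma::trapz(tt, r)
  if (denom <= 0) stop("reference curve integrates to zero")
  pracma::trapz(tt, abs(r - rh)) / denom
}
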