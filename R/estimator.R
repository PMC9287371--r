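#' Risk triples
#'
#' A risk triple is the model output for one prediction: normalized
#' probabilities of the three observable states (normal, low-grade,
#' high-grade) at a target age.
#'
#' @param probs Numeric vector of length 3, nonnegative; normalized to sum
#'   to one.
#' @param target_time Target age in years (optional attribute).
#' @return Classed numeric vector of length 3 summing to 1.
#' @export
risk_triple <- function(probs, target_time = NA_real_) {
  stopifnot(is.numeric(probs), length(probs) == 3, all(is.finite(probs)),
            all(probs >= 0))
  total <- sum(probs)
  if (total <= 0) stop("risk triple has zero total mass")
  out <- probs / total
  names(out) <- STATE_LABELS
  structure(out, target_time = target_time, class = "risk_triple")
}

#' @export
print.risk_triple <- function(x, ...) {
  cat(sprintf("<risk_triple> normal %.4f | low-grade %.4f | high-grade %.4f",
              x[1], x[2], x[3]))
  tt <- attr(x, "target_time")
  if (is.finite(tt)) cat(sprintf("  (age %.2f)", tt))
  cat("\n")
  invisible(x)
}

#' Shared incremental estimator contract
#'
#' Every risk estimator in the package implements the same three-verb
#' contract so that the rolling prediction protocol is estimator-agnostic:
#'
#' * `init_state(estimator)` creates an empty per-subject tracking state;
#' * `observe(estimator, state, record)` folds one exam record (a one-row
#'   data frame with `age`, `exam_type`, `state`) into the tracking state,
#'   requiring strictly increasing times;
#' * `predict_risk(estimator, state, t_hat)` returns a [risk_triple()] for a
#'   target age strictly after the last observed record.
#'
#' Incremental updating never re-fits the reference model: the matrix
#' factorization estimators update per-profile likelihood weights, the HMM
#' updates its forward variable, and the feature-based baselines extend
#' their count features.
#'
#' @param estimator A fitted risk estimator.
#' @param ... Passed to methods.
#' @name estimator-contract
NULL

#' @rdname estimator-contract
#' @export
init_state <- function(estimator, ...) UseMethod("init_state")

#' @rdname estimator-contract
#' @param state A per-subject tracking state from `init_state`/`observe`.
#' @param record One-row data frame with columns `age`, `exam_type`, `state`.
#' @export
observe <- function(estimator, state, record, ...) UseMethod("observe")

#' @rdname estimator-contract
#' @param t_hat Target age (years), strictly after the last observed record.
#' @export
predict_risk <- function(estimator, state, t_hat, ...) UseMethod("predict_risk")

check_record <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  stopifnot(record$state %in% STATES, record$exam_type %in% EXAM_TYPES)
  record
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
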