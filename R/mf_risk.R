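#' Discrete state emission probabilities from a latent value
#'
#' Probability of observing state `s` in \{1, 2, 3\} given a continuous
#' latent value `m`: a softmax over the three states of
#' `-(m - s)^2 / (2 sigma^2)`, i.e. a Gaussian kernel around the latent
#' value normalized over the discrete state set so the three probabilities
#' sum to one.
#'
#' @param m Latent value(s).
#' @param s State(s) in 1..3, recycled against `m`.
#' @param sigma Emission noise scale, > 0.
#' @return Probabilities, same length as `m`/`s` recycled.
#' @examples
#' emission_prob(1, 1:3, sigma = 1)   # 0.5741 0.3482 0.0777
#' @export
emission_prob <- function(m, s, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  stopifnot(all(s %in% STATES))
  P <- emission_matrix(m, sigma)
  n <- max(length(m), length(s))
  P[cbind(rep_len(seq_along(m), n), rep_len(as.integer(s), n))]
}

# length(m) x 3 matrix of normalized emission probabilities
emission_matrix <- function(m, sigma) {
  E <- outer(m, STATES, function(mm, ss) -(mm - ss)^2 / (2 * sigma^2))
  E <- exp(E - apply(E, 1, max))
  E / rowSums(E)
}

#' Log-likelihood of a screening history under one latent profile
#'
#' Sum over the history's records of the log emission probability of the
#' recorded state given the profile's latent value in the record's age bin.
#' An empty history has log-likelihood 0 (empty product).
#'
#' @param history Data frame with columns `age` and `state`.
#' @param profile_row Numeric vector of latent values over the grid columns.
#' @param grid The [age_grid()] the profile lives on.
#' @param sigma Emission noise scale.
#' @return Scalar log-likelihood.
#' @export
history_log_likelihood <- function(history, profile_row, grid, sigma) {
  if (is.null(history) || !nrow(history)) return(0)
  cols <- age_to_column(history$age, grid)
  sum(log(emission_prob(profile_row[cols], history$state, sigma)))
}

#' Per-profile likelihood weights and their recursive update
#'
#' `likelihood_weights` holds, for each reference latent profile, the
#' running log-likelihood of a subject's history; `update_likelihood` folds
#' one new exam record into the weights by adding that record's per-profile
#' log emission term. The recursive update equals recomputing the batch
#' history likelihood on the extended history.
#'
#' @param n Number of reference profiles.
#' @return `likelihood_weights`: list with `log_w` (length-`n` zeros) and
#'   `last_time` (`-Inf`).
#' @export
likelihood_weights <- function(n) {
  list(log_w = numeric(n), last_time = -Inf)
}

#' @rdname likelihood_weights
#' @param weights A `likelihood_weights` list.
#' @param record One-row data frame (`age`, `state`, `exam_type`).
#' @param profiles A `latent_profiles` object.
#' @export
update_likelihood <- function(weights, record, profiles) {
  check_record(record)
  if (record$age <= weights$last_time)
    stop("out-of-order record: time ", record$age,
         " is not after ", weights$last_time)
  col <- age_to_column(record$age, profiles$grid)
  weights$log_w <- weights$log_w +
    log(emission_prob(profiles$values[, col], record$state, profiles$sigma))
  weights$last_time <- record$age
  weights
}

#' Posterior predictive risk from likelihood-weighted latent profiles
#'
#' Approximates the posterior predictive distribution of the state at a
#' target age by a mixture over the reference latent profiles: each
#' profile's emission distribution at the target age bin, weighted by the
#' profile's history likelihood. Computed in log space with a max shift;
#' individual profiles may underflow as long as at least one survives.
#'
#' @param weights `likelihood_weights` accumulated over the history.
#' @param profiles A `latent_profiles` object.
#' @param t_hat Target age, strictly after the last incorporated record.
#' @return A [risk_triple()].
#' @export
predict_mixture_risk <- function(weights, profiles, t_hat) {
  if (t_hat <= weights$last_time)
    stop("target time must be after the last incorporated record")
  if (all(!is.finite(weights$log_w)))
    stop("no compatible reference profile (all likelihood weights are zero)")
  col <- age_to_column(t_hat, profiles$grid)
  E <- emission_matrix(profiles$values[, col], profiles$sigma)
  lw <- weights$log_w - max(weights$log_w)
  w <- exp(lw)
  risk_triple(as.numeric(crossprod(E, w)), target_time = t_hat)
}

#' Matrix factorization risk estimator
#'
#' Wraps fitted latent profiles (from [fit_swcmf()] or [fit_gdl()]) in the
#' shared incremental estimator contract: `observe()` updates the
#' per-profile likelihood weights recursively, `predict_risk()` forms the
#' posterior predictive mixture at the target age. The reference profiles
#' are never re-fit as a test history grows.
#'
#' @param profiles A `latent_profiles` object.
#' @return Object of class `mf_risk_estimator` / `risk_estimator`.
#' @export
mf_risk_estimator <- function(profiles) {
  stopifnot(inherits(profiles, "latent_profiles"))
  structure(list(profiles = profiles),
            class = c("mf_risk_estimator", "risk_estimator"))
}

#' @export
print.mf_risk_estimator <- function(x, ...) {
  cat(sprintf("<mf_risk_estimator> backend %s, %d reference profiles, sigma %.4f\n",
              x$profiles$backend %||% "swcmf", nrow(x$profiles$values),
              x$profiles$sigma))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
init_state.mf_risk_estimator <- function(estimator, ...) {
  likelihood_weights(nrow(estimator$profiles$values))
}

#' @export
observe.mf_risk_estimator <- function(estimator, state, record, ...) {
  update_likelihood(state, record, estimator$profiles)
}

#' @export
predict_risk.mf_risk_estimator <- function(estimator, state, t_hat, ...) {
  predict_mixture_risk(state, estimator$profiles, t_hat)
}
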