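#' Hidden Markov model parameters for screening histories
#'
#' The HMM risk estimator consumes its parameters from configuration rather
#' than fitting them: three hidden states (normal / low-risk / high-risk), a
#' continuous-time transition intensity matrix whose exponential over the
#' elapsed time gives the hidden-state transition probabilities, an initial
#' law over hidden states banded by age at first exam, per-exam-type
#' emission matrices, and Poisson exam intensities per hidden state and exam
#' type from which the exam-type law `p(exam | hidden)` is derived by rate
#' normalization.
#'
#' @param initial_law 3-row-per-band matrix (bands x hidden states) of
#'   initial hidden-state probabilities, rows summing to 1.
#' @param band_breaks Interior age boundaries defining the initial-law
#'   bands.
#' @param generator 3x3 intensity matrix over hidden states (off-diagonals
#'   >= 0, rows summing to 0), or a list of per-band generators for a
#'   piecewise age-dependent chain.
#' @param emission Named list (`cytology`, `histology`) of 3x3
#'   row-stochastic matrices, rows = hidden states, columns = observed
#'   states.
#' @param exam_intensity Matrix hidden states x exam types of Poisson visit
#'   rates (per year); only the within-row ratios matter for prediction.
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(initial_law, band_breaks, generator, emission,
                       exam_intensity) {
  initial_law <- as.matrix(initial_law)
  stopifnot(ncol(initial_law) == 3,
            nrow(initial_law) == length(band_breaks) + 1)
  validate_row_stochastic(initial_law, "initial law")
  gens <- if (is.list(generator)) generator else list(generator)
  for (Q in gens) validate_generator(Q)
  stopifnot(all(EXAM_TYPES %in% names(emission)))
  for (nm in EXAM_TYPES) {
    stopifnot(all(dim(emission[[nm]]) == c(3, 3)))
    validate_row_stochastic(emission[[nm]], paste(nm, "emission"))
  }
  exam_intensity <- as.matrix(exam_intensity)
  stopifnot(nrow(exam_intensity) == 3, ncol(exam_intensity) == 2,
            all(exam_intensity >= 0), all(rowSums(exam_intensity) > 0))
  colnames(exam_intensity) <- EXAM_TYPES
  p_exam <- exam_intensity / rowSums(exam_intensity)
  structure(list(initial_law = initial_law, band_breaks = band_breaks,
                 generators = gens, banded = is.list(generator),
                 emission = emission, exam_intensity = exam_intensity,
                 p_exam_given_hidden = p_exam),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("<hmm_params> 3 hidden states, %s generator, %d initial-law bands\n",
              if (x$banded) "age-banded" else "time-homogeneous",
              nrow(x$initial_law)))
  invisible(x)
}

#' Default documented HMM parameters
#'
#' A plausible parameterization of the screening disease process used by
#' the package's tests and examples: hidden progression/regression rates of
#' the order of once per decade, histology increasingly likely (and more
#' accurate) as the hidden risk rises, and an initial law that puts more
#' mass on normal at older first-exam ages.
#'
#' @return An [hmm_params()] object.
#' @export
default_hmm_params <- function() {
  hmm_params(
    initial_law = rbind(
      c(0.92, 0.060, 0.020),
      c(0.94, 0.040, 0.020),
      c(0.955, 0.030, 0.015)
    ),
    band_breaks = c(36, 46),
    generator = rbind(
      c(-0.10, 0.09, 0.01),
      c(0.30, -0.40, 0.10),
      c(0.02, 0.08, -0.10)
    ),
    emission = list(
      cytology = rbind(
        c(0.93, 0.06, 0.01),
        c(0.40, 0.50, 0.10),
        c(0.10, 0.35, 0.55)
      ),
      histology = rbind(
        c(0.97, 0.025, 0.005),
        c(0.20, 0.70, 0.10),
        c(0.03, 0.17, 0.80)
      )
    ),
    exam_intensity = rbind(
      c(0.32, 0.01),
      c(0.45, 0.15),
      c(0.50, 0.45)
    )
  )
}

hmm_transition <- function(params, age0, age1) {
  stopifnot(age1 >= age0)
  if (!params$banded)
    return(ctmc_transition_prob(params$generators[[1]], age1 - age0))
  cuts <- sort(unique(c(age0,
                        params$band_breaks[params$band_breaks > age0 &
                                             params$band_breaks < age1],
                        age1)))
  P <- diag(3)
  for (k in seq_len(length(cuts) - 1)) {
    b <- age_band_index(cuts[k], params$band_breaks)
    b <- min(b, length(params$generators))
    P <- P %*% ctmc_transition_prob(params$generators[[b]], cuts[k + 1] - cuts[k])
  }
  P
}

#' Forward filtering for the HMM risk estimator
#'
#' `init_alpha` starts the forward variable at the first exam: the age-band
#' prior times the emission probability of the first observation.
#' `forward_update` advances it through one more exam: hidden-state
#' transition over the elapsed time (generator exponential) followed by the
#' new observation's emission. Both work on unnormalized log
#' probabilities; `alpha_probs` normalizes on demand.
#'
#' @param record One-row data frame with `age`, `exam_type`, `state`.
#' @param params An [hmm_params()].
#' @return An `alpha_state`: list with `log_alpha` (length 3) and `time`.
#' @export
init_alpha <- function(record, params) {
  check_record(record)
  band <- min(age_band_index(record$age, params$band_breaks),
              nrow(params$initial_law))
  prior <- params$initial_law[band, ]
  emis <- params$emission[[record$exam_type]][, record$state]
  la <- log(prior) + log(emis)
  if (all(!is.finite(la)))
    stop("zero prior mass everywhere for the first record")
  structure(list(log_alpha = la, time = record$age), class = "alpha_state")
}

#' @rdname init_alpha
#' @param alpha An `alpha_state`.
#' @export
forward_update <- function(alpha, record, params) {
  check_record(record)
  if (record$age <= alpha$time)
    stop("record time must strictly increase (got ", record$age,
         " after ", alpha$time, ")")
  P <- hmm_transition(params, alpha$time, record$age)
  log_emis <- log(params$emission[[record$exam_type]][, record$state])
  la <- vapply(1:3, function(h) {
    logsumexp(log(P[, h]) + alpha$log_alpha)
  }, numeric(1)) + log_emis
  structure(list(log_alpha = la, time = record$age), class = "alpha_state")
}

#' @rdname init_alpha
#' @export
alpha_probs <- function(alpha) {
  w <- exp(alpha$log_alpha - max(alpha$log_alpha))
  w / sum(w)
}

#' Predict future observed-state probabilities from the forward variable
#'
#' Marginalizes over the hidden state at the last exam, the hidden state at
#' the target age (generator exponential over the gap), and the future exam
#' type (Poisson-rate-normalized exam law per hidden state), composing with
#' the emission matrices to yield the observed-state risk triple.
#'
#' @param alpha An `alpha_state` after filtering the history.
#' @param t_hat Target age, strictly after `alpha$time`.
#' @param params An [hmm_params()].
#' @return A [risk_triple()].
#' @export
predict_state_probs <- function(alpha, t_hat, params) {
  if (t_hat <= alpha$time)
    stop("target time must be after the last filtered record")
  w <- alpha_probs(alpha)
  P <- hmm_transition(params, alpha$time, t_hat)
  q <- as.numeric(crossprod(P, w))   # distribution over future hidden state
  probs <- numeric(3)
  for (rho_i in seq_along(EXAM_TYPES)) {
    rho <- EXAM_TYPES[rho_i]
    probs <- probs +
      as.numeric(crossprod(params$emission[[rho]],
                           q * params$p_exam_given_hidden[, rho_i]))
  }
  risk_triple(probs, target_time = t_hat)
}

#' HMM risk estimator
#'
#' Wraps [hmm_params()] in the shared incremental estimator contract:
#' `observe()` runs one step of the forward recursion, `predict_risk()`
#' marginalizes the filtered hidden state forward to the target age.
#'
#' @param params An [hmm_params()] object (defaults to
#'   [default_hmm_params()]).
#' @return Object of class `hmm_risk_estimator` / `risk_estimator`.
#' @export
hmm_risk_estimator <- function(params = default_hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  structure(list(params = params),
            class = c("hmm_risk_estimator", "risk_estimator"))
}

#' @export
print.hmm_risk_estimator <- function(x, ...) {
  cat("<hmm_risk_estimator> forward-filter estimator\n")
  print(x$params)
  invisible(x)
}

#' @export
init_state.hmm_risk_estimator <- function(estimator, ...) NULL

#' @export
observe.hmm_risk_estimator <- function(estimator, state, record, ...) {
  if (is.null(state)) init_alpha(record, estimator$params)
  else forward_update(state, record, estimator$params)
}

#' @export
predict_risk.hmm_risk_estimator <- function(estimator, state, t_hat, ...) {
  if (is.null(state)) stop("no records observed yet")
  predict_state_probs(state, t_hat, estimator$params)
}
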