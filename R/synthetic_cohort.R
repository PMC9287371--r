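#' Transition probabilities of a continuous-time Markov chain
#'
#' Matrix exponential of a transition intensity matrix scaled by the elapsed
#' time: `P(dt) = expm(Q * dt)`. Rows of `Q` must sum to zero with
#' nonnegative off-diagonal rates.
#'
#' @param Q Square intensity (generator) matrix.
#' @param dt Elapsed time, years, >= 0.
#' @return Row-stochastic transition probability matrix.
#' @export
ctmc_transition_prob <- function(Q, dt) {
  validate_generator(Q)
  stopifnot(is.numeric(dt), dt >= 0)
  if (dt == 0) return(diag(nrow(Q)))
  P <- as.matrix(Matrix::expm(Q * dt))
  # clip tiny negative round-off and renormalize rows
  P[P < 0] <- 0
  P / rowSums(P)
}

validate_generator <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("generator must be a square matrix")
  off <- Q - diag(diag(Q))
  if (any(off < -1e-12))
    stop("generator off-diagonal rates must be nonnegative")
  if (any(abs(rowSums(Q)) > 1e-8))
    stop("generator rows must sum to zero")
  invisible(Q)
}

validate_row_stochastic <- function(M, what = "matrix") {
  if (any(M < -1e-12) || any(abs(rowSums(M) - 1) > 1e-12))
    stop(what, " must be row-stochastic")
  invisible(M)
}

# Reversible 3-state birth-death generator with stationary law `pi`, given
# the regression rates q21 (low->normal) and q32 (high->low). Detailed
# balance fixes the progression rates.
birth_death_generator <- function(pi, q21, q32) {
  stopifnot(length(pi) == 3, all(pi > 0), abs(sum(pi) - 1) < 1e-9)
  q12 <- q21 * pi[2] / pi[1]
  q23 <- q32 * pi[3] / pi[2]
  Q <- rbind(
    c(-q12, q12, 0),
    c(q21, -(q21 + q23), q23),
    c(0, q32, -q32)
  )
  dimnames(Q) <- list(STATE_LABELS, STATE_LABELS)
  Q
}

#' Synthetic screening-cohort generator configuration
#'
#' Defaults emulate the headline characteristics of Nordic registry screening
#' data: over 85\% of exam results normal and under 5\% high-grade, the
#' normal proportion drifting from about 0.87 before age 36 up to about 0.93
#' at ages 46+, inter-exam gaps spanning roughly one month to twenty years,
#' a median of 6 exams per history, and first exams concentrated at ages
#' 20--30.
#'
#' The underlying disease process is a 3-state continuous-time Markov chain
#' (normal / low-grade / high-grade) whose intensity matrix is piecewise
#' constant over the age bands `<36`, `36--45` and `46+`. Each band's
#' generator is reversible with a stationary law matching the band's target
#' state mix after accounting for exam misclassification. At every visit an
#' exam type is drawn conditional on the current true state (histology is
#' more likely after abnormality) and the observed state is drawn through
#' the exam type's confusion matrix; histology is the less noisy modality.
#'
#' @param n_histories Number of subjects to simulate.
#' @param seed Master seed; per-subject substreams are derived from it so a
#'   cohort is reproducible and independent of simulation order.
#' @param first_exam_age Normal location/scale plus truncation bounds for the
#'   age at first exam.
#' @param visit_gap Log-normal parameters and truncation bounds (years) for
#'   the gaps between successive exams.
#' @param band_breaks Interior age-band boundaries (years).
#' @param band_stationary List of 3 stationary laws over the true states, one
#'   per age band.
#' @param regression_rates Rates (per year) of low-grade to normal and
#'   high-grade to low-grade regression used to build each band's generator.
#' @param prob_histology Probability that a visit uses histology, per current
#'   true state.
#' @param confusion List with row-stochastic 3x3 confusion matrices
#'   `cytology` and `histology` mapping true to observed state.
#' @param n_exams Shifted negative-binomial law for exams per history:
#'   `1 + rnbinom(size, mu)`, calibrated so the cohort median is 6.
#' @param max_age Visits beyond this age are not generated (histories are
#'   truncated, never emptied).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    n_histories = 10000L,
    seed = 2026L,
    first_exam_age = list(mean = 26, sd = 5, min = 18, max = 55),
    visit_gap = list(meanlog = log(2.0), sdlog = 0.85, min = 1 / 12, max = 20),
    band_breaks = c(36, 46),
    band_stationary = list(
      c(0.890, 0.080, 0.030),
      c(0.925, 0.055, 0.020),
      c(0.965, 0.026, 0.009)
    ),
    regression_rates = c(low_to_normal = 0.45, high_to_low = 0.12),
    prob_histology = c(0.03, 0.30, 0.60),
    confusion = list(
      cytology = rbind(
        c(0.955, 0.040, 0.005),
        c(0.320, 0.600, 0.080),
        c(0.050, 0.200, 0.750)
      ),
      histology = rbind(
        c(0.970, 0.025, 0.005),
        c(0.120, 0.780, 0.100),
        c(0.020, 0.100, 0.880)
      )
    ),
    n_exams = list(size = 2.2, mu = 6.2),
    max_age = 79.5) {
  stopifnot(n_histories >= 1, length(band_breaks) + 1 == length(band_stationary))
  for (pi_b in band_stationary)
    stopifnot(length(pi_b) == 3, all(pi_b > 0), abs(sum(pi_b) - 1) < 1e-9)
  for (nm in EXAM_TYPES)
    validate_row_stochastic(confusion[[nm]], paste(nm, "confusion matrix"))
  stopifnot(all(prob_histology >= 0 & prob_histology <= 1))
  generators <- lapply(band_stationary, birth_death_generator,
                       q21 = regression_rates[[1]], q32 = regression_rates[[2]])
  for (Q in generators) validate_generator(Q)
  structure(
    list(n_histories = as.integer(n_histories), seed = as.integer(seed),
         first_exam_age = first_exam_age, visit_gap = visit_gap,
         band_breaks = band_breaks, band_stationary = band_stationary,
         generators = generators, prob_histology = prob_histology,
         confusion = confusion, n_exams = n_exams, max_age = max_age),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d histories, seed %d, %d age bands\n",
              x$n_histories, x$seed, length(x$band_stationary)))
  invisible(x)
}

age_band_index <- function(age, breaks) {
  findInterval(age, breaks) + 1L
}

# Transition probability matrix over [age0, age1] under the piecewise
# age-band generator: the interval is split at band boundaries and the
# per-segment exponentials are chained.
piecewise_transition <- function(age0, age1, config) {
  stopifnot(age1 >= age0)
  cuts <- sort(unique(c(age0, config$band_breaks[config$band_breaks > age0 &
                                                   config$band_breaks < age1], age1)))
  P <- diag(3)
  for (k in seq_len(length(cuts) - 1)) {
    b <- age_band_index(cuts[k], config$band_breaks)
    P <- P %*% ctmc_transition_prob(config$generators[[b]], cuts[k + 1] - cuts[k])
  }
  P
}

rtrunc_norm1 <- function(mean, sd, lo, hi) {
  u <- stats::runif(1, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

rtrunc_lnorm1 <- function(meanlog, sdlog, lo, hi) {
  u <- stats::runif(1, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

#' Simulate a single screening history
#'
#' Draws the age at first exam, the number of exams, and the visit ages; the
#' true state evolves between visits as a continuous-time Markov chain under
#' the age band's intensity matrix. At each visit an exam type is drawn given
#' the current true state and the observed state is drawn through that exam's
#' confusion matrix.
#'
#' @param config A [generator_config()].
#' @param subject_id Identifier for the simulated subject.
#' @return Data frame with columns `subject_id`, `age`, `exam_type`, `state`
#'   and `true_state` (the simulator's latent state, used by oracle checks).
#' @export
simulate_history <- function(config, subject_id = "s1") {
  fa <- config$first_exam_age
  age <- rtrunc_norm1(fa$mean, fa$sd, fa$min, fa$max)
  n_visits <- 1L + stats::rnbinom(1, size = config$n_exams$size,
                                  mu = config$n_exams$mu)
  band <- age_band_index(age, config$band_breaks)
  s_true <- sample.int(3L, 1L, prob = config$band_stationary[[band]])
  ages <- numeric(n_visits)
  true_states <- integer(n_visits)
  i <- 1L
  ages[1L] <- age
  true_states[1L] <- s_true
  while (i < n_visits) {
    g <- config$visit_gap
    gap <- rtrunc_lnorm1(g$meanlog, g$sdlog, g$min, g$max)
    next_age <- age + gap
    if (next_age > config$max_age) break
    P <- piecewise_transition(age, next_age, config)
    s_true <- sample.int(3L, 1L, prob = P[s_true, ])
    i <- i + 1L
    ages[i] <- next_age
    true_states[i] <- s_true
    age <- next_age
  }
  ages <- ages[seq_len(i)]
  true_states <- true_states[seq_len(i)]
  is_hist <- stats::runif(i) < config$prob_histology[true_states]
  exam_type <- ifelse(is_hist, "histology", "cytology")
  observed <- vapply(seq_len(i), function(k) {
    C <- config$confusion[[exam_type[k]]]
    sample.int(3L, 1L, prob = C[true_states[k], ])
  }, integer(1))
  data.frame(subject_id = subject_id, age = ages, exam_type = exam_type,
             state = observed, true_state = true_states,
             stringsAsFactors = FALSE)
}

#' Simulate a screening cohort
#'
#' Histories are drawn independently from per-subject substreams derived from
#' the master seed, so the cohort is reproducible and does not depend on
#' simulation order. The global RNG state is left untouched.
#'
#' @param config A [generator_config()].
#' @return A [screening_cohort()] whose data carries the simulator's
#'   `true_state` column; metadata echoes the configuration.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  # one pre-drawn substream seed per subject (< 2^31)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_histories)
  ids <- sprintf("s%06d", seq_len(config$n_histories))
  histories <- vector("list", config$n_histories)
  for (k in seq_len(config$n_histories)) {
    set.seed(sub_seeds[k])
    histories[[k]] <- simulate_history(config, subject_id = ids[k])
  }
  screening_cohort(do.call(rbind, histories),
                   metadata = list(generator = config))
}

#' Per-age-bin state distribution
#'
#' Proportions of observed states inside each age bin; the tool used to check
#' the age drift of the state distribution (e.g. the normal share rising from
#' about 0.87 under age 36 to about 0.93 at 46+).
#'
#' @param cohort A [screening_cohort()].
#' @param age_bins List of half-open intervals `c(lo, hi)`; must not overlap.
#' @return Data frame with one row per bin: `lo`, `hi`, `n`, and proportions
#'   `p_normal`, `p_low_grade`, `p_high_grade` (NA when the bin is empty).
#' @export
state_distribution_by_age <- function(cohort,
                                      age_bins = list(c(16, 36), c(36, 46), c(46, 80))) {
  stopifnot(inherits(cohort, "screening_cohort"), length(age_bins) >= 1)
  bins <- do.call(rbind, lapply(age_bins, function(b) {
    stopifnot(length(b) == 2, b[1] < b[2])
    b
  }))
  ord <- order(bins[, 1])
  bins <- bins[ord, , drop = FALSE]
  if (nrow(bins) > 1 && any(bins[-1, 1] < bins[-nrow(bins), 2] - 1e-12))
    stop("age bins overlap")
  out <- lapply(seq_len(nrow(bins)), function(k) {
    sel <- cohort$data$age >= bins[k, 1] & cohort$data$age < bins[k, 2]
    n <- sum(sel)
    p <- if (n) as.numeric(prop.table(table(factor(cohort$data$state[sel],
                                                   levels = STATES))))
         else rep(NA_real_, 3)
    data.frame(lo = bins[k, 1], hi = bins[k, 2], n = n,
               p_normal = p[1], p_low_grade = p[2], p_high_grade = p[3])
  })
  do.call(rbind, out)
}
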