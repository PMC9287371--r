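#' Oracle risk estimator reading the simulator's true state
#'
#' An upper-bound comparator available only on synthetic cohorts: it reads
#' the simulated subject's latent true state at the last observed visit and
#' propagates it to the target age with the generator actually used by the
#' simulator, composing with the simulator's exam-type and confusion laws
#' to yield the exact distribution of the next observed state. No fitted
#' model can beat it other than by chance.
#'
#' @param config The [generator_config()] that produced the cohort.
#' @return Object of class `oracle_risk_estimator` / `risk_estimator`.
#' @export
oracle_risk_estimator <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  structure(list(config = config),
            class = c("oracle_risk_estimator", "risk_estimator"))
}

#' @export
init_state.oracle_risk_estimator <- function(estimator, ...) {
  list(true_state = NA_integer_, last_time = -Inf)
}

#' @export
observe.oracle_risk_estimator <- function(estimator, state, record, ...) {
  if (is.null(record$true_state))
    stop("oracle estimator needs the simulator's true_state column")
  if (record$age <= state$last_time) stop("out-of-order record")
  list(true_state = as.integer(record$true_state), last_time = record$age)
}

#' @export
predict_risk.oracle_risk_estimator <- function(estimator, state, t_hat, ...) {
  if (!is.finite(state$last_time)) stop("no records observed yet")
  if (t_hat <= state$last_time) stop("target time must be after last record")
  cfg <- estimator$config
  P <- piecewise_transition(state$last_time, t_hat, cfg)
  p_true <- P[state$true_state, ]
  probs <- numeric(3)
  for (s in STATES) {
    mix <- (1 - cfg$prob_histology[s]) * cfg$confusion$cytology[s, ] +
      cfg$prob_histology[s] * cfg$confusion$histology[s, ]
    probs <- probs + p_true[s] * mix
  }
  risk_triple(probs, target_time = t_hat)
}

#' Split a cohort into training and test sets
#'
#' Implements the registry-style sampling rules: only histories with at
#' least `min_exams` results are eligible; training histories are drawn
#' sequentially without replacement with selection weight proportional to
#' the most severe result in the history (enriching abnormal histories);
#' test histories are drawn uniformly from the remainder restricted to a
#' first exam at ages 20--30. The two sets are disjoint by construction.
#'
#' @param cohort A [screening_cohort()].
#' @param n_train,n_test Requested set sizes.
#' @param min_exams Minimum records per eligible history (default 3).
#' @param test_first_exam_age Closed age range for the test-side first exam.
#' @param seed Seed for the weighted draws.
#' @return List with `train` and `test` cohorts.
#' @export
sample_train_test <- function(cohort, n_train, n_test, min_exams = 3L,
                              test_first_exam_age = c(20, 30), seed = 1L) {
  stopifnot(inherits(cohort, "screening_cohort"))
  histories <- cohort_histories(cohort)
  sizes <- vapply(histories, nrow, integer(1))
  eligible <- names(histories)[sizes >= min_exams]
  if (length(eligible) < n_train)
    stop("only ", length(eligible), " histories with >= ", min_exams,
         " exams; cannot draw ", n_train, " training histories")
  weights <- vapply(histories[eligible], most_severe_state, integer(1))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  train_ids <- sample(eligible, n_train, prob = weights)
  rest <- setdiff(eligible, train_ids)
  first_age <- vapply(histories[rest], function(h) min(h$age), numeric(1))
  pool <- rest[first_age >= test_first_exam_age[1] &
                 first_age <= test_first_exam_age[2]]
  if (length(pool) < n_test)
    stop("only ", length(pool), " eligible test histories (first exam in [",
         test_first_exam_age[1], ", ", test_first_exam_age[2],
         "]); cannot draw ", n_test)
  test_ids <- sample(pool, n_test)
  subset_cohort <- function(ids) {
    screening_cohort(cohort$data[cohort$data$subject_id %in% ids, ,
                                 drop = FALSE],
                     metadata = cohort$metadata)
  }
  list(train = subset_cohort(train_ids), test = subset_cohort(test_ids))
}

#' Moving-window incremental predictions over one history
#'
#' Emulates a history growing over time: the first two results are
#' revealed to the estimator, the third is predicted, then each previous
#' result is incorporated via the estimator's incremental update before
#' predicting the next one. A prediction may only condition on records at
#' least `horizon` years (six months by default) before the target; a
#' record inside the gap is withheld until a later target admits it.
#' Targets whose mandatory first two records fall inside the gap are
#' skipped and reported.
#'
#' @param estimator A fitted risk estimator (shared contract).
#' @param history Data frame of one subject's records (>= 3 rows).
#' @param horizon Gap between the last usable record and the target,
#'   years.
#' @return List with `predictions` (data frame: `target_index`,
#'   `target_age`, `p1`, `p2`, `p3`, `truth`) and `skipped` (target
#'   indices dropped under the gap rule).
#' @export
rolling_prediction <- function(estimator, history, horizon = 0.5) {
  stopifnot(nrow(history) >= 3)
  state <- init_state(estimator)
  incorporated <- 0L
  preds <- list(); skipped <- integer(0)
  for (j in 3:nrow(history)) {
    cut <- history$age[j] - horizon
    # reveal the mandatory first two, then any record clearing the gap
    while (incorporated < j - 1L &&
           (incorporated < 2L || history$age[incorporated + 1L] <= cut)) {
      incorporated <- incorporated + 1L
      state <- observe(estimator, state,
                       history[incorporated, , drop = FALSE])
    }
    if (history$age[incorporated] > cut) {
      skipped <- c(skipped, j)
      next
    }
    p <- predict_risk(estimator, state, history$age[j])
    preds[[length(preds) + 1L]] <- data.frame(
      target_index = j, target_age = history$age[j],
      p1 = p[1], p2 = p[2], p3 = p[3], truth = history$state[j])
  }
  list(predictions = if (length(preds)) do.call(rbind, preds)
       else data.frame(target_index = integer(0), target_age = numeric(0),
                       p1 = numeric(0), p2 = numeric(0), p3 = numeric(0),
                       truth = integer(0)),
       skipped = skipped)
}

rolling_predictions_cohort <- function(estimator, cohort, horizon = 0.5) {
  histories <- cohort_histories(cohort)
  histories <- histories[vapply(histories, nrow, integer(1)) >= 3]
  out <- vector("list", length(histories))
  failed <- character(0)
  for (k in seq_along(histories)) {
    h <- histories[[k]]
    res <- tryCatch(rolling_prediction(estimator, h, horizon),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, h$subject_id[1])
      next
    }
    if (nrow(res$predictions)) {
      res$predictions$subject_id <- h$subject_id[1]
      out[[k]] <- res$predictions
    }
  }
  preds <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  attr(preds, "failed_subjects") <- failed
  preds
}

#' Experiment configuration
#'
#' @param generator A [generator_config()] for the simulated cohort.
#' @param n_train,n_test Training and test set sizes (training histories
#'   also feed the latent profile matrix and the baseline learners).
#' @param n_validation Hold-out histories used to fit the adaptive
#'   thresholds and the Z-scoring parameters. They are drawn from the
#'   cohort remainder (disjoint from both training and test subjects)
#'   under the same filters as the test set, so the thresholds are tuned
#'   on the natural state distribution rather than the severity-enriched
#'   training one.
#' @param estimators Character vector out of `"mf"`, `"gdl"`, `"hmm"`,
#'   `"lr"`, `"rf"`, `"gtb"`, `"oracle"`.
#' @param horizon Prediction gap in years (default 0.5 = six months).
#' @param min_exams Minimum exams per usable history (default 3).
#' @param intervals [age_intervals()] for the adaptive strategy.
#' @param factorization [factorization_config()] for the mf/gdl backends.
#' @param hmm [hmm_params()] for the HMM estimator.
#' @param grid [age_grid()] for the latent profile matrix.
#' @param seed Seed governing sampling and stochastic learners.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              n_train = 1000L, n_test = 2000L,
                              n_validation = 300L,
                              estimators = c("mf", "hmm", "lr"),
                              horizon = 0.5, min_exams = 3L,
                              intervals = age_intervals(),
                              factorization = factorization_config(),
                              hmm = default_hmm_params(),
                              grid = age_grid(),
                              seed = 1L) {
  stopifnot(horizon > 0, min_exams >= 3)
  known <- c("mf", "gdl", "hmm", "lr", "rf", "gtb", "oracle")
  stopifnot(all(estimators %in% known))
  structure(list(generator = generator, n_train = as.integer(n_train),
                 n_test = as.integer(n_test),
                 n_validation = as.integer(n_validation),
                 estimators = estimators, horizon = horizon,
                 min_exams = as.integer(min_exams), intervals = intervals,
                 factorization = factorization, hmm = hmm, grid = grid,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

fit_experiment_estimators <- function(config, fit_histories, val_histories,
                                      Z) {
  ests <- list()
  for (nm in config$estimators) {
    ests[[nm]] <- switch(
      nm,
      mf = mf_risk_estimator(fit_swcmf(Z, config$factorization)),
      gdl = mf_risk_estimator(fit_gdl(Z, config = config$factorization)),
      hmm = hmm_risk_estimator(config$hmm),
      lr = baseline_risk_estimator("lr", fit_histories,
                                   zscore_histories = val_histories,
                                   horizon = config$horizon,
                                   seed = config$seed),
      rf = baseline_risk_estimator("rf", fit_histories,
                                   horizon = config$horizon,
                                   seed = config$seed),
      gtb = baseline_risk_estimator("gtb", fit_histories,
                                    horizon = config$horizon,
                                    seed = config$seed),
      oracle = oracle_risk_estimator(config$generator)
    )
  }
  ests
}

#' Run the end-to-end prediction experiment
#'
#' Simulates a screening cohort, samples training and test histories under
#' the registry-style rules, fits every requested estimator on the
#' training side, runs the moving-window incremental prediction protocol
#' over the test histories, fits the adaptive thresholds on a disjoint
#' hold-out validation split, classifies under both strategies and
#' assembles the report: stratified Brier scores, multiclass MCC per age
#' interval per strategy, and absolute risk curves with the
#' relative-deviation indicator per state. Fully reproducible under the
#' configured seeds.
#'
#' @param config An [experiment_config()].
#' @param cohort Optionally a pre-simulated [screening_cohort()] (must
#'   carry `true_state` if the oracle estimator is requested).
#' @return Object of class `screenrisk_experiment`: list with
#'   `predictions` (long per-prediction log), `thresholds`, `brier`, `rk`,
#'   `eta`, `curves`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(config$generator)
  split <- sample_train_test(cohort, config$n_train, config$n_test,
                             min_exams = config$min_exams,
                             seed = config$seed)
  fit_histories <- cohort_histories(split$train)
  # hold-out validation split for thresholds and Z-scoring: drawn from the
  # remainder (never train or test) under the test-side filters, so it
  # reflects the natural (un-enriched) state distribution
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed + 1L)
  used <- unique(cohort$data$subject_id[cohort$data$subject_id %in%
                                          c(names(fit_histories),
                                            unique(split$test$data$subject_id))])
  rest <- cohort_histories(cohort)
  rest <- rest[setdiff(names(rest), used)]
  sizes <- vapply(rest, nrow, integer(1))
  first_age <- vapply(rest, function(h) min(h$age), numeric(1))
  pool <- names(rest)[sizes >= config$min_exams &
                        first_age >= 20 & first_age <= 30]
  if (length(pool) < config$n_validation)
    stop("only ", length(pool), " eligible hold-out validation histories; ",
         "cannot draw ", config$n_validation)
  val_histories <- rest[sample(pool, config$n_validation)]
  val_cohort <- screening_cohort(do.call(rbind, val_histories))
  Z <- to_state_matrix(screening_cohort(do.call(rbind, fit_histories)),
                       config$grid)

  estimators <- fit_experiment_estimators(config, fit_histories,
                                          val_histories, Z)

  all_preds <- list(); thresholds <- list()
  for (nm in names(estimators)) {
    est <- estimators[[nm]]
    val_preds <- rolling_predictions_cohort(est, val_cohort, config$horizon)
    thresholds[[nm]] <- fit_thresholds(
      as.matrix(val_preds[, c("p1", "p2", "p3")]), val_preds$truth,
      val_preds$target_age, config$intervals, seed = config$seed,
      n_boot = 25L)
    preds <- rolling_predictions_cohort(est, split$test, config$horizon)
    preds$model <- nm
    P <- as.matrix(preds[, c("p1", "p2", "p3")])
    preds$pred_default <- apply(P, 1, classify_default)
    preds$pred_adaptive <- vapply(seq_len(nrow(P)), function(i) {
      classify_adaptive(P[i, ], preds$target_age[i], thresholds[[nm]],
                        config$intervals)
    }, integer(1))
    all_preds[[nm]] <- preds
  }
  predictions <- do.call(rbind, all_preds)
  rownames(predictions) <- NULL

  report <- summarize_experiment(predictions, config$intervals)
  structure(c(report,
              list(predictions = predictions, thresholds = thresholds,
                   config = config)),
            class = "screenrisk_experiment")
}

#' Recompute the report tables from a per-prediction log
#'
#' Evaluation is a pure function of the per-prediction log, so the report
#' can be regenerated from the persisted log alone.
#'
#' @param predictions Long data frame as produced by [run_experiment()].
#' @param intervals [age_intervals()] used for the per-interval scores.
#' @param window Risk-curve window width, years.
#' @return List with `brier`, `rk`, `curves`, `eta`.
#' @export
summarize_experiment <- function(predictions, intervals = age_intervals(),
                                 window = 10 / 12) {
  models <- unique(predictions$model)
  brier <- t(vapply(models, function(nm) {
    d <- predictions[predictions$model == nm, ]
    brier_stratified(as.matrix(d[, c("p1", "p2", "p3")]), d$truth)
  }, numeric(3)))
  ki <- interval_index(predictions$target_age, intervals)
  rk <- do.call(rbind, lapply(models, function(nm) {
    sel_m <- predictions$model == nm
    do.call(rbind, lapply(seq_len(intervals$n), function(k) {
      d <- predictions[sel_m & ki == k, ]
      data.frame(model = nm, interval = k,
                 rk_default = if (nrow(d)) mcc_multiclass(d$truth, d$pred_default)
                              else NA_real_,
                 rk_adaptive = if (nrow(d)) mcc_multiclass(d$truth, d$pred_adaptive)
                               else NA_real_)
    }))
  }))
  t0 <- min(predictions$target_age)
  d0 <- predictions[predictions$model == models[1], ]
  reference <- absolute_risk_curve(d0$target_age, d0$truth, window, t_min = t0)
  curves <- list(reference = reference)
  etas <- do.call(rbind, lapply(models, function(nm) {
    d <- predictions[predictions$model == nm, ]
    pc <- absolute_risk_curve(d$target_age, d$pred_adaptive, window, t_min = t0)
    curves[[nm]] <<- pc
    data.frame(model = nm, state = STATES,
               eta = vapply(STATES, function(s) eta(reference, pc, state = s),
                            numeric(1)))
  }))
  list(brier = brier, rk = rk, curves = curves, eta = etas)
}

#' @export
print.screenrisk_experiment <- function(x, ...) {
  cat("<screenrisk_experiment>\n")
  cat(sprintf("  %d predictions, models: %s\n", nrow(x$predictions),
              paste(unique(x$predictions$model), collapse = ", ")))
  cat("\nBrier scores stratified by true state:\n")
  print(round(x$brier, 4))
  cat("\nR_K by age interval (default vs adaptive):\n")
  print(transform(x$rk, rk_default = round(rk_default, 4),
                  rk_adaptive = round(rk_adaptive, 4)), row.names = FALSE)
  cat("\neta (relative deviation of adaptive-strategy risk curves):\n")
  e <- x$eta; e$eta <- round(e$eta, 4)
  print(e, row.names = FALSE)
  invisible(x)
}

#' Plot absolute risk curves from an experiment
#'
#' One panel per state: the reference (hold-out) curve with each model's
#' predicted curve overlaid, mirroring the standard calibration display for
#' this analysis.
#'
#' @param x A `screenrisk_experiment`.
#' @param states States to plot (default all three).
#' @param ... Unused.
#' @export
plot.screenrisk_experiment <- function(x, states = STATES, ...) {
  curves <- x$curves
  models <- setdiff(names(curves), "reference")
  op <- graphics::par(mfrow = c(1, length(states)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in states) {
    col <- paste0("p", s)
    ref <- curves$reference
    ylim <- range(unlist(lapply(curves, `[[`, col)), na.rm = TRUE)
    plot(ref$center, ref[[col]], type = "l", lwd = 2, ylim = ylim,
         xlab = "age (years)", ylab = "absolute risk",
         main = STATE_LABELS[s])
    for (i in seq_along(models))
      graphics::lines(curves[[models[i]]]$center, curves[[models[i]]][[col]],
                      col = i + 1, lty = 2)
    graphics::legend("topright", legend = c("reference", models),
                     col = c(1, seq_along(models) + 1),
                     lty = c(1, rep(2, length(models))), cex = 0.7, bty = "n")
  }
  invisible(x)
}
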