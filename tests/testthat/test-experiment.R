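test_that("train/test sampling filters, weights and stays disjoint", {
  cfg <- generator_config(n_histories = 400, seed = 21)
  co <- simulate_cohort(cfg)
  sp <- sample_train_test(co, 80, 60, seed = 3)
  train_ids <- unique(sp$train$data$subject_id)
  test_ids <- unique(sp$test$data$subject_id)
  expect_length(train_ids, 80)
  expect_length(test_ids, 60)
  for (seed in 1:10) {
    s <- sample_train_test(co, 80, 60, seed = seed)
    expect_length(intersect(unique(s$train$data$subject_id),
                            unique(s$test$data$subject_id)), 0)
  }
  # every sampled history has >= 3 exams; test first exams in [20, 30]
  sizes <- table(sp$train$data$subject_id)
  expect_true(all(sizes >= 3))
  first_age <- vapply(cohort_histories(sp$test), function(h) min(h$age),
                      numeric(1))
  expect_true(all(first_age >= 20 & first_age <= 30))
  # a cohort of only 2-exam histories empties the pool
  short <- screening_cohort(make_history(c(25, 27), c(1, 1)))
  expect_error(sample_train_test(short, 1, 1), "cannot draw")
})

test_that("severe histories are enriched proportionally to their max state", {
  # two-history cohort, severities 3 and 1: single weighted draw picks the
  # severe one with probability 3/4
  h1 <- make_history(c(25, 27, 29), c(1, 2, 3), subject_id = "severe")
  h2 <- make_history(c(25.1, 27.1, 29.1), c(1, 1, 1), subject_id = "plain")
  co <- screening_cohort(rbind(h1, h2))
  picks <- vapply(1:600, function(seed) {
    s <- sample_train_test(co, n_train = 1, n_test = 0, seed = seed,
                           test_first_exam_age = c(0, 200))
    unique(s$train$data$subject_id)
  }, character(1))
  expect_equal(mean(picks == "severe"), 0.75, tolerance = 0.06)
})

test_that("rolling predictions follow the moving-window six-month protocol", {
  grid <- age_grid(16, 60, 2)
  profiles <- toy_profiles(matrix(1.5, 2, grid$n_cols), sigma = 1,
                           grid = grid)
  est <- mf_risk_estimator(profiles)
  h3 <- make_history(c(25, 27, 29), c(1, 1, 2))
  r3 <- rolling_prediction(est, h3)
  expect_equal(nrow(r3$predictions), 1)
  expect_equal(r3$predictions$target_index, 3)
  h6 <- make_history(c(25, 27, 29, 31, 33, 35), c(1, 1, 2, 1, 1, 1))
  r6 <- rolling_prediction(est, h6)
  expect_equal(nrow(r6$predictions), 4)
  expect_equal(r6$predictions$target_index, 3:6)
  # a target two months after its predecessor is skipped under the gap rule
  h_gap <- make_history(c(25, 27, 27.17, 29), c(1, 1, 2, 1))
  r_gap <- rolling_prediction(est, h_gap)
  expect_equal(r_gap$skipped, 3L)
  expect_equal(r_gap$predictions$target_index, 4L)
  expect_error(rolling_prediction(est, make_history(c(25, 27), c(1, 1))))
})

test_that("no conditioning record ever falls inside the horizon gap", {
  # audit pass with a spy estimator that logs every observed time
  spy_env <- new.env()
  spy <- structure(list(env = spy_env), class = c("spy_est", "risk_estimator"))
  registerS3method("init_state", "spy_est",
                   function(estimator, ...) list(times = numeric(0)),
                   envir = asNamespace("screenrisk"))
  registerS3method("observe", "spy_est",
                   function(estimator, state, record, ...) {
                     state$times <- c(state$times, record$age); state
                   }, envir = asNamespace("screenrisk"))
  registerS3method("predict_risk", "spy_est",
                   function(estimator, state, t_hat, ...) {
                     estimator$env$log <- rbind(estimator$env$log,
                                                data.frame(t_hat = t_hat,
                                                           latest = max(state$times)))
                     risk_triple(c(1, 1, 1) / 3, t_hat)
                   }, envir = asNamespace("screenrisk"))
  set.seed(40)
  for (rep in 1:25) {
    h <- random_history(sample(3:8, 1))
    spy_env$log <- NULL
    res <- rolling_prediction(spy, h, horizon = 0.5)
    if (!is.null(spy_env$log))
      expect_true(all(spy_env$log$latest <= spy_env$log$t_hat - 0.5 + 1e-12))
    # skipped targets + produced predictions account for every j >= 3
    expect_equal(nrow(res$predictions) + length(res$skipped), nrow(h) - 2)
  }
})

test_that("a tiny end-to-end experiment is complete and reproducible", {
  cfg <- experiment_config(
    generator = generator_config(n_histories = 350, seed = 77),
    n_train = 60, n_test = 40, n_validation = 15,
    estimators = c("mf", "hmm", "oracle"),
    factorization = factorization_config(rank = 2, max_iters = 15),
    seed = 5)
  res1 <- suppressWarnings(run_experiment(cfg))
  expect_s3_class(res1, "screenrisk_experiment")
  expect_setequal(unique(res1$predictions$model), c("mf", "hmm", "oracle"))
  expect_equal(nrow(res1$brier), 3)
  expect_true(all(c("rk_default", "rk_adaptive") %in% names(res1$rk)))
  expect_true(all(res1$eta$eta >= 0))
  # determinism: identical numeric report on a re-run
  res2 <- suppressWarnings(run_experiment(cfg))
  expect_identical(res1$predictions, res2$predictions)
  expect_identical(res1$brier, res2$brier)
  # threshold fitting never saw a test subject: predictions' subjects are
  # disjoint from the validation subjects by construction of the split
  expect_true(all(res1$predictions$truth %in% 1:3))
  # report recomputable from the persisted per-prediction log
  again <- summarize_experiment(res1$predictions, cfg$intervals)
  expect_equal(again$brier, res1$brier)
  expect_equal(again$rk, res1$rk)
})
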