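#' Cumulative count features for the machine learning comparators
#'
#' Builds the feature vector used by the logistic regression, random forest
#' and gradient boosting comparators: cumulative counts of each state
#' crossed with exam type over the records up to the cut time (six counts),
#' together with the age at the last counted exam and the target age.
#'
#' @param history Data frame of one subject's records.
#' @param cut_time Only records with `age <= cut_time` are counted.
#' @param t_hat Target age (> `cut_time`).
#' @return Named numeric vector of length 8.
#' @export
build_features <- function(history, cut_time, t_hat) {
  stopifnot(cut_time < t_hat)
  sel <- history$age <= cut_time
  if (!any(sel)) stop("no records at or before the cut time")
  h <- history[sel, , drop = FALSE]
  counts <- table(factor(h$exam_type, levels = EXAM_TYPES),
                  factor(h$state, levels = STATES))
  out <- c(as.numeric(t(counts)), max(h$age), t_hat)
  names(out) <- c(t(outer(c("cyt", "hist"), STATES,
                          function(e, s) paste0("n_", e, "_s", s))),
                  "age_last_exam", "age_target")
  out
}

#' Z-scoring with frozen normalization parameters
#'
#' Standardizes features to zero mean and unit standard deviation using
#' moments estimated once from a training block; the frozen parameters are
#' then applied to any later data without recomputation. Standard
#' deviations are floored to avoid division by zero on constant features.
#'
#' @param train Numeric matrix (rows = samples) used to estimate moments.
#' @param sd_floor Minimum standard deviation.
#' @return `zscore_fit`: list with `mean`, `sd` (floored) and
#'   `constant` flags.
#' @export
zscore_fit <- function(train, sd_floor = 1e-8) {
  train <- as.matrix(train)
  stopifnot(nrow(train) >= 1)
  mu <- colMeans(train)
  # population convention: divide by n, so {0, 2} maps to {-1, 1}
  sdv <- sqrt(colMeans(sweep(train, 2, mu)^2))
  constant <- sdv < sd_floor
  list(mean = mu, sd = pmax(sdv, sd_floor), constant = constant)
}

#' @rdname zscore_fit
#' @param params A `zscore_fit` result.
#' @param x Matrix (or vector) to normalize with the frozen parameters.
#' @export
zscore_apply <- function(params, x) {
  one_row <- is.null(dim(x))
  x <- if (one_row) matrix(x, nrow = 1) else as.matrix(x)
  out <- sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
  out[, params$constant] <- 0
  if (one_row) out[1, ] else out
}

# Training design: one row per (history, target index >= 2) pair, honouring
# the prediction horizon when counting features.
baseline_training_design <- function(histories, horizon = 0.5) {
  rows <- list(); ys <- integer(0)
  for (h in histories) {
    if (nrow(h) < 2) next
    for (j in 2:nrow(h)) {
      cut <- h$age[j] - horizon
      if (!any(h$age <= cut)) next
      rows[[length(rows) + 1L]] <- build_features(h, cut, h$age[j])
      ys[length(ys) + 1L] <- h$state[j]
    }
  }
  if (!length(rows)) stop("no usable training targets for the baselines")
  list(X = do.call(rbind, rows), y = ys)
}

fit_baseline_learner <- function(model, X, y, seed = 1L, prev = NULL,
                                 zs = NULL) {
  yf <- factor(y, levels = STATES)
  if (model == "lr") {
    Xn <- zscore_apply(zs, X)
    df <- data.frame(Xn, y = yf)
    wts <- if (!is.null(prev)) prev$wts else NULL
    fit <- tryCatch(
      nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 300, Wts = wts),
      error = function(e) nnet::multinom(y ~ ., data = df, trace = FALSE,
                                         maxit = 300))
    list(fit = fit, wts = fit$wts)
  } else if (model == "rf") {
    df <- data.frame(X, y = yf)
    list(fit = ranger::ranger(y ~ ., data = df, probability = TRUE,
                              num.trees = 100, seed = seed, num.threads = 1,
                              respect.unordered.factors = TRUE))
  } else if (model == "gtb") {
    dtr <- xgboost::xgb.DMatrix(as.matrix(X), label = as.integer(yf) - 1L)
    nr <- if (is.null(prev)) 60L else 20L
    list(fit = xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = 3,
                    max_depth = 4, eta = 0.2, nthread = 1, seed = seed),
      data = dtr, nrounds = nr, verbose = 0,
      xgb_model = prev$fit))
  } else stop("unknown baseline model: ", model)
}

predict_baseline_probs <- function(model, learner, x, zs = NULL) {
  if (model == "lr") {
    xn <- zscore_apply(zs, x)
    df <- as.data.frame(matrix(xn, nrow = 1,
                               dimnames = list(NULL, names(zs$mean))))
    p3 <- numeric(3); names(p3) <- STATES
    pr <- stats::predict(learner$fit, newdata = df, type = "probs")
    if (is.null(dim(pr)) && length(pr) == 1) {
      # two-class fit: multinom returns P(second level)
      lv <- learner$fit$lev
      p3[lv[1]] <- 1 - pr; p3[lv[2]] <- pr
    } else if (is.null(dim(pr))) p3[names(pr)] <- pr
    else p3[colnames(pr)] <- pr
    as.numeric(p3)
  } else if (model == "rf") {
    df <- as.data.frame(matrix(x, nrow = 1, dimnames = list(NULL, names(x))))
    pr <- stats::predict(learner$fit, data = df)$predictions
    p3 <- numeric(3); names(p3) <- STATES
    p3[colnames(pr)] <- pr[1, ]
    as.numeric(p3)
  } else {
    pr <- stats::predict(learner$fit,
                         xgboost::xgb.DMatrix(matrix(x, nrow = 1)))
    as.numeric(matrix(pr, ncol = 3, byrow = TRUE)[1, ])
  }
}

#' Feature-based baseline risk estimators
#'
#' Adapters giving multinomial logistic regression (`"lr"`), random forest
#' (`"rf"`) and gradient tree boosting (`"gtb"`) the shared incremental
#' estimator contract. The learners are fit on cumulative count features
#' (see [build_features()]) built from the training histories; logistic
#' regression features are Z-scored with parameters frozen from a hold-out
#' block. `observe()` extends the subject's record buffer;
#' `predict_risk()` rebuilds the feature vector at the current cut and
#' queries the fitted learner, renormalizing the class probabilities.
#'
#' @param model One of `"lr"`, `"rf"`, `"gtb"`.
#' @param train_histories List of per-subject data frames used to fit the
#'   learner.
#' @param zscore_histories Optional hold-out block whose features freeze the
#'   Z-scoring parameters (defaults to the training block).
#' @param horizon Prediction horizon in years used when building training
#'   targets.
#' @param seed Seed for the stochastic learners.
#' @return Object of class `baseline_risk_estimator` / `risk_estimator`.
#' @export
baseline_risk_estimator <- function(model = c("lr", "rf", "gtb"),
                                    train_histories,
                                    zscore_histories = NULL,
                                    horizon = 0.5, seed = 1L) {
  model <- match.arg(model)
  design <- baseline_training_design(train_histories, horizon)
  zs <- NULL
  if (model == "lr") {
    zX <- if (is.null(zscore_histories)) design$X else
      baseline_training_design(zscore_histories, horizon)$X
    zs <- zscore_fit(zX)
  }
  learner <- fit_baseline_learner(model, design$X, design$y, seed = seed,
                                  zs = zs)
  structure(list(model = model, learner = learner, zscore = zs,
                 design = design, horizon = horizon, seed = seed),
            class = c("baseline_risk_estimator", "risk_estimator"))
}

#' @export
print.baseline_risk_estimator <- function(x, ...) {
  cat(sprintf("<baseline_risk_estimator> %s, %d training targets\n",
              toupper(x$model), nrow(x$design$X)))
  invisible(x)
}

#' Warm-start refitting with additional data
#'
#' Refits a baseline estimator after new labelled rows become available,
#' initializing from the current parameter estimates where the learner
#' supports it: logistic regression restarts its optimizer from the current
#' coefficient vector, gradient boosting continues from the existing
#' ensemble. The random forest has no incremental form, so it is refit from
#' scratch on the pooled data and a notice is emitted.
#'
#' @param estimator A [baseline_risk_estimator()].
#' @param new_X Matrix of additional feature rows (same columns as the
#'   training design); may have zero rows.
#' @param new_y Integer states for the new rows.
#' @return The refitted estimator (unchanged when no rows are added).
#' @export
warm_start_refit <- function(estimator, new_X, new_y) {
  stopifnot(inherits(estimator, "baseline_risk_estimator"))
  new_X <- as.matrix(new_X)
  if (nrow(new_X) == 0) return(estimator)
  if (ncol(new_X) != ncol(estimator$design$X))
    stop("new rows do not match the training feature schema")
  stopifnot(nrow(new_X) == length(new_y), all(new_y %in% STATES))
  X <- rbind(estimator$design$X, new_X)
  y <- c(estimator$design$y, as.integer(new_y))
  prev <- if (estimator$model %in% c("lr", "gtb")) estimator$learner else NULL
  if (estimator$model == "rf")
    message("random forest has no warm start; refitting from scratch on pooled data")
  estimator$learner <- fit_baseline_learner(estimator$model, X, y,
                                            seed = estimator$seed,
                                            prev = prev, zs = estimator$zscore)
  estimator$design <- list(X = X, y = y)
  estimator
}

#' @export
init_state.baseline_risk_estimator <- function(estimator, ...) {
  list(records = NULL, last_time = -Inf)
}

#' @export
observe.baseline_risk_estimator <- function(estimator, state, record, ...) {
  check_record(record)
  if (record$age <= state$last_time)
    stop("out-of-order record in baseline estimator state")
  keep <- c("subject_id", "age", "exam_type", "state")
  keep <- intersect(keep, names(record))
  state$records <- rbind(state$records, record[, keep, drop = FALSE])
  state$last_time <- record$age
  state
}

#' @export
predict_risk.baseline_risk_estimator <- function(estimator, state, t_hat, ...) {
  if (is.null(state$records)) stop("no records observed yet")
  if (t_hat <= state$last_time)
    stop("target time must be after the last observed record")
  x <- build_features(state$records, cut_time = state$last_time, t_hat = t_hat)
  p <- predict_baseline_probs(estimator$model, estimator$learner, x,
                              zs = estimator$zscore)
  p <- pmax(p, 1e-12)
  risk_triple(p, target_time = t_hat)
}
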