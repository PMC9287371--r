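#' Age intervals for the adaptive classifier
#'
#' Ordered, non-overlapping, gap-free intervals over the prediction age
#' range. The defaults reflect how HPV infection risk peaks in early
#' adulthood while cancer risk peaks in middle age: 20--35, 36--45 and 46+.
#'
#' @param breaks Left endpoints of the intervals; the last interval is
#'   unbounded above.
#' @return Object of class `age_intervals`.
#' @export
age_intervals <- function(breaks = c(20, 36, 46)) {
  stopifnot(length(breaks) >= 1, !is.unsorted(breaks, strictly = TRUE))
  structure(list(breaks = breaks, n = length(breaks)), class = "age_intervals")
}

#' @rdname age_intervals
#' @param age Age(s) in years.
#' @param intervals An `age_intervals` object.
#' @return `interval_index`: 1-based interval index; ages below the first
#'   break are an error.
#' @export
interval_index <- function(age, intervals) {
  stopifnot(inherits(intervals, "age_intervals"))
  if (any(age < intervals$breaks[1]))
    stop("age below the covered range (starts at ", intervals$breaks[1], ")")
  findInterval(age, intervals$breaks)
}

#' @export
print.age_intervals <- function(x, ...) {
  labs <- c(paste0("[", x$breaks[-x$n], ", ", x$breaks[-1], ")"),
            paste0("[", x$breaks[x$n], ", Inf)"))
  cat("<age_intervals>", paste(labs, collapse = " "), "\n")
  invisible(x)
}

#' Default classification strategy: most probable state
#'
#' Argmax over the risk triple; exact ties are broken toward the more
#' severe state, consistent with tolerating false positives over false
#' negatives in a screening application.
#'
#' @param risk A [risk_triple()] or numeric vector of length 3.
#' @return Predicted state in 1..3.
#' @export
classify_default <- function(risk) {
  p <- as.numeric(risk)
  stopifnot(length(p) == 3)
  max(which(p >= max(p) - 1e-12))
}

#' Adaptive classification strategy: age-stratified probability thresholds
#'
#' Priority-ordered thresholding adapted to class imbalance and age drift:
#' within the age interval containing `age`, predict high-grade when its
#' probability reaches that interval's high-grade threshold; otherwise
#' predict low-grade when its probability reaches the low-grade threshold;
#' otherwise predict normal. Normal is the fallback, so only the low- and
#' high-grade thresholds are free parameters.
#'
#' @param risk A [risk_triple()] or numeric vector of length 3.
#' @param age Age at the prediction target, years.
#' @param thresholds A [threshold_set()].
#' @param intervals The [age_intervals()] the thresholds are indexed by.
#' @return Predicted state in 1..3.
#' @export
classify_adaptive <- function(risk, age, thresholds, intervals = age_intervals()) {
  p <- as.numeric(risk)
  stopifnot(length(p) == 3, inherits(thresholds, "threshold_set"))
  k <- interval_index(age, intervals)
  if (p[3] >= thresholds$delta3[k]) return(3L)
  if (p[2] >= thresholds$delta2[k]) return(2L)
  1L
}

#' @rdname classify_adaptive
#' @param delta2,delta3 Per-interval thresholds in (0, 1) for the low-grade
#'   and high-grade states.
#' @param r_k Optional achieved training scores (diagnostics).
#' @export
threshold_set <- function(delta2, delta3, r_k = NULL) {
  stopifnot(length(delta2) == length(delta3),
            all(delta2 > 0 & delta2 < 1), all(delta3 > 0 & delta3 < 1))
  structure(list(delta2 = delta2, delta3 = delta3, r_k = r_k),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  for (k in seq_along(x$delta2))
    cat(sprintf("interval %d: delta_low = %.3f, delta_high = %.3f%s\n",
                k, x$delta2[k], x$delta3[k],
                if (!is.null(x$r_k)) sprintf("  (train R_K %.3f)", x$r_k[k])
                else ""))
  invisible(x)
}

# vectorized adaptive rule over a risk matrix, one interval's thresholds
classify_adaptive_matrix <- function(P, d2, d3) {
  out <- rep(1L, nrow(P))
  out[P[, 2] >= d2] <- 2L
  out[P[, 3] >= d3] <- 3L
  out
}

#' Multiclass Matthews correlation coefficient
#'
#' The K-category correlation summarizing a confusion matrix in a single
#' score in \[-1, 1\]: with `n` samples, `n_plus` correct predictions, and
#' per-class truth counts `n_s` and prediction counts `nhat_s`,
#' \deqn{R_K = \frac{n_+ n - \sum_s \hat n_s n_s}
#'   {\sqrt{(n^2 - \sum_s \hat n_s^2)(n^2 - \sum_s n_s^2)}}.}
#' A degenerate denominator (all truths or all predictions in one class)
#' yields 0 by convention.
#'
#' @param truth,pred Integer state vectors of equal length.
#' @return Scalar score in \[-1, 1\].
#' @export
mcc_multiclass <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  stopifnot(length(truth) >= 1)
  n <- length(truth)
  n_plus <- sum(truth == pred)
  n_s <- tabulate(truth, nbins = 3)
  nhat_s <- tabulate(pred, nbins = 3)
  num <- n_plus * n - sum(nhat_s * n_s)
  den <- sqrt(n^2 - sum(nhat_s^2)) * sqrt(n^2 - sum(n_s^2))
  if (den == 0) return(0)
  num / den
}

# Classic rand/1/bin differential evolution (maximization), bounded and
# seeded; small enough problems that exhaustive restarts are unnecessary.
de_optimize <- function(fn, lower, upper, n_pop = 30L, max_gen = 200L,
                        f_weight = 0.8, cr = 0.9, tol = 1e-10, seed = 1L) {
  d <- length(lower)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  pop <- matrix(stats::runif(n_pop * d, lower, upper), n_pop, d, byrow = TRUE)
  fit <- apply(pop, 1, fn)
  for (g in seq_len(max_gen)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3)
      v <- pop[idx[1], ] + f_weight * (pop[idx[2], ] - pop[idx[3], ])
      v <- pmin(pmax(v, lower), upper)
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      fu <- fn(u)
      if (fu >= fit[i]) { pop[i, ] <- u; fit[i] <- fu }
    }
    if (max(fit) - min(fit) < tol) break
  }
  best <- which.max(fit)
  list(par = pop[best, ], value = fit[best], generations = g)
}

#' Fit adaptive classification thresholds by maximizing the multiclass MCC
#'
#' For each age interval, searches the low- and high-grade probability
#' thresholds in (0, 1) that maximize [mcc_multiclass()] of the adaptive
#' rule on the supplied predictions, using a seeded differential evolution
#' run. Intervals with fewer than two distinct true states cannot be
#' scored and fall back to thresholds of 0.5 with a warning.
#'
#' @param risks Matrix (n x 3) of predicted risk triples.
#' @param truths Integer vector of observed states.
#' @param ages Ages at the prediction targets.
#' @param intervals An [age_intervals()].
#' @param n_pop,max_gen,seed Differential evolution settings.
#' @param n_boot When positive, the fitting objective is the mean score
#'   over this many bootstrap resamples of the interval's samples instead
#'   of the single-sample score. Per-interval MCC rests on a handful of
#'   minority predictions, so the plain optimum can sit on a sampling
#'   fluke; averaging over resamples selects thresholds that transfer.
#'   The reported per-interval `r_k` is always the plain score of the
#'   chosen thresholds.
#' @return A [threshold_set()] with the achieved per-interval scores.
#' @export
fit_thresholds <- function(risks, truths, ages, intervals = age_intervals(),
                           n_pop = 30L, max_gen = 200L, seed = 1L,
                           n_boot = 0L) {
  risks <- as.matrix(risks)
  stopifnot(ncol(risks) == 3, nrow(risks) == length(truths),
            length(truths) == length(ages))
  K <- intervals$n
  d2 <- d3 <- rep(0.5, K)
  rk <- rep(NA_real_, K)
  # samples below the covered range carry no interval to fit
  ki <- rep(NA_integer_, length(ages))
  inside <- ages >= intervals$breaks[1]
  ki[inside] <- interval_index(ages[inside], intervals)
  for (k in seq_len(K)) {
    sel <- !is.na(ki) & ki == k
    if (sum(sel) < 1 || length(unique(truths[sel])) < 2) {
      warning("age interval ", k,
              " lacks two distinct true states; using default thresholds 0.5")
      next
    }
    P <- risks[sel, , drop = FALSE]
    y <- truths[sel]
    plain_obj <- function(delta) {
      mcc_multiclass(y, classify_adaptive_matrix(P, delta[1], delta[2]))
    }
    obj <- plain_obj
    if (n_boot > 0) {
      old_seed <- get0(".Random.seed", envir = globalenv())
      set.seed(seed + 1000L * k)
      boot_idx <- replicate(n_boot, sample.int(length(y), replace = TRUE))
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
      obj <- function(delta) {
        lab <- classify_adaptive_matrix(P, delta[1], delta[2])
        mean(vapply(seq_len(n_boot), function(b)
          mcc_multiclass(y[boot_idx[, b]], lab[boot_idx[, b]]),
          numeric(1)))
      }
    }
    res <- de_optimize(obj, lower = c(0.001, 0.001), upper = c(0.999, 0.999),
                       n_pop = n_pop, max_gen = max_gen, seed = seed + k)
    delta <- center_thresholds(res$par, P, obj)
    d2[k] <- delta[1]; d3[k] <- delta[2]; rk[k] <- plain_obj(delta)
  }
  threshold_set(d2, d3, r_k = rk)
}

# The MCC objective is piecewise constant in the thresholds, changing only
# at the sample probabilities; an optimizer may return a knife-edge point
# of the optimal plateau. Re-center each threshold at the midpoint of its
# plateau (holding the other fixed), keeping the training score identical
# while improving transfer to new data.
center_thresholds <- function(delta, P, obj) {
  base <- obj(delta)
  for (dim in 1:2) {
    bp <- sort(unique(c(0.001, P[, dim + 1], 0.999)))
    lo <- max(bp[bp < delta[dim]], 0.001)
    hi_set <- bp[bp >= delta[dim]]
    hi <- if (length(hi_set)) min(hi_set) else 0.999
    cand <- delta
    cand[dim] <- (lo + hi) / 2
    if (obj(cand) >= base - 1e-12) delta <- cand
  }
  delta
}
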