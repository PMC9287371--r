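toy_hmm <- function(generator = NULL) {
  if (is.null(generator))
    generator <- rbind(c(-0.2, 0.15, 0.05),
                       c(0.3, -0.5, 0.2),
                       c(0.05, 0.15, -0.2))
  hmm_params(
    initial_law = rbind(c(0.5, 0.3, 0.2), c(0.6, 0.25, 0.15),
                        c(0.7, 0.2, 0.1)),
    band_breaks = c(36, 46),
    generator = generator,
    emission = list(
      cytology = rbind(c(0.9, 0.08, 0.02), c(0.5, 0.4, 0.1),
                       c(0.1, 0.3, 0.6)),
      histology = rbind(c(0.95, 0.04, 0.01), c(0.3, 0.6, 0.1),
                        c(0.05, 0.2, 0.75))
    ),
    exam_intensity = rbind(c(0.3, 0.02), c(0.4, 0.2), c(0.5, 0.5))
  )
}

test_that("alpha initialization multiplies age-band prior and emission", {
  params <- toy_hmm()
  # hand product: prior (0.5, 0.3, 0.2) x cytology column for x = 1
  a <- init_alpha(make_history(25, 1), params)
  expect_equal(alpha_probs(a),
               c(0.5 * 0.9, 0.3 * 0.5, 0.2 * 0.1) /
                 sum(c(0.45, 0.15, 0.02)), tolerance = 1e-12)
  # prior with support only on the first hidden state
  p2 <- params; p2$initial_law[1, ] <- c(1, 0, 0)
  a2 <- init_alpha(make_history(25, 1), p2)
  expect_equal(alpha_probs(a2), c(1, 0, 0))
  # all-zero mass is an error
  p3 <- params
  p3$initial_law[1, ] <- c(0, 1, 0)
  p3$emission$cytology[2, ] <- c(0, 0, 1)
  expect_error(init_alpha(make_history(25, 1), p3), "zero prior mass")
})

test_that("repeated identical observations sharpen alpha under a frozen chain", {
  params <- toy_hmm(generator = matrix(0, 3, 3))
  a <- init_alpha(make_history(25, 1), params)
  conf <- alpha_probs(a)[1]
  for (k in 1:5) {
    a <- forward_update(a, make_history(25 + k, 1), params)
    expect_gt(alpha_probs(a)[1], conf)
    conf <- alpha_probs(a)[1]
  }
  expect_gt(conf, 0.98)
  expect_error(forward_update(a, make_history(25, 1), params),
               "strictly increase")
})

test_that("long-gap transitions approach the stationary law", {
  set.seed(8)
  Q <- random_generator()
  P <- ctmc_transition_prob(Q, 500)
  # stationary law via eigen-decomposition of the transpose
  e <- eigen(t(Q))
  stat <- Re(e$vectors[, which.min(abs(e$values))])
  stat <- stat / sum(stat)
  for (s in 1:3) expect_equal(as.numeric(P[s, ]), stat, tolerance = 1e-8)
})

test_that("Chapman-Kolmogorov holds for the generator exponential", {
  set.seed(14)
  for (i in 1:5) {
    Q <- random_generator()
    d1 <- runif(1, 0.1, 5); d2 <- runif(1, 0.1, 5)
    expect_equal(ctmc_transition_prob(Q, d1) %*% ctmc_transition_prob(Q, d2),
                 ctmc_transition_prob(Q, d1 + d2), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("forward filter equals exhaustive hidden-path enumeration", {
  params <- toy_hmm()
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    h <- random_history(n)
    a <- init_alpha(h[1, ], params)
    for (i in seq_len(n)[-1]) a <- forward_update(a, h[i, ], params)
    # brute force: sum over all 3^n hidden paths
    Ps <- lapply(seq_len(n)[-1], function(i)
      ctmc_transition_prob(params$generators[[1]], h$age[i] - h$age[i - 1]))
    band <- min(findInterval(h$age[1], params$band_breaks) + 1, 3)
    paths <- as.matrix(expand.grid(rep(list(1:3), n)))
    post <- numeric(3)
    for (r in seq_len(nrow(paths))) {
      path <- paths[r, ]
      pr <- params$initial_law[band, path[1]] *
        params$emission[[h$exam_type[1]]][path[1], h$state[1]]
      for (i in seq_len(n)[-1]) {
        pr <- pr * Ps[[i - 1]][path[i - 1], path[i]] *
          params$emission[[h$exam_type[i]]][path[i], h$state[i]]
      }
      post[path[n]] <- post[path[n]] + pr
    }
    expect_equal(alpha_probs(a), post / sum(post), tolerance = 1e-10)
  }
})

test_that("prediction collapses to the emission row for a frozen point mass", {
  params <- toy_hmm(generator = matrix(0, 3, 3))
  # single exam type: zero histology intensity
  params$exam_intensity <- rbind(c(0.3, 0), c(0.4, 0), c(0.5, 0))
  params$p_exam_given_hidden <- params$exam_intensity /
    rowSums(params$exam_intensity)
  a <- structure(list(log_alpha = c(0, -Inf, -Inf), time = 30),
                 class = "alpha_state")
  pred <- predict_state_probs(a, 30.001, params)
  expect_equal(as.numeric(pred), params$emission$cytology[1, ],
               tolerance = 1e-9)
})

test_that("predictions respect the 1<->3 relabeling symmetry", {
  rev3 <- function(M) M[3:1, 3:1]
  sym <- hmm_params(
    initial_law = rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)),
    band_breaks = c(36, 46),
    generator = rbind(c(-0.3, 0.2, 0.1), c(0.25, -0.5, 0.25),
                      c(0.1, 0.2, -0.3)),
    emission = list(
      cytology = rbind(c(0.8, 0.15, 0.05), c(0.2, 0.6, 0.2),
                       c(0.05, 0.15, 0.8)),
      histology = rbind(c(0.9, 0.08, 0.02), c(0.1, 0.8, 0.1),
                        c(0.02, 0.08, 0.9))
    ),
    exam_intensity = rbind(c(0.3, 0.1), c(0.4, 0.2), c(0.3, 0.1))
  )
  mirrored <- sym
  mirrored$initial_law <- sym$initial_law[, 3:1]
  mirrored$generators[[1]] <- rev3(sym$generators[[1]])
  mirrored$emission <- lapply(sym$emission, rev3)
  mirrored$exam_intensity <- sym$exam_intensity[3:1, ]
  mirrored$p_exam_given_hidden <- mirrored$exam_intensity /
    rowSums(mirrored$exam_intensity)
  h <- make_history(c(25, 27), c(1, 2))
  h_m <- make_history(c(25, 27), c(3, 2))
  a <- forward_update(init_alpha(h[1, ], sym), h[2, ], sym)
  am <- forward_update(init_alpha(h_m[1, ], mirrored), h_m[2, ], mirrored)
  expect_equal(as.numeric(predict_state_probs(a, 29, sym)),
               rev(as.numeric(predict_state_probs(am, 29, mirrored))),
               tolerance = 1e-10)
})

test_that("prediction marginalization matches term-by-term brute force", {
  params <- toy_hmm()
  h <- make_history(c(25, 28), c(1, 2), exam_types = c("cytology", "histology"))
  a <- forward_update(init_alpha(h[1, ], params), h[2, ], params)
  t_hat <- 29
  P <- ctmc_transition_prob(params$generators[[1]], t_hat - h$age[2])
  w <- alpha_probs(a)
  oracle <- numeric(3)
  for (s in 1:3) for (rho in c("cytology", "histology"))
    for (hh in 1:3) for (hj in 1:3) {
      rho_i <- match(rho, c("cytology", "histology"))
      oracle[s] <- oracle[s] +
        params$emission[[rho]][hh, s] *
        params$p_exam_given_hidden[hh, rho_i] *
        P[hj, hh] * w[hj]
    }
  oracle <- oracle / sum(oracle)
  expect_equal(as.numeric(predict_state_probs(a, t_hat, params)), oracle,
               tolerance = 1e-12)
  expect_error(predict_state_probs(a, h$age[2], params), "after")
})

test_that("the HMM estimator contract runs a history end to end", {
  est <- hmm_risk_estimator(toy_hmm())
  st <- init_state(est)
  h <- make_history(c(24, 26, 29), c(1, 2, 1))
  for (i in 1:3) st <- observe(est, st, h[i, ])
  pr <- predict_risk(est, st, 31)
  expect_s3_class(pr, "risk_triple")
  expect_equal(sum(pr), 1, tolerance = 1e-9)
})

test_that("HMM parameters round-trip through the keyed config file", {
  params <- toy_hmm()
  path <- tempfile(fileext = ".yaml")
  mat2list <- function(M) lapply(seq_len(nrow(M)), function(i) as.numeric(M[i, ]))
  yaml::write_yaml(list(
    initial_law = mat2list(params$initial_law),
    band_breaks = params$band_breaks,
    generator = mat2list(params$generators[[1]]),
    emission = list(cytology = mat2list(params$emission$cytology),
                    histology = mat2list(params$emission$histology)),
    exam_intensity = mat2list(params$exam_intensity)
  ), path)
  back <- read_hmm_params(path)
  expect_equal(back$initial_law, params$initial_law, ignore_attr = TRUE)
  expect_equal(back$generators[[1]], params$generators[[1]],
               ignore_attr = TRUE)
  expect_equal(back$p_exam_given_hidden, params$p_exam_given_hidden,
               ignore_attr = TRUE)
})
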