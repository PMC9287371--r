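# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

make_history <- function(ages, states,
                         exam_types = rep("cytology", length(ages)),
                         subject_id = "s1") {
  data.frame(subject_id = rep_len(subject_id, length(ages)), age = ages,
             exam_type = exam_types, state = as.integer(states),
             stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  screening_cohort(do.call(rbind, list(...)))
}

# A generator whose disease process never moves and whose exams never err:
# every history repeats its initial state.
frozen_chain_config <- function(n = 5L, seed = 1L) {
  zero_Q <- matrix(0, 3, 3)
  idC <- diag(3)
  cfg <- generator_config(n_histories = n, seed = seed)
  cfg$generators <- list(zero_Q, zero_Q, zero_Q)
  cfg$confusion <- list(cytology = idC, histology = idC)
  cfg
}

# Small random-rate 3-state generator for property tests
random_generator <- function() {
  Q <- matrix(stats::runif(9, 0.05, 0.8), 3, 3)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

random_history <- function(n_records, grid = age_grid()) {
  ages <- sort(stats::runif(n_records, 20, 70))
  while (any(diff(ages) < 1e-3))
    ages <- sort(stats::runif(n_records, 20, 70))
  make_history(ages, sample(1:3, n_records, replace = TRUE),
               sample(c("cytology", "histology"), n_records, replace = TRUE))
}

# Tiny latent profile reference for mixture tests
toy_profiles <- function(M, sigma = 0.8, grid = NULL) {
  if (is.null(grid))
    grid <- age_grid(16, 16 + ncol(M), resolution = 1L)
  structure(list(values = M, grid = grid, sigma = sigma,
                 config = NULL, backend = "toy"),
            class = "latent_profiles")
}
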