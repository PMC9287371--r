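#' Read HMM parameters from a keyed configuration file
#'
#' Loads an [hmm_params()] object from a YAML file with keys
#' `initial_law` (list of rows), `band_breaks`, `generator` (list of rows,
#' or a list of such matrices under `generators` for an age-banded chain),
#' `emission` (`cytology` / `histology`, lists of rows) and
#' `exam_intensity` (list of rows, columns cytology then histology). The
#' schema is validated by the `hmm_params` constructor.
#'
#' @param path Path to a YAML file.
#' @return An [hmm_params()] object.
#' @export
read_hmm_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_mat <- function(x) do.call(rbind, lapply(x, as.numeric))
  generator <- if (!is.null(cfg$generators))
    lapply(cfg$generators, as_mat) else as_mat(cfg$generator)
  hmm_params(
    initial_law = as_mat(cfg$initial_law),
    band_breaks = as.numeric(cfg$band_breaks),
    generator = generator,
    emission = list(cytology = as_mat(cfg$emission$cytology),
                    histology = as_mat(cfg$emission$histology)),
    exam_intensity = as_mat(cfg$exam_intensity)
  )
}

#' Persist and reload fitted classification thresholds
#'
#' Thresholds are stored as a keyed YAML file holding the interval left
#' endpoints and the per-interval low- and high-grade thresholds.
#'
#' @param thresholds A [threshold_set()].
#' @param intervals The matching [age_intervals()].
#' @param path Output path.
#' @export
write_thresholds <- function(thresholds, intervals, path) {
  stopifnot(inherits(thresholds, "threshold_set"),
            inherits(intervals, "age_intervals"))
  yaml::write_yaml(list(breaks = intervals$breaks,
                        delta_low_grade = thresholds$delta2,
                        delta_high_grade = thresholds$delta3), path)
  invisible(path)
}

#' @rdname write_thresholds
#' @return `read_thresholds`: list with `thresholds` and `intervals`.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(thresholds = threshold_set(as.numeric(cfg$delta_low_grade),
                                  as.numeric(cfg$delta_high_grade)),
       intervals = age_intervals(as.numeric(cfg$breaks)))
}

#' Persist and reload fitted latent profiles
#'
#' The profile matrix is written as a plain tab-separated table next to a
#' JSON sidecar carrying the grid, the emission scale and the backend, so
#' a fitted reference can be reloaded without refitting.
#'
#' @param profiles A `latent_profiles` object.
#' @param basename Output path prefix; writes `<basename>.tsv` and
#'   `<basename>.json`.
#' @export
save_latent_profiles <- function(profiles, basename) {
  stopifnot(inherits(profiles, "latent_profiles"))
  utils::write.table(profiles$values, paste0(basename, ".tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(grid = profiles$grid[c("t_min", "t_max", "resolution")],
         sigma = profiles$sigma,
         backend = profiles$backend %||% "swcmf",
         subjects = profiles$subjects),
    paste0(basename, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' @rdname save_latent_profiles
#' @export
load_latent_profiles <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  M <- as.matrix(utils::read.table(paste0(basename, ".tsv"), sep = "\t"))
  dimnames(M) <- NULL
  grid <- age_grid(meta$grid$t_min, meta$grid$t_max, meta$grid$resolution)
  new_latent_profiles(M, grid, meta$sigma, config = NULL,
                      extra = list(backend = meta$backend,
                                   subjects = meta$subjects))
}
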