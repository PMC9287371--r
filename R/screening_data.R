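#' Discrete age grid for state matrices
#'
#' Defines the column layout used when a collection of screening histories is
#' rasterized into a partially observed state matrix: ages from `t_min` to
#' `t_max` split into half-open bins of width `1/resolution` years.
#'
#' @param t_min Youngest age covered, in years (default 16).
#' @param t_max Oldest age covered, in years (default 80).
#' @param resolution Bins per year, integer >= 1 (default 4, i.e. quarterly
#'   bins; the latent risk is assumed to change slowly within a year, so a
#'   sub-annual grid loses little while keeping the matrix narrow).
#' @return An object of class `age_grid` with fields `t_min`, `t_max`,
#'   `resolution` and `n_cols`.
#' @examples
#' g <- age_grid()
#' g$n_cols                      # (80 - 16) * 4 = 256 columns
#' age_to_column(25, g)          # 1-based column of the bin holding age 25
#' @export
age_grid <- function(t_min = 16, t_max = 80, resolution = 4L) {
  stopifnot(is.numeric(t_min), is.numeric(t_max), t_min < t_max)
  resolution <- as.integer(resolution)
  stopifnot(resolution >= 1L)
  n <- (t_max - t_min) * resolution
  if (abs(n - round(n)) > 1e-9)
    stop("(t_max - t_min) * resolution must be an integer number of columns")
  structure(
    list(t_min = t_min, t_max = t_max, resolution = resolution,
         n_cols = as.integer(round(n))),
    class = "age_grid"
  )
}

#' @rdname age_grid
#' @param age Age(s) in decimal years.
#' @param grid An `age_grid`.
#' @return `age_to_column`: 1-based column index of the half-open bin
#'   containing `age`; ages equal to `t_max` fold into the last bin.
#' @export
age_to_column <- function(age, grid) {
  stopifnot(inherits(grid, "age_grid"))
  if (any(age < grid$t_min - 1e-9 | age > grid$t_max + 1e-9))
    stop("age outside grid span [", grid$t_min, ", ", grid$t_max, "]")
  col <- floor((age - grid$t_min) * grid$resolution) + 1L
  pmin.int(as.integer(col), grid$n_cols)
}

#' @rdname age_grid
#' @param column 1-based column index.
#' @return `column_midpoint_age`: the age at the centre of a bin.
#' @export
column_midpoint_age <- function(column, grid) {
  grid$t_min + (column - 0.5) / grid$resolution
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf("<age_grid> [%g, %g] years, %d bins/year, %d columns\n",
              x$t_min, x$t_max, x$resolution, x$n_cols))
  invisible(x)
}

EXAM_TYPES <- c("cytology", "histology")
STATES <- 1:3
STATE_LABELS <- c("normal", "low-grade", "high-grade")

validate_records <- function(df, context = "records") {
  required <- c("subject_id", "age", "exam_type", "state")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", context, ": ", paste(missing, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$age <- as.numeric(df$age)
  df$exam_type <- as.character(df$exam_type)
  df$state <- as.integer(df$state)
  bad_state <- which(!(df$state %in% STATES))
  if (length(bad_state))
    stop("invalid state (must be 1, 2 or 3) at row(s): ",
         paste(utils::head(bad_state, 5L), collapse = ", "))
  bad_type <- which(!(df$exam_type %in% EXAM_TYPES))
  if (length(bad_type))
    stop("invalid exam_type (must be 'cytology' or 'histology') at row(s): ",
         paste(utils::head(bad_type, 5L), collapse = ", "))
  bad_age <- which(!is.finite(df$age) | df$age < 16 | df$age > 100)
  if (length(bad_age))
    stop("age outside [16, 100] at row(s): ",
         paste(utils::head(bad_age, 5L), collapse = ", "))
  df
}

#' Construct a screening cohort
#'
#' A cohort holds one row per exam: subject identifier, age at exam in decimal
#' years, exam modality (`"cytology"` or `"histology"`) and the observed state
#' coded 1 = normal, 2 = low-grade, 3 = high-grade. Records are validated and
#' sorted by subject and age; tied ages within a subject are an error.
#'
#' @param records A data frame with columns `subject_id`, `age`, `exam_type`,
#'   `state` (extra columns are preserved).
#' @param metadata Optional named list echoed through (provenance, generator
#'   configuration, ...).
#' @return An object of class `screening_cohort` with elements `data`
#'   (validated, sorted data frame) and `metadata`.
#' @export
screening_cohort <- function(records, metadata = list()) {
  df <- validate_records(as.data.frame(records, stringsAsFactors = FALSE))
  df <- df[order(df$subject_id, df$age), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df)) {
    dup <- stats::ave(df$age, df$subject_id,
                      FUN = function(a) c(0, diff(a)) == 0 & seq_along(a) > 1)
    if (any(dup == 1)) {
      subj <- unique(df$subject_id[dup == 1])
      stop("duplicate exam times within subject(s): ",
           paste(utils::head(subj, 5L), collapse = ", "))
    }
  }
  structure(list(data = df, metadata = metadata), class = "screening_cohort")
}

#' @export
print.screening_cohort <- function(x, ...) {
  n_subj <- length(unique(x$data$subject_id))
  cat(sprintf("<screening_cohort> %d histories, %d exam records\n",
              n_subj, nrow(x$data)))
  if (nrow(x$data)) {
    tab <- prop.table(table(factor(x$data$state, levels = STATES)))
    cat(sprintf("  state mix: %.3f normal / %.3f low-grade / %.3f high-grade\n",
                tab[1], tab[2], tab[3]))
    cat(sprintf("  ages %.1f-%.1f\n", min(x$data$age), max(x$data$age)))
  }
  invisible(x)
}

#' @rdname screening_cohort
#' @param x A `screening_cohort`.
#' @return `cohort_histories`: a named list of per-subject data frames, each
#'   sorted by age.
#' @export
cohort_histories <- function(x) {
  stopifnot(inherits(x, "screening_cohort"))
  split(x$data, x$data$subject_id)
}

#' Read and write screening histories as CSV
#'
#' The on-disk dialect is comma-separated UTF-8 with a header row and columns
#' `subject_id,age,exam_type,state`; ages use dot decimals and exam types are
#' lowercase strings. Rows violating the record invariants abort the read with
#' a message naming the offending rows.
#'
#' @param path Path to a CSV file.
#' @return `read_histories`: a validated [screening_cohort()].
#' @export
read_histories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  screening_cohort(df, metadata = list(source = path))
}

#' @rdname read_histories
#' @param cohort A `screening_cohort`.
#' @param columns Columns to write; defaults to the dialect's four columns.
#' @export
write_histories <- function(cohort, path,
                            columns = c("subject_id", "age", "exam_type", "state")) {
  stopifnot(inherits(cohort, "screening_cohort"))
  utils::write.csv(cohort$data[, columns, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Most severe state in a history
#'
#' The maximum observed state over a subject's records; used as the sampling
#' weight when training histories are drawn with probability proportional to
#' the most severe result.
#'
#' @param history Data frame of one subject's records (column `state`).
#' @return Integer in 1..3.
#' @export
most_severe_state <- function(history) {
  if (is.null(history$state) || !length(history$state))
    stop("empty history: no states to summarize")
  max(as.integer(history$state))
}

#' Rasterize a cohort into a partially observed state matrix
#'
#' Each subject becomes a row; each record fills the grid column containing
#' its age. When two records of one subject collide in a bin the more severe
#' state is kept (false positives are preferred over false negatives in this
#' application). Unobserved cells are `NA`.
#'
#' @param cohort A [screening_cohort()].
#' @param grid An [age_grid()]; all record ages must fall inside its span.
#' @return An object of class `state_matrix`: list with `values` (N x T
#'   integer matrix, `NA` = unobserved), `grid`, and `subjects` (row order).
#' @export
to_state_matrix <- function(cohort, grid = age_grid()) {
  stopifnot(inherits(cohort, "screening_cohort"), inherits(grid, "age_grid"))
  df <- cohort$data
  out_of_span <- df$age < grid$t_min - 1e-9 | df$age > grid$t_max + 1e-9
  if (any(out_of_span))
    stop("record age outside grid span for subject(s): ",
         paste(utils::head(unique(df$subject_id[out_of_span]), 5L), collapse = ", "))
  subjects <- unique(df$subject_id)
  values <- matrix(NA_integer_, nrow = length(subjects), ncol = grid$n_cols,
                   dimnames = list(subjects, NULL))
  row_idx <- match(df$subject_id, subjects)
  col_idx <- age_to_column(df$age, grid)
  # severity rule on collisions: process in increasing state order so the
  # most severe write wins
  ord <- order(df$state)
  values[cbind(row_idx[ord], col_idx[ord])] <- df$state[ord]
  structure(list(values = values, grid = grid, subjects = subjects),
            class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("<state_matrix> %d x %d, %d observed cells (%.2f%% fill)\n",
              nrow(x$values), ncol(x$values), sum(!is.na(x$values)),
              100 * mean(!is.na(x$values))))
  invisible(x)
}
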