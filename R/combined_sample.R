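#' Construct a combined trial + survey sample
#'
#' Builds the central data container used by all estimation routines: a
#' data frame holding the union of randomized-trial records (`S = 1`) and
#' survey records from the external target population (`S = 0`), together
#' with the known randomization probability stored as metadata.
#'
#' Required columns are `S` (trial indicator) and the covariates; `A`
#' (treatment), `U` (observed time) and `delta` (event indicator) must be
#' present and non-missing exactly for trial rows. `w_survey` holds the
#' design weight (inverse inclusion probability) for survey rows and is
#' fixed at 1 for trial rows; when absent, every weight defaults to 1,
#' the fully observed population case.
#'
#' @param data data frame with columns `id`, `S`, `D`, `A`, `U`, `delta`,
#'   `w_survey` and covariate columns. Only `S` and the covariates are
#'   mandatory; `id` defaults to the row number, `D` to 1 and `w_survey`
#'   to 1.
#' @param pi known randomization probability P(A = 1 | S = 1), in (0, 1).
#' @param covariates character vector naming covariate columns. Defaults
#'   to every column not among the reserved names.
#' @return object of class `combined_sample` (a validated data frame with
#'   attributes `pi` and `covariates`).
#' @examples
#' df <- data.frame(S = c(1, 1, 0, 0), A = c(0, 1, NA, NA),
#'                  U = c(1, 2, NA, NA), delta = c(1, 0, NA, NA),
#'                  X1 = rnorm(4))
#' smp <- combined_sample(df)
#' summarize_sample(smp)
#' @export
combined_sample <- function(data, pi = 0.5, covariates = NULL) {
  stopifnot(is.data.frame(data))
  reserved <- c("id", "S", "D", "A", "U", "delta", "w_survey")
  if (!"S" %in% names(data)) stop("missing mandatory column: S", call. = FALSE)
  if (is.null(covariates)) covariates <- setdiff(names(data), reserved)
  if (length(covariates) == 0L) {
    stop("no covariate columns found", call. = FALSE)
  }
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))
  if (!"D" %in% names(data)) data$D <- 1
  if (!"w_survey" %in% names(data)) data$w_survey <- 1
  for (col in c("A", "U", "delta")) {
    if (!col %in% names(data)) {
      if (any(data$S == 1)) {
        stop("missing mandatory column for trial rows: ", col, call. = FALSE)
      }
      data[[col]] <- NA_real_
    }
  }
  data <- data[c(reserved, covariates)]
  for (col in c("S", "D", "A", "U", "delta", "w_survey", covariates)) {
    data[[col]] <- as.numeric(data[[col]])
  }
  out <- structure(data, pi = pi, covariates = covariates,
                   class = c("combined_sample", "data.frame"))
  validate_sample(out)
  out
}

#' Validate a combined sample against its structural invariants
#'
#' Checks that trial rows carry complete `(A, U, delta)` with `U > 0`,
#' survey fields are absent on trial rows' counterpart, weights are
#' positive (and exactly 1 on trial rows), each arm has at least one trial
#' record and the survey part is non-empty.
#'
#' @param x a `combined_sample`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_sample <- function(x) {
  pi <- attr(x, "pi")
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1) {
    stop("pi must be a single number in (0, 1)", call. = FALSE)
  }
  if (!all(x$S %in% c(0, 1))) stop("S must be 0/1", call. = FALSE)
  if (!all(x$D %in% c(0, 1))) stop("D must be 0/1", call. = FALSE)
  if (any(x$S == 1 & x$D != 1)) {
    stop("all trial records must have D = 1", call. = FALSE)
  }
  trial <- x$S == 1
  bad <- trial & (is.na(x$A) | is.na(x$U) | is.na(x$delta))
  if (any(bad)) {
    stop("trial row(s) with missing A/U/delta: id ",
         paste(utils::head(x$id[bad], 5L), collapse = ", "), call. = FALSE)
  }
  if (any(trial & x$U <= 0)) {
    stop("nonpositive observed time U: id ",
         paste(utils::head(x$id[trial & x$U <= 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (!all(x$A[trial] %in% c(0, 1)) || !all(x$delta[trial] %in% c(0, 1))) {
    stop("A and delta must be 0/1 on trial rows", call. = FALSE)
  }
  if (any(!trial & (!is.na(x$A) | !is.na(x$U) | !is.na(x$delta)))) {
    stop("A/U/delta must be missing on survey rows", call. = FALSE)
  }
  if (any(is.na(x$w_survey)) || any(x$w_survey <= 0)) {
    stop("w_survey must be positive", call. = FALSE)
  }
  if (any(trial & x$w_survey != 1)) {
    stop("w_survey must equal 1 on trial rows", call. = FALSE)
  }
  if (sum(trial & x$A == 1) < 1L || sum(trial & x$A == 0) < 1L) {
    stop("need at least one trial record in each arm", call. = FALSE)
  }
  if (sum(!trial) < 1L) stop("need at least one survey record", call. = FALSE)
  covs <- attr(x, "covariates")
  if (any(vapply(x[covs], function(v) any(!is.finite(v)), logical(1)))) {
    stop("covariates must be finite", call. = FALSE)
  }
  invisible(x)
}

#' Read a combined sample from a delimited text file
#'
#' Reads a comma- or tab-delimited table with a header row, optionally
#' renaming columns through a schema map, and validates the result. A
#' missing `w_survey` column defaults every weight to 1 (covariates fully
#' observed across the target population, m = N).
#'
#' @param path file path.
#' @param schema optional named character vector mapping canonical names
#'   (`S`, `A`, `U`, `delta`, ...) to column names in the file, e.g.
#'   `c(S = "in_trial", U = "time")`.
#' @param pi known randomization probability.
#' @param covariates optional covariate column selection (canonical names).
#' @param sep field delimiter; auto-detected from the header when `NULL`.
#' @return a `combined_sample`.
#' @export
read_sample <- function(path, schema = NULL, pi = 0.5, covariates = NULL,
                        sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(unname(schema), names(df))
    if (length(miss) > 0L) {
      stop("schema column(s) not present in file: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (canon in names(schema)) {
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  if (!"S" %in% names(df)) stop("missing mandatory column: S", call. = FALSE)
  for (col in c("A", "U", "delta")) {
    if (!col %in% names(df) && any(df$S == 1)) {
      stop("missing mandatory column: ", col, call. = FALSE)
    }
  }
  combined_sample(df, pi = pi, covariates = covariates)
}

#' Write a combined sample to a delimited text file
#'
#' Canonical column order (`id, S, D, A, U, delta, w_survey, X...`) so that
#' `write_sample(read_sample(f))` round-trips the table.
#'
#' @param sample a `combined_sample`.
#' @param path output path.
#' @param sep delimiter, comma by default.
#' @export
write_sample <- function(sample, path, sep = ",") {
  utils::write.table(as.data.frame(sample), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a combined sample
#'
#' @param sample a `combined_sample`.
#' @return list with trial size `n`, survey size `m`, per-arm counts,
#'   trial censoring fraction and the survey weight total (an estimate of
#'   the target population size N).
#' @export
summarize_sample <- function(sample) {
  trial <- sample$S == 1
  n <- sum(trial)
  out <- list(
    n = n,
    m = sum(!trial),
    n_treated = sum(trial & sample$A == 1),
    n_control = sum(trial & sample$A == 0),
    censoring_fraction = sum(trial & sample$delta == 0) / n,
    weight_total = sum(sample$w_survey[!trial]),
    pi = attr(sample, "pi"),
    covariates = attr(sample, "covariates")
  )
  class(out) <- "sample_summary"
  out
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("Combined trial + survey sample\n")
  cat(sprintf("  trial n = %d (A=1: %d, A=0: %d), survey m = %d\n",
              x$n, x$n_treated, x$n_control, x$m))
  cat(sprintf("  trial censoring fraction = %.3f\n", x$censoring_fraction))
  cat(sprintf("  survey weight total (estimated N) = %.1f\n", x$weight_total))
  cat(sprintf("  randomization probability pi = %.3f\n", x$pi))
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.combined_sample <- function(x, ...) {
  print(summarize_sample(x))
  invisible(x)
}

# Split into trial/survey parts with metadata pulled off before subsetting
# (data-frame subsetting drops custom attributes).
.split_sample <- function(sample) {
  covs <- attr(sample, "covariates")
  pi <- attr(sample, "pi")
  df <- as.data.frame(sample)
  trial <- df[df$S == 1, , drop = FALSE]
  survey <- df[df$S == 0, , drop = FALSE]
  list(trial = trial, survey = survey, pi = pi, covs = covs)
}

#' Read a key-value configuration file
#'
#' Plain-text `key = value` lines (`#` comments allowed). Comma-separated
#' values become vectors; numeric-looking values are converted.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}
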