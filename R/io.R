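#' Read and write triad response files
#'
#' Responses are stored as delimited text with header columns `standard`,
#' `test1`, `test2`, `response` and optionally `participant`; `response` is
#' 1 when test1 was chosen as the more different test, 0 otherwise.
#' Malformed rows are rejected with their file line numbers (header = line
#' 1). The write/read pair is a lossless round trip.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return `read_responses`: a `data.frame` of class `mot_responses`.
#' @export
read_responses <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("standard", "test1", "test2", "response")
  optional <- "participant"
  unknown <- setdiff(names(df), c(required, optional))
  if (length(unknown) > 0L) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  line_of <- function(i) i + 1L # header occupies line 1
  for (v in c("standard", "test1", "test2")) {
    vals <- suppressWarnings(as.numeric(df[[v]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s at line %d of %s", v, line_of(bad[1L]),
                   path))
    }
    df[[v]] <- vals
  }
  resp <- suppressWarnings(as.numeric(df$response))
  bad <- which(is.na(resp) | !resp %in% c(0, 1))
  if (length(bad) > 0L) {
    stop(sprintf("response must be 0 or 1; offending value at line %d of %s",
                 line_of(bad[1L]), path))
  }
  df$response <- as.integer(resp)
  if (is.null(df$participant)) df$participant <- 1L
  class(df) <- c("mot_responses", "data.frame")
  df
}

#' @rdname read_responses
#' @param responses a response data frame to write.
#' @export
write_responses <- function(responses, path, sep = ",") {
  cols <- c("standard", "test1", "test2", "response", "participant")
  if (is.null(responses$participant)) responses$participant <- 1L
  utils::write.table(responses[, cols], path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write triad design files
#'
#' Designs are delimited text with columns `standard`, `test1`, `test2`
#' (one triad per row); derived difference columns are recomputed on read.
#'
#' @param path file path.
#' @param sep field separator.
#' @return `read_design`: a `triad_design` data frame.
#' @export
read_design <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep)
  required <- c("standard", "test1", "test2")
  if (!all(required %in% names(df))) {
    stop("design file must have columns standard, test1, test2")
  }
  bad <- which(!(df$test1 <= df$standard & df$standard <= df$test2))
  if (length(bad) > 0L) {
    stop(sprintf("triad violates test1 <= standard <= test2 at line %d of %s",
                 bad[1L] + 1L, path))
  }
  df <- df[, required]
  df$d1 <- df$standard - df$test1
  df$d2 <- df$test2 - df$standard
  df$delta_d <- df$d1 - df$d2
  df$dbar <- (df$d1 + df$d2) / 2
  class(df) <- c("triad_design", "data.frame")
  df
}

#' @rdname read_design
#' @param design a design data frame to write.
#' @export
write_design <- function(design, path, sep = ",") {
  utils::write.table(design[, c("standard", "test1", "test2")], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a difference-scaling fit as structured JSON
#'
#' @param fit a `diff_scaling_fit`.
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "diff_scaling_fit"))
  jsonlite::write_json(list(
    kind = fit$kind, k = fit$k,
    fixed = as.list(fit$fixed),
    knot_x = fit$f$knot_x, knot_y = fit$f$knot_y,
    sigma = fit$sigma, max = fit$max,
    nll = fit$nll, avg_nll = fit$avg_nll,
    n_records = fit$n_records, converged = fit$converged,
    boundary = fit$boundary, restarts = fit$restarts, seed = fit$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a validation-run configuration file
#'
#' Flat YAML with keys such as `study`, `n_per_triad`, `sigma_dd`,
#' `f_true`, `g_map`, `models`, `repetitions`, `seed`.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  yaml::read_yaml(path)
}
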