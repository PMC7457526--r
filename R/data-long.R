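#' Validate and order long-format multichannel data
#'
#' Takes a long-format data frame with one row per (subject, condition,
#' channel) observation and returns a validated dataset with rows sorted
#' condition-major within subject: for each subject all channels of the first
#' condition, then all channels of the second, and so on. This ordering matches
#' the vectorization assumed by every correlation structure in the package and
#' is fixed project-wide. Subjects and factor levels keep their
#' first-appearance order, which also determines the reference level of the
#' condition and channel dummies.
#'
#' Incomplete grids are rejected: each subject must have exactly one row for
#' every (condition, channel) combination. Missing values in the response or
#' covariates are an error.
#'
#' @param data A data frame in long format.
#' @param subject,condition,channel,response Column names (strings) for the
#'   subject identifier, condition label, channel label and numeric response.
#' @param covariates Character vector of covariate column names; default: all
#'   remaining columns, which must be numeric.
#' @return An object of class `erp_data`: a list with the sorted `data` tibble,
#'   the column mapping, covariate names, and the dimensions `n` (subjects),
#'   `J` (conditions), `K` (channels).
#' @examples
#' df <- expand.grid(subject = 1:2, condition = c("std", "odd"),
#'                   channel = c("c1", "c2"))
#' df$response <- rnorm(nrow(df))
#' as_erp_data(df)
#' @export
as_erp_data <- function(data, subject = "subject", condition = "condition",
                        channel = "channel", response = "response",
                        covariates = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  core <- c(subject = subject, condition = condition, channel = channel,
            response = response)
  missing_cols <- setdiff(unname(core), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Column(s) not found in `data`: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (!is.numeric(data[[response]])) {
    abort(sprintf("Response column `%s` must be numeric.", response))
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), unname(core))
  } else {
    missing_cov <- setdiff(covariates, names(data))
    if (length(missing_cov) > 0) {
      abort(sprintf("Covariate column(s) not found: %s.",
                    paste(missing_cov, collapse = ", ")))
    }
  }
  for (cv in covariates) {
    if (!is.numeric(data[[cv]])) {
      abort(sprintf("Covariate column `%s` must be numeric.", cv))
    }
  }
  used <- c(unname(core), covariates)
  nas <- vapply(data[used], function(x) any(is.na(x)), TRUE)
  if (any(nas)) {
    abort(sprintf("Missing values in column(s): %s.",
                  paste(used[nas], collapse = ", ")))
  }

  subj_levels <- unique(as.character(data[[subject]]))
  cond_levels <- unique(as.character(data[[condition]]))
  chan_levels <- unique(as.character(data[[channel]]))
  J <- length(cond_levels)
  K <- length(chan_levels)

  # complete-grid check, naming the offending subject
  tab <- table(data[[subject]], data[[condition]], data[[channel]])
  bad <- rownames(tab)[apply(tab != 1L, 1, any)]
  if (length(bad) > 0) {
    abort(sprintf(
      "Subject \"%s\" does not have exactly one row per (condition, channel) cell; only complete %d x %d grids are supported.",
      bad[1], J, K
    ))
  }

  ord <- order(
    match(as.character(data[[subject]]), subj_levels),
    match(as.character(data[[condition]]), cond_levels),
    match(as.character(data[[channel]]), chan_levels)
  )
  out <- list(
    data = data[ord, , drop = FALSE],
    subject = subject, condition = condition, channel = channel,
    response = response, covariates = covariates,
    subject_levels = subj_levels, condition_levels = cond_levels,
    channel_levels = chan_levels,
    n = length(subj_levels), J = J, K = K
  )
  class(out) <- "erp_data"
  out
}

#' Read long-format multichannel data from a delimited file
#'
#' Reads a CSV or TSV file (delimiter chosen by extension: `.tsv`/`.txt` are
#' tab-delimited, anything else comma-delimited) and validates it with
#' [as_erp_data()].
#'
#' @param path File path.
#' @inheritParams as_erp_data
#' @return An `erp_data` object.
#' @export
read_erp_long <- function(path, subject = "subject", condition = "condition",
                          channel = "channel", response = "response",
                          covariates = NULL) {
  reader <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  data <- reader(path, show_col_types = FALSE, progress = FALSE)
  as_erp_data(data, subject = subject, condition = condition,
              channel = channel, response = response, covariates = covariates)
}

#' Write an `erp_data` object back to a delimited file
#'
#' Values are written at full precision so that a read/write round trip
#' preserves finite decimal inputs exactly.
#'
#' @param x An `erp_data` object.
#' @param path Output path; `.tsv`/`.txt` write tab-delimited, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_erp_long <- function(x, path) {
  stopifnot(inherits(x, "erp_data"))
  writer <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::write_tsv
  } else {
    readr::write_csv
  }
  writer(x$data, path)
  invisible(path)
}

#' @export
print.erp_data <- function(x, ...) {
  cat("<erp_data>", x$n, "subjects x", x$J, "conditions x", x$K,
      "channels;", length(x$covariates), "covariates\n")
  print(head(x$data, 6))
  invisible(x)
}

#' @export
as_tibble.erp_data <- function(x, ...) x$data
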