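#' Assemble the model design matrix and penalty groups
#'
#' Builds the stacked design matrix for the marginal model
#' `g(mu_ijk) = X_i' beta + condition_j + channel_k` with reference-cell dummy
#' coding for the condition and channel factors (reference level = first
#' appearance in the data). Columns are ordered: intercept (optional),
#' condition dummies (J - 1), channel dummies (K - 1), covariates.
#'
#' The channel dummies are registered as a single penalty group, so a
#' multi-level channel factor is kept or dropped as a whole; the intercept and
#' the condition dummies are unpenalized by default (the model adjusts for
#' condition rather than selecting it; override by passing the returned groups
#' through [group_structure()] yourself). Covariates listed in
#' `covariate_groups` form the given penalized groups; remaining covariates
#' become singleton groups unless named in `unpenalized_covariates`.
#'
#' @param x An [as_erp_data()] object.
#' @param include_intercept Include an intercept column (default `TRUE`).
#' @param condition_term,channel_term Include the factor dummies (default
#'   `TRUE`); requires at least 2 levels of the corresponding factor.
#' @param covariate_groups Optional named list mapping group labels to
#'   character vectors of covariate names.
#' @param unpenalized_covariates Covariate names exempt from the penalty.
#' @return A list of class `gpgee_design` with the design matrix `x` (rows in
#'   the dataset's subject/condition-major order), the [group_structure()]
#'   `groups`, the response vector `y`, term names, and dimensions `n`, `J`,
#'   `K`.
#' @export
build_design <- function(x, include_intercept = TRUE, condition_term = TRUE,
                         channel_term = TRUE, covariate_groups = NULL,
                         unpenalized_covariates = NULL) {
  stopifnot(inherits(x, "erp_data"))
  if (condition_term && x$J < 2) {
    abort("A condition term requires at least 2 condition levels.")
  }
  if (channel_term && x$K < 2) {
    abort("A channel term requires at least 2 channel levels.")
  }
  d <- x$data
  cols <- list()
  terms <- character(0)
  if (include_intercept) {
    cols <- c(cols, list(rep(1, nrow(d))))
    terms <- c(terms, "(Intercept)")
  }
  cond_idx <- integer(0)
  if (condition_term) {
    for (lv in x$condition_levels[-1]) {
      cols <- c(cols, list(as.numeric(d[[x$condition]] == lv)))
      terms <- c(terms, paste0("condition_", lv))
    }
    cond_idx <- seq.int(length(terms) - (x$J - 2), length(terms))
  }
  chan_idx <- integer(0)
  if (channel_term) {
    for (lv in x$channel_levels[-1]) {
      cols <- c(cols, list(as.numeric(d[[x$channel]] == lv)))
      terms <- c(terms, paste0("channel_", lv))
    }
    chan_idx <- seq.int(length(terms) - (x$K - 2), length(terms))
  }
  cov_idx <- integer(0)
  if (length(x$covariates) > 0) {
    cols <- c(cols, lapply(x$covariates, function(cv) d[[cv]]))
    cov_idx <- seq.int(length(terms) + 1L, length(terms) + length(x$covariates))
    terms <- c(terms, x$covariates)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  p <- ncol(X)

  unpen <- c(if (include_intercept) 1L else integer(0), cond_idx)
  groups <- list()
  if (length(chan_idx) > 0) groups$channel <- chan_idx
  grouped_covs <- character(0)
  if (!is.null(covariate_groups)) {
    bad <- setdiff(unlist(covariate_groups), x$covariates)
    if (length(bad) > 0) {
      abort(sprintf("Unknown covariate(s) in `covariate_groups`: %s.",
                    paste(bad, collapse = ", ")))
    }
    for (gname in names(covariate_groups)) {
      groups[[gname]] <- match(covariate_groups[[gname]], terms)
    }
    grouped_covs <- unlist(covariate_groups)
  }
  if (!is.null(unpenalized_covariates)) {
    bad <- setdiff(unpenalized_covariates, x$covariates)
    if (length(bad) > 0) {
      abort(sprintf("Unknown covariate(s) in `unpenalized_covariates`: %s.",
                    paste(bad, collapse = ", ")))
    }
    unpen <- c(unpen, match(unpenalized_covariates, terms))
  }
  singles <- setdiff(x$covariates, c(grouped_covs, unpenalized_covariates))
  for (cv in singles) groups[[cv]] <- match(cv, terms)

  gs <- group_structure(groups, unpenalized = unpen, p = p)
  structure(
    list(x = X, y = d[[x$response]], groups = gs, terms = terms,
         n = x$n, J = x$J, K = x$K,
         condition_cols = cond_idx, channel_cols = chan_idx,
         covariate_cols = cov_idx),
    class = "gpgee_design"
  )
}
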