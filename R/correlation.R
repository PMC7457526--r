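#' First-order autoregressive correlation matrix
#'
#' Builds the AR1 correlation matrix with entry `rho^|s - t|`. Used both as a
#' working correlation for a whole within-subject vector and as the channel
#' factor of a Kronecker (separable) structure, where it encodes correlation
#' that decays with distance between recording sites.
#'
#' @param dim Matrix dimension (positive integer).
#' @param rho Autocorrelation coefficient, strictly inside (-1, 1).
#' @return A `dim` x `dim` correlation matrix.
#' @examples
#' cor_ar1(3, 0.5)
#' @export
cor_ar1 <- function(dim, rho) {
  check_dim(dim)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      abs(rho) >= 1) {
    abort("`rho` must satisfy |rho| < 1 for an AR1 correlation.")
  }
  idx <- seq_len(dim)
  rho ^ abs(outer(idx, idx, "-"))
}

#' Compound-symmetry (exchangeable) correlation matrix
#'
#' All off-diagonal entries equal `rho`. Positive definiteness requires
#' `rho > -1/(dim - 1)`.
#'
#' @inheritParams cor_ar1
#' @param rho Common correlation, inside (-1/(dim-1), 1).
#' @return A `dim` x `dim` correlation matrix.
#' @examples
#' cor_cs(3, 0.5)
#' @export
cor_cs <- function(dim, rho) {
  check_dim(dim)
  lo <- if (dim > 1) -1 / (dim - 1) else -1
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho <= lo || rho >= 1) {
    abort(sprintf(
      "`rho` must lie in (%.4f, 1) for a positive-definite CS correlation.",
      lo
    ))
  }
  R <- matrix(rho, dim, dim)
  diag(R) <- 1
  R
}

#' Kronecker (separable) correlation matrix
#'
#' Combines a condition-level correlation `B` (J x J) and a channel-level
#' correlation `Sigma` (K x K) into the JK x JK within-subject correlation
#' `B %x% Sigma`, matching the condition-major vectorization of the responses:
#' entry ((j,k), (j',k')) equals `B[j, j'] * Sigma[k, k']`.
#'
#' @param B Condition-factor correlation matrix (unit diagonal, symmetric,
#'   positive definite).
#' @param Sigma Channel-factor correlation matrix (same requirements).
#' @return The Kronecker-product correlation matrix.
#' @examples
#' cor_kronecker(diag(2), cor_ar1(3, 0.9))
#' @export
cor_kronecker <- function(B, Sigma) {
  check_correlation_matrix(B, "B")
  check_correlation_matrix(Sigma, "Sigma")
  kronecker(B, Sigma)
}

check_dim <- function(dim) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1 || dim != round(dim)) {
    abort("`dim` must be a positive integer.")
  }
  invisible(dim)
}

check_correlation_matrix <- function(R, name) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (max(abs(diag(R) - 1)) > 1e-8) {
    abort(sprintf("`%s` must have unit diagonal.", name))
  }
  if (max(abs(R - t(R))) > 1e-8) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  invisible(R)
}

# --- working-correlation specification ---------------------------------------

cor_kind_codes <- c(
  independence = 0L, ar1 = 1L, cs = 2L, unstructured = 3L, kronecker = 4L
)
cor_bcodes <- c(independence = 0L, unstructured = 1L)
cor_scodes <- c(ar1 = 1L, cs = 2L, unstructured = 3L)

#' Parse a working-correlation specification string
#'
#' Grammar: `"independence"`, `"ar1"`, `"cs"`, `"unstructured"`, or
#' `"kron:<B-spec>,<Sigma-spec>"` where the condition factor `<B-spec>` is
#' `unstructured` or `independence` and the channel factor `<Sigma-spec>` is
#' `ar1`, `cs`, or `unstructured`. For example `"kron:unstructured,ar1"` is the
#' separable structure with an unstructured condition correlation and AR1
#' channel correlation.
#'
#' @param corstr Specification string.
#' @return A list with elements `kind`, and for the Kronecker kind
#'   `condition_spec` and `channel_spec`, plus the integer codes used by the
#'   solver.
#' @examples
#' parse_corstr("kron:unstructured,ar1")
#' @export
parse_corstr <- function(corstr) {
  if (!is.character(corstr) || length(corstr) != 1L || is.na(corstr)) {
    abort("`corstr` must be a single string.")
  }
  grammar <- paste(
    "valid forms: \"independence\", \"ar1\", \"cs\", \"unstructured\",",
    "\"kron:<B-spec>,<Sigma-spec>\" with <B-spec> in {unstructured,",
    "independence} and <Sigma-spec> in {ar1, cs, unstructured}"
  )
  if (startsWith(corstr, "kron:")) {
    parts <- strsplit(sub("^kron:", "", corstr), ",", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    if (length(parts) != 2L || !parts[1] %in% names(cor_bcodes) ||
        !parts[2] %in% names(cor_scodes)) {
      abort(sprintf("Invalid correlation spec \"%s\"; %s.", corstr, grammar))
    }
    structure(
      list(
        kind = "kronecker", condition_spec = parts[1], channel_spec = parts[2],
        kind_code = cor_kind_codes[["kronecker"]],
        bcode = cor_bcodes[[parts[1]]], scode = cor_scodes[[parts[2]]]
      ),
      class = "corstr_spec"
    )
  } else {
    if (!corstr %in% setdiff(names(cor_kind_codes), "kronecker")) {
      abort(sprintf("Invalid correlation spec \"%s\"; %s.", corstr, grammar))
    }
    structure(
      list(
        kind = corstr, condition_spec = NULL, channel_spec = NULL,
        kind_code = cor_kind_codes[[corstr]], bcode = 0L, scode = 0L
      ),
      class = "corstr_spec"
    )
  }
}

#' Estimate a working correlation from Pearson residuals
#'
#' Method-of-moments estimation on a matrix of per-subject residual vectors.
#' Rows must be ordered condition-major (channel index fastest), columns are
#' subjects. Denominators are pooled globally (the overall mean squared
#' residual), so the residual scale cancels and each estimated factor has unit
#' diagonal. AR1/CS coefficients are clipped to their positive-definite ranges
#' (`[-0.99, 0.99]` for AR1); an estimated unstructured matrix that is not
#' positive definite has its eigenvalues floored at 1e-6 and is rescaled back
#' to unit diagonal.
#'
#' @param residuals Numeric matrix, `J*K` rows by `n` subjects (or a list of
#'   per-subject residual vectors of length `J*K`).
#' @param corstr Correlation specification string (see [parse_corstr()]).
#' @param J,K Number of conditions and channels; required for the Kronecker
#'   kind, otherwise `J = 1`, `K = m` is assumed.
#' @return An object of class `working_correlation`: a list with the realized
#'   matrix `R`, the specification, and for the Kronecker kind the factors `B`
#'   and `Sigma`; scalar structures also carry the estimated `rho`.
#' @examples
#' set.seed(1)
#' e <- matrix(rnorm(20 * 50), 20, 50)
#' estimate_working_correlation(e, "ar1")
#' @export
estimate_working_correlation <- function(residuals, corstr, J = NULL,
                                         K = NULL) {
  if (is.list(residuals)) residuals <- do.call(cbind, residuals)
  if (!is.matrix(residuals) || !is.numeric(residuals)) {
    abort("`residuals` must be a numeric matrix (rows = J*K, cols = subjects).")
  }
  if (ncol(residuals) < 2L) {
    abort("Correlation estimation needs at least 2 subjects.")
  }
  spec <- if (inherits(corstr, "corstr_spec")) corstr else parse_corstr(corstr)
  m <- nrow(residuals)
  if (spec$kind == "kronecker") {
    if (is.null(J) || is.null(K)) {
      abort("`J` and `K` are required for the kronecker correlation kind.")
    }
    if (J * K != m) abort("`J * K` must equal the number of residual rows.")
  } else {
    J <- 1L
    K <- m
  }
  est <- estimate_R_cpp(residuals, as.integer(J), as.integer(K),
                        spec$kind_code, spec$bcode, spec$scode)
  R <- est$R
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort("Estimated working correlation is not positive definite.")
  }
  out <- list(
    spec = spec, R = R, dim = m, J = J, K = K,
    B = if (spec$kind == "kronecker") est$B else NULL,
    Sigma = if (spec$kind == "kronecker") est$Sigma else NULL,
    rho = switch(spec$kind, ar1 = , cs = R[1, 2], NULL)
  )
  class(out) <- "working_correlation"
  out
}

#' @export
print.working_correlation <- function(x, ...) {
  cat("<working_correlation> kind:", x$spec$kind, "\n")
  if (x$spec$kind == "kronecker") {
    cat("  condition factor:", x$spec$condition_spec,
        " channel factor:", x$spec$channel_spec, "\n")
  }
  if (!is.null(x$rho)) cat("  rho:", format(x$rho, digits = 4), "\n")
  cat("  dimension:", x$dim, "x", x$dim, "\n")
  invisible(x)
}
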