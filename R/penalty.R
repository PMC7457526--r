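#' Derivative of the SCAD penalty
#'
#' Evaluates the continuous derivative of the smoothly clipped absolute
#' deviation penalty: `lambda` on `[0, lambda]`, the linear decay
#' `(a*lambda - theta)_+ / (a - 1)` on `(lambda, a*lambda)`, and 0 beyond
#' `a*lambda`. With `a = 3.7` (the usual choice) large signals escape
#' shrinkage, which is what makes SCAD nearly unbiased for strong effects.
#'
#' @param theta Nonnegative argument(s); for group selection this is the L1
#'   norm of a coefficient group.
#' @param lambda Nonnegative penalty level.
#' @param a SCAD shape parameter, must exceed 2 (default 3.7).
#' @return Numeric vector of the same length as `theta`.
#' @examples
#' scad_derivative(c(0.5, 2, 5), lambda = 1)
#' @export
scad_derivative <- function(theta, lambda, a = 3.7) {
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta < 0)) {
    abort("`theta` must be nonnegative and finite.")
  }
  check_penalty(lambda, a)
  if (lambda == 0) return(rep(0, length(theta)))
  ifelse(theta <= lambda, lambda, pmax(a * lambda - theta, 0) / (a - 1))
}

check_penalty <- function(lambda, a) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0) {
    abort("`lambda` must be a single nonnegative number.")
  }
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 2) {
    abort("`a` must be a single number greater than 2.")
  }
  invisible(NULL)
}

#' Group penalty vector
#'
#' For each penalty group the SCAD derivative is evaluated at the group's L1
#' norm and broadcast to every coefficient in the group, so covariates enter or
#' leave the model together; unpenalized coefficients receive 0.
#'
#' @param beta Coefficient vector.
#' @param groups A [group_structure()] covering `length(beta)` coefficients.
#' @param lambda,a SCAD penalty parameters (see [scad_derivative()]).
#' @return Nonnegative vector, same length as `beta`, constant within groups.
#' @examples
#' gs <- group_structure(list(1:2))
#' group_penalty_vector(c(0.5, 0.5), gs, lambda = 2)
#' @export
group_penalty_vector <- function(beta, groups, lambda, a = 3.7) {
  gid <- group_ids(groups, length(beta))
  check_penalty(lambda, a)
  q <- numeric(length(beta))
  for (g in seq_along(groups$groups)) {
    idx <- groups$groups[[g]]
    q[idx] <- scad_derivative(sum(abs(beta[idx])), lambda, a)
  }
  q
}

#' Minorization-maximization penalty matrix
#'
#' The diagonal matrix `E_n` of the MM surrogate for the nonsmooth group-SCAD
#' penalty: entry `j` is `q_j / (epsilon + |beta_j|)` where `q_j` is the group
#' penalty vector entry, and 0 for unpenalized coefficients. A small `epsilon`
#' keeps the surrogate smooth at zero; entries can therefore be as large as
#' `lambda / epsilon` for coefficients at exactly zero.
#'
#' @inheritParams group_penalty_vector
#' @param epsilon Positive smoothing constant (default 1e-6).
#' @return A diagonal matrix of dimension `length(beta)`.
#' @examples
#' gs <- group_structure(list(1:2))
#' mm_penalty_matrix(c(0.5, 0.5), gs, lambda = 2)
#' @export
mm_penalty_matrix <- function(beta, groups, lambda, a = 3.7, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    abort("`epsilon` must be a single positive number.")
  }
  q <- group_penalty_vector(beta, groups, lambda, a)
  diag(q / (epsilon + abs(beta)), nrow = length(beta))
}
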