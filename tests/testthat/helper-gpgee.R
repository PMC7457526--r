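# Shared fixtures and independent reference implementations used as oracles.

# small long-format dataset with a complete (condition x channel) grid
make_erp_tibble <- function(n = 2, J = 2, K = 3, p = 0, seed = 1,
                            shuffle = FALSE) {
  withr::with_seed(seed, {
    df <- expand.grid(
      channel = paste0("ch", seq_len(K)),
      condition = paste0("cond", seq_len(J)),
      subject = paste0("s", seq_len(n)),
      stringsAsFactors = FALSE
    )[, c("subject", "condition", "channel")]
    df$response <- round(rnorm(nrow(df)), 3)
    if (p > 0) {
      for (j in seq_len(p)) df[[paste0("x", j)]] <- round(rnorm(nrow(df)), 3)
    }
    if (shuffle) df <- df[sample(nrow(df)), ]
    tibble::as_tibble(df)
  })
}

# stacked random regression fixture with clustered rows
make_xy_fixture <- function(n = 10, J = 2, K = 3, p = 4, seed = 1,
                            beta = NULL, rho = 0) {
  withr::with_seed(seed, {
    m <- J * K
    x <- matrix(rnorm(n * m * p), n * m, p)
    if (is.null(beta)) beta <- rnorm(p)
    eps <- if (rho == 0) {
      rnorm(n * m)
    } else {
      U <- chol(cor_ar1(m, rho))
      as.vector(t(matrix(rnorm(n * m), n, m) %*% U))
    }
    list(x = x, y = drop(x %*% beta) + eps, beta = beta, n = n, J = J, K = K)
  })
}

# independent per-coefficient SCAD PGEE: direct MM Newton-Raphson loop written
# against the update formulas, without any group machinery
ref_pgee <- function(x, y, n, J, K, corstr, lambda, a = 3.7, eps = 1e-6,
                     tol = 1e-5, max_iter = 200) {
  beta <- qr.solve(x, y)
  m <- J * K
  p <- ncol(x)
  spec <- parse_corstr(corstr)
  for (k in seq_len(max_iter)) {
    resid <- y - drop(x %*% beta)
    R <- if (spec$kind == "independence") diag(m) else
      estimate_working_correlation(matrix(resid, m), corstr, J = J, K = K)$R
    W <- solve(R)
    E <- matrix(resid, m)
    S <- drop(crossprod(x, as.vector(W %*% E)))
    H <- matrix(0, p, p)
    for (i in seq_len(n)) {
      Xi <- x[((i - 1) * m + 1):(i * m), , drop = FALSE]
      H <- H + t(Xi) %*% W %*% Xi
    }
    q <- scad_derivative(abs(beta), lambda, a)
    En <- q / (eps + abs(beta))
    bn <- beta + solve(H + diag(n * En + 1e-8, p), S - n * En * beta)
    delta <- sum(abs(bn - beta))
    beta <- bn
    if (delta < tol) break
  }
  beta
}

# plain-R moment estimators mirroring the documented formulas
ref_ar1_rho <- function(E, L) {
  m <- nrow(E)
  nseg <- m / L
  num <- c()
  for (i in seq_len(ncol(E))) {
    for (s in seq_len(nseg)) {
      seg <- E[((s - 1) * L + 1):(s * L), i]
      num <- c(num, seg[-L] * seg[-1])
    }
  }
  max(min(mean(num) / mean(E^2), 0.99), -0.99)
}

ref_cs_rho <- function(E, L) {
  m <- nrow(E)
  nseg <- m / L
  num <- c()
  for (i in seq_len(ncol(E))) {
    for (s in seq_len(nseg)) {
      seg <- E[((s - 1) * L + 1):(s * L), i]
      op <- tcrossprod(seg)
      num <- c(num, op[upper.tri(op)])
    }
  }
  lo <- if (L > 1) -1 / (L - 1) + 1e-6 else 0
  max(min(mean(num) / mean(E^2), 0.99), lo)
}

ref_unstructured <- function(E) {
  S <- tcrossprod(E) / ncol(E)
  d <- sqrt(diag(S))
  R <- S / outer(d, d)
  diag(R) <- 1
  R
}

# residuals from a separable B (x) Sigma Gaussian error model, m x n
simulate_kron_residuals <- function(n, B, Sigma, seed = 1) {
  withr::with_seed(seed, {
    V <- kronecker(B, Sigma)
    t(matrix(rnorm(n * nrow(V)), n, nrow(V)) %*% chol(V))
  })
}

table1_groups <- function() {
  group_structure(split(1:40, rep(1:8, each = 5)))
}
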