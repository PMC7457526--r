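test_that("GEE score matches normal equations and explicit-inverse oracle", {
  fx <- make_xy_fixture(n = 8, J = 2, K = 2, p = 3, seed = 21)
  ols <- qr.solve(fx$x, fx$y)
  # independence working correlation: score vanishes at the OLS solution
  expect_lt(max(abs(gee_score(ols, fx$x, fx$y, fx$n, diag(4)))), 1e-10)
  # R = I, beta = 0, y = X 1: S = X'X 1
  y1 <- drop(fx$x %*% rep(1, 3))
  expect_equal(gee_score(rep(0, 3), fx$x, y1, fx$n, diag(4)),
               drop(crossprod(fx$x) %*% rep(1, 3)))
  # 2-subject toy with AR1(0.5): explicit 2x2 inverse as the oracle
  x <- matrix(1, 4, 1)
  y <- c(1, 2, 0, 1)
  R <- cor_ar1(2, 0.5)
  Rinv <- matrix(c(1, -0.5, -0.5, 1), 2) / 0.75
  oracle <- sum(Rinv %*% c(1, 2)) + sum(Rinv %*% c(0, 1))
  expect_equal(gee_score(0, x, y, 2, R), oracle, tolerance = 1e-12)
})

test_that("GEE hessian is the stacked quadratic form, PSD, equal to naive loop", {
  fx <- make_xy_fixture(n = 6, J = 2, K = 2, p = 3, seed = 22)
  H_I <- gee_hessian(rep(0, 3), fx$x, fx$y, fx$n, diag(4))
  expect_equal(H_I, crossprod(fx$x))
  R <- cor_ar1(4, 0.6)
  H <- gee_hessian(rep(0, 3), fx$x, fx$y, fx$n, R)
  expect_equal(H, t(H))
  expect_gt(min(eigen(H, only.values = TRUE)$values), -1e-10)
  # naive triple-product loop oracle
  W <- solve(R)
  Hn <- matrix(0, 3, 3)
  for (i in 1:fx$n) {
    Xi <- fx$x[((i - 1) * 4 + 1):(i * 4), ]
    for (s in 1:4) for (t in 1:4) {
      Hn <- Hn + W[s, t] * outer(Xi[s, ], Xi[t, ])
    }
  }
  expect_equal(H, Hn)
  expect_error(gee_score(rep(0, 3), fx$x, fx$y, fx$n, matrix(1, 4, 4)),
               "singular|positive")
})

test_that("Newton-MM step reduces to Fisher scoring and preserves stationarity", {
  fx <- make_xy_fixture(n = 5, J = 1, K = 3, p = 2, seed = 23)
  ols <- qr.solve(fx$x, fx$y)
  b0 <- c(0.3, -0.2)
  S <- gee_score(b0, fx$x, fx$y, fx$n, diag(3))
  H <- gee_hessian(b0, fx$x, fx$y, fx$n, diag(3))
  # E_n = 0: one step lands on least squares for the Gaussian identity model
  expect_equal(newton_mm_step(b0, H, diag(0, 2), S, fx$n, ridge = 0), ols)
  # beta = 0, S = 0 stays at 0
  expect_equal(newton_mm_step(rep(0, 2), H, diag(c(1, 1)), rep(0, 2), fx$n),
               rep(0, 2))
  # scalar instance verified against hand arithmetic:
  # H = 4, En = 2, S = 1, n = 3, beta = 0.5 ->
  # 0.5 + (1 - 3*2*0.5) / (4 + 3*2) = 0.3
  expect_equal(newton_mm_step(0.5, matrix(4), matrix(2), 1, 3, ridge = 0),
               0.3)
})

test_that("lambda = 0 with independence correlation equals least squares", {
  for (seed in 1:5) {
    fx <- make_xy_fixture(n = 12, J = 2, K = 3, p = 5, seed = seed)
    gs <- group_structure(list(1:2, 3:5))
    fit <- gpgee_fit_xy(fx$x, fx$y, fx$n, fx$J, fx$K, gs,
                        corstr = "independence", lambda = 0)
    expect_lt(max(abs(fit$beta - qr.solve(fx$x, fx$y))), 1e-8)
  }
})

test_that("full-shrinkage lambda drops every penalized group", {
  fx <- make_xy_fixture(n = 15, J = 2, K = 3, p = 4, seed = 31,
                        beta = c(1, 0.5, -0.5, 0.2))
  x <- cbind(1, fx$x)  # unpenalized intercept
  gs <- group_structure(list(2:3, 4:5), unpenalized = 1L)
  fit <- gpgee_fit_xy(x, fx$y, fx$n, fx$J, fx$K, gs,
                      corstr = "independence", lambda = 1e6)
  expect_equal(unname(fit$beta[2:5]), rep(0, 4))
  expect_length(fit$selected_groups, 0)
  # unpenalized coefficient equals the fit on unpenalized columns alone
  expect_lt(abs(fit$beta[1] - mean(fx$y)), 1e-6)
})

test_that("all-singleton solver reproduces a direct per-coefficient SCAD PGEE", {
  for (seed in c(41, 42)) {
    fx <- make_xy_fixture(n = 20, J = 2, K = 3, p = 6, seed = seed,
                          beta = c(2, 1, 0, 0, 0.5, 0), rho = 0.6)
    gs <- singleton_groups(6)
    for (lambda in c(0.05, 0.3)) {
      fit <- gpgee_fit_xy(fx$x, fx$y, fx$n, fx$J, fx$K, gs, corstr = "ar1",
                          lambda = lambda, zero_threshold = 0)
      ref <- ref_pgee(fx$x, fx$y, fx$n, fx$J, fx$K, "ar1", lambda)
      expect_lt(max(abs(fit$beta - ref)), 1e-8)
    }
  }
})

test_that("compiled path iterates match the R-level step composition", {
  fx <- make_xy_fixture(n = 10, J = 2, K = 3, p = 4, seed = 51, rho = 0.5)
  gs <- group_structure(list(1:2, 3:4))
  spec <- parse_corstr("kron:unstructured,ar1")
  lambda <- 0.2
  beta <- qr.solve(fx$x, fx$y)
  m <- 6
  for (k in 1:3) {
    path <- gpgee:::gpgee_path_cpp(
      fx$x, fx$y, fx$n, 2L, 3L, gs$gid, 2L, spec$kind_code, spec$bcode,
      spec$scode, lambda, 3.7, 1e-6, 0, k, qr.solve(fx$x, fx$y), 0, FALSE
    )
    # same k iterations assembled from the exported R operations
    beta_r <- qr.solve(fx$x, fx$y)
    for (j in 1:k) {
      resid <- fx$y - drop(fx$x %*% beta_r)
      R <- estimate_working_correlation(matrix(resid, m), spec,
                                        J = 2, K = 3)$R
      S <- gee_score(beta_r, fx$x, fx$y, fx$n, R)
      H <- gee_hessian(beta_r, fx$x, fx$y, fx$n, R)
      En <- mm_penalty_matrix(beta_r, gs, lambda)
      beta_r <- newton_mm_step(beta_r, H, En, S, fx$n, ridge = 0)
    }
    expect_lt(max(abs(path$beta[, 1] - beta_r)), 1e-9)
  }
})

test_that("retained support shrinks monotonically along an increasing penalty grid", {
  design <- table1_design(n = 40)
  for (seed in c(61, 62)) {
    sim <- simulate_table1_data(design, seed = seed)
    fit <- gpgee_fit_xy(sim$x, sim$y, 40, 2, 10, table1_groups(),
                        corstr = "kron:unstructured,ar1")
    lam <- fit$bic_path$lambda  # descending
    supports <- lapply(seq_along(lam), function(l) {
      b <- fit$beta_path[, l]
      which(vapply(table1_groups()$groups, function(i) any(b[i] != 0), TRUE))
    })
    # the support at a larger lambda is contained in the next (smaller) one
    for (l in seq_len(length(lam) - 1)) {
      expect_true(all(supports[[l]] %in% supports[[l + 1]]))
    }
  }
})

test_that("BIC tuning returns the requested grid and sensible choices", {
  fx <- make_xy_fixture(n = 15, J = 2, K = 3, p = 4, seed = 71,
                        beta = c(1.5, 1, 0, 0))
  gs <- group_structure(list(1:2, 3:4))
  # a one-point grid returns that fit
  fit1 <- gpgee_fit_xy(fx$x, fx$y, fx$n, fx$J, fx$K, gs,
                       corstr = "independence", lambda = 0.4)
  expect_equal(fit1$lambda, 0.4)
  expect_equal(nrow(fit1$bic_path), 1)
  # default grid: 30 descending values, bic finite where fits succeeded
  fit30 <- gpgee_fit_xy(fx$x, fx$y, fx$n, fx$J, fx$K, gs, corstr = "cs")
  expect_equal(nrow(fit30$bic_path), 30)
  expect_true(all(diff(fit30$bic_path$lambda) < 0))
  expect_true(all(is.finite(fit30$bic_path$bic)))
})

test_that("pure-noise designs retain no penalized group in most replicates", {
  n <- 100
  m <- 8
  gs <- group_structure(list(1:5, 6:10))
  none <- 0
  reps <- 100
  for (r in seq_len(reps)) {
    fx <- withr::with_seed(700 + r, {
      x <- matrix(rnorm(n * m * 10), n * m, 10)
      list(x = x, y = rnorm(n * m))
    })
    fit <- gpgee_fit_xy(fx$x, fx$y, n, 2, m / 2, gs, corstr = "independence")
    none <- none + (length(fit$selected_groups) == 0)
  }
  expect_gte(none / reps, 0.90)
})

test_that("BIC path decreases to an interior minimum on a fixed benchmark replicate", {
  sim <- simulate_table1_data(table1_design(n = 50), seed = 301)
  fit <- gpgee_fit_xy(sim$x, sim$y, 50, 2, 10, table1_groups(),
                      corstr = "kron:unstructured,ar1")
  bic <- fit$bic_path$bic
  best <- which.min(bic)
  expect_gt(best, 1)
  expect_lt(best, length(bic))
  # decreasing into the minimum, higher after it
  expect_true(all(diff(bic[1:best]) < 0))
  expect_true(all(bic[(best + 1):length(bic)] > bic[best]))
})

test_that("tidy and glance return well-formed summaries", {
  sim <- simulate_table1_data(table1_design(n = 30), seed = 5)
  fit <- gpgee_fit_xy(sim$x, sim$y, 30, 2, 10, table1_groups(),
                      corstr = "kron:unstructured,ar1")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 40)
  expect_named(td, c("term", "estimate", "group", "penalized", "selected"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_obs, 600)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("data-frame interface reproduces the matrix interface on simulated data", {
  sim <- simulate_table1_data(table1_design(n = 25), seed = 9)
  fit_xy <- gpgee_fit_xy(sim$x, sim$y, 25, 2, 10, table1_groups(),
                         corstr = "kron:unstructured,ar1")
  df <- as_tibble(sim)
  fit_df <- gpgee(df, covariate_groups = table1_covariate_groups(),
                  include_intercept = FALSE, condition_term = FALSE,
                  channel_term = FALSE, corstr = "kron:unstructured,ar1")
  expect_equal(unname(fit_df$beta), unname(fit_xy$beta))
  expect_equal(fit_df$selected_groups, fit_xy$selected_groups)
})
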