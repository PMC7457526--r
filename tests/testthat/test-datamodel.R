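test_that("shuffled long data is re-sorted condition-major within subject", {
  df <- make_erp_tibble(n = 2, J = 2, K = 3, shuffle = TRUE, seed = 4)
  ed <- as_erp_data(df)
  expect_equal(ed$n, 2)
  expect_equal(ed$J, 2)
  expect_equal(ed$K, 3)
  d <- ed$data
  # subject blocks are contiguous, condition-major, channel fastest
  expect_equal(d$subject, rep(ed$subject_levels, each = 6))
  expect_equal(d$condition, rep(rep(ed$condition_levels, each = 3), 2))
  expect_equal(d$channel, rep(ed$channel_levels, 4))
  # values travel with their (subject, condition, channel) key
  key <- paste(df$subject, df$condition, df$channel)
  expect_equal(
    d$response,
    df$response[match(paste(d$subject, d$condition, d$channel), key)]
  )
})

test_that("loader contract errors: missing columns, NA, incomplete grids", {
  df <- make_erp_tibble()
  expect_error(as_erp_data(dplyr::select(df, -response)), "not found")
  df_na <- df
  df_na$response[3] <- NA
  expect_error(as_erp_data(df_na), "Missing values")
  df_chr <- df
  df_chr$response <- as.character(df_chr$response)
  expect_error(as_erp_data(df_chr), "numeric")
  # drop one grid cell of subject s2 -> balance error naming the subject
  df_bad <- df[-which(df$subject == "s2")[5], ]
  expect_error(as_erp_data(df_bad), "s2")
})

test_that("delimited round trip preserves values and ordering exactly", {
  df <- make_erp_tibble(n = 3, J = 2, K = 2, p = 2, seed = 9)
  ed <- as_erp_data(df)
  path <- withr::local_tempfile(fileext = ".csv")
  write_erp_long(ed, path)
  ed2 <- read_erp_long(path)
  expect_identical(as.data.frame(ed$data), as.data.frame(ed2$data))
  expect_identical(ed$condition_levels, ed2$condition_levels)
})

test_that("design matrix layout matches the ERP model, channel dummies one group", {
  # 2 conditions x 13 channels, no covariates: 1 + 1 + 12 columns
  df <- make_erp_tibble(n = 4, J = 2, K = 13, seed = 2)
  des <- build_design(as_erp_data(df))
  expect_equal(ncol(des$x), 14)
  expect_equal(des$terms[1:2], c("(Intercept)", "condition_cond2"))
  # the channel dummy block is a single penalized group of 12
  expect_equal(length(des$groups$groups$channel), 12)
  expect_equal(des$groups$unpenalized, c(1L, 2L))
  # J=2, K=2 gives one dummy each
  des2 <- build_design(as_erp_data(make_erp_tibble(n = 2, J = 2, K = 2)))
  expect_equal(ncol(des2$x), 3)
  # full column rank on a balanced grid
  expect_equal(qr(des$x)$rank, ncol(des$x))
})

test_that("factor terms with a single level are rejected", {
  df <- make_erp_tibble(n = 2, J = 2, K = 1)
  expect_error(build_design(as_erp_data(df)), "channel")
  df2 <- make_erp_tibble(n = 2, J = 1, K = 3)
  expect_error(build_design(as_erp_data(df2)), "condition")
  expect_silent(build_design(as_erp_data(df2), condition_term = FALSE))
})

test_that("covariate grouping and unpenalized covariates are honored", {
  df <- make_erp_tibble(n = 3, J = 2, K = 3, p = 5, seed = 5)
  des <- build_design(as_erp_data(df),
                      covariate_groups = list(blood = c("x1", "x2", "x3")),
                      unpenalized_covariates = "x5")
  gs <- des$groups
  expect_equal(des$terms[gs$groups$blood], c("x1", "x2", "x3"))
  expect_true(match("x5", des$terms) %in% gs$unpenalized)
  # x4 falls through to a singleton group
  expect_equal(des$terms[gs$groups$x4], "x4")
})

test_that("group structure JSON round-trips against term names", {
  terms <- c("(Intercept)", "condition_odd", "x1", "x2", "x3")
  spec <- list(groups = list(list("x1", "x2"), list("x3")),
               unpenalized = list("(Intercept)", "condition_odd"))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(spec, path, auto_unbox = TRUE)
  gs <- read_group_structure(path, terms)
  expect_equal(gs$groups[[1]], c(3L, 4L))
  expect_equal(gs$unpenalized, c(1L, 2L))
  expect_error(read_group_structure(path, terms[-5]), "x3")
})

test_that("prescreening drops the later of a correlated pair and is idempotent", {
  # three effectively uncorrelated columns: all retained
  x <- withr::with_seed(11, matrix(rnorm(600), 200, 3))
  stopifnot(max(abs(cor(x)[upper.tri(diag(3))])) < 0.7)
  res <- prescreen_correlated(x, 0.7)
  expect_equal(res$retained, 1:3)
  expect_equal(nrow(res$dropped), 0)

  # exact duplicate: second copy dropped
  x2 <- cbind(x, x[, 1])
  res2 <- prescreen_correlated(x2, 0.7)
  expect_equal(res2$retained, 1:3)
  expect_equal(res2$dropped$r, 1)

  # (x, x + tiny noise, y): sample correlation computed directly as oracle
  x3 <- withr::with_seed(12, {
    a <- rnorm(100)
    cbind(a = a, b = a + rnorm(100, sd = 0.01), c = rnorm(100))
  })
  r12 <- cor(x3[, 1], x3[, 2])
  expect_gt(r12, 0.99)
  res3 <- prescreen_correlated(x3, 0.7)
  expect_equal(res3$retained, c(1L, 3L))
  expect_equal(res3$dropped$kept, "a")
  expect_equal(res3$dropped$dropped, "b")
  expect_equal(res3$dropped$r, r12)

  # idempotent: re-screening the retained columns drops nothing
  res4 <- prescreen_correlated(x3[, res3$retained], 0.7)
  expect_equal(res4$retained, seq_along(res3$retained))

  expect_error(prescreen_correlated(cbind(x, 0)), "zero variance")
})
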