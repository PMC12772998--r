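test_that("design matrices have the documented block structure", {
  pop <- fixture_pop()
  d_full <- build_design(pop, "journey")
  expect_equal(ncol(d_full$X), 48L + 48L)
  ind <- d_full$X[, 1:48, drop = FALSE]
  expect_true(all(Matrix::rowSums(ind != 0) == 1))
  expect_equal(build_design(pop, "action")$n_val, 16L)
  expect_equal(build_design(pop, "patch")$n_val, 24L)
  expect_equal(build_design(pop, "progression")$n_val, 8L)
  expect_equal(build_design(pop, "none")$n_val, 0L)
  expect_error(build_design(pop, "granular"), "unknown granularity")
  # rows: stay trials x 8 run bins, offset is log duration
  n_stay <- sum(!pop$labels$is_switch)
  expect_equal(nrow(d_full$X), n_stay * 8L)
  expect_equal(d_full$offset[1L],
               log(pop$durations[d_full$stay_idx[1L], 1L]))
})

test_that("unpenalized fits match a brute-force likelihood oracle", {
  # tiny instance: 3 columns, 60 rows
  set.seed(20)
  X <- Matrix::Matrix(matrix(rnorm(180), 60L, 3L), sparse = TRUE)
  off <- rep(log(0.5), 60L)
  beta_true <- c(0.4, -0.3, 0.2)
  y <- rpois(60L, exp(0.8 + as.numeric(X %*% beta_true) + off))
  design <- structure(list(X = X, offset = off, trial_id = rep(1:20, 3L),
                           granularity = "test", n_ind = 3L, n_val = 0L),
                      class = "glm_design")
  fit <- fit_poisson_glm(design, y, lambda = 0)
  # oracle: direct numerical maximization of the Poisson log-likelihood
  Xd <- as.matrix(X)
  nll <- function(par) {
    eta <- par[1L] + Xd %*% par[-1L] + off
    sum(exp(eta)) - sum(y * eta)
  }
  oracle <- optim(rep(0, 4L), nll, method = "BFGS",
                  control = list(maxit = 500L, reltol = 1e-14))
  expect_lt(max(abs(c(fit$intercept, fit$coef) - oracle$par)), 1e-3)
})

test_that("adding value terms never hurts unpenalized training deviance", {
  pop <- fixture_pop()
  d0 <- build_design(pop, "none")
  d1 <- build_design(pop, "progression")
  y <- design_counts(pop, d0, 1L)
  rows <- seq_len(nrow(d0$X))
  f0 <- fit_poisson_glm(d0, y, lambda = 0)
  f1 <- fit_poisson_glm(d1, y, lambda = 0)
  expect_lte(poisson_deviance(y, f1$predict(rows)),
             poisson_deviance(y, f0$predict(rows)) + 1e-6)
})

test_that("an unstructured neuron explains no held-out deviance", {
  pop <- fixture_pop()
  design <- build_design(pop, "none")
  set.seed(21)
  y <- rpois(nrow(design$X), 5 * exp(design$offset))
  f <- fit_poisson_glm_cv(design, y, n_repeats = 5L, seed = 22L)
  expect_lt(abs(median(f$fractions)), 0.02)
  # all-zero neurons are flagged with zero fractions
  f0 <- fit_poisson_glm_cv(design, rep(0L, nrow(design$X)),
                           n_repeats = 5L, seed = 22L)
  expect_true(f0$flagged)
  expect_equal(f0$fractions, rep(0, 5L))
})

test_that("a tuned value-coding neuron beats the reduced model per repeat", {
  pop <- fixture_pop()
  spec <- fixture_spec()
  cls <- vapply(spec$neurons, `[[`, character(1), "class")
  amp <- vapply(spec$neurons, function(nr) max(abs(nr$gain)), numeric(1))
  k <- which(cls == "progression")[which.max(amp[cls == "progression"])]
  d0 <- build_design(pop, "none")
  d1 <- build_design(pop, "progression")
  y <- design_counts(pop, d0, k)
  lam <- choose_lambda(d0, y, seed = 23L)
  f0 <- fit_poisson_glm_cv(d0, y, n_repeats = 20L, seed = 24L, lambda = lam)
  f1 <- fit_poisson_glm_cv(d1, y, n_repeats = 20L, seed = 24L, lambda = lam)
  expect_gte(mean(f1$fractions > f0$fractions), 0.95)
})

test_that("generality categorization recovers known coding classes", {
  pop <- fixture_pop()
  spec <- fixture_spec()
  cls <- vapply(spec$neurons, `[[`, character(1), "class")
  grans <- c("none", "progression", "action", "patch", "journey")
  designs <- stats::setNames(
    lapply(grans, function(g) build_design(pop, g)), grans)
  run_one <- function(k) {
    y <- design_counts(pop, designs$none, k)
    lam <- choose_lambda(designs$none, y, seed = 30L + k)
    fits <- lapply(designs, function(d) {
      fit_poisson_glm_cv(d, y, n_repeats = 10L, seed = 30L + k,
                         lambda = lam)
    })
    names(fits)[1L] <- "reduced"
    categorize_value_generality(fits)
  }
  # a no-gain neuron is assigned "none"
  k_none <- which(cls == "none")[1L]
  expect_equal(run_one(k_none)$category, "none")
  # a strongly journey-specific neuron is assigned "journey"
  amp <- vapply(spec$neurons, function(nr) max(abs(nr$gain)), numeric(1))
  k_j <- which(cls == "journey")[which.max(amp[cls == "journey"])]
  expect_equal(run_one(k_j)$category, "journey")
  # missing a granularity raises
  y <- design_counts(pop, designs$none, k_j)
  f <- fit_poisson_glm_cv(designs$none, y, n_repeats = 5L, seed = 3L,
                          lambda = 0.01)
  expect_error(categorize_value_generality(list(reduced = f)),
               "missing granularity")
})
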