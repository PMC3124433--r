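test_that("the presence gate orders probabilities with the covariate and
           recovers known coefficients", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  fit <- fit_presence_stage(x, c(0, 0, 1, 1))
  p <- predict(fit, x)
  expect_true(all(diff(p) > 0))

  set.seed(41)
  n <- 10000
  X <- cbind(rnorm(n), rnorm(n))
  beta <- c(-0.5, 1.2, -0.8)
  pr <- plogis(cbind(1, X) %*% beta)
  y <- rbinom(n, 1, pr)
  fit2 <- fit_presence_stage(X, y)
  # asymptotic standard errors from the information matrix
  W <- as.numeric(plogis(cbind(1, X) %*% fit2$coefficients))
  info <- crossprod(cbind(1, X) * sqrt(W * (1 - W)))
  se <- sqrt(diag(solve(info)))
  expect_true(all(abs(fit2$coefficients - beta) < 3 * se))

  # constant covariates: the fit reduces to the empirical prevalence
  fit3 <- fit_presence_stage(matrix(0, 100, 1), rep(c(0, 1), c(60, 40)))
  expect_equal(unique(round(predict(fit3, matrix(0, 5, 1)), 10)), 0.4)

  expect_error(fit_presence_stage(x, c(1, 1, 1, 1), cell = "L,n=5"),
               "L,n=5")
})

test_that("the gate threshold balances false positives and negatives", {
  expect_equal(select_gate_threshold(c(0.9, 0.1), c(1, 0)), 0.9)
  expect_equal(select_gate_threshold(c(0.3, 0.7, 0.5), c(1, 1, 1)), 0.3)
  # six-point set with a unique balancing threshold, against brute force
  p <- c(0.05, 0.2, 0.4, 0.6, 0.8, 0.95)
  l <- c(0, 1, 0, 0, 1, 1)
  brute <- function(p, lab) {
    cand <- sort(unique(p))
    im <- vapply(cand, function(t) {
      abs(sum(lab == 0 & p >= t) - sum(lab == 1 & p < t))
    }, numeric(1))
    cand[which.min(im)]
  }
  expect_equal(select_gate_threshold(p, l), brute(p, l))
  set.seed(42)
  for (i in 1:25) {
    pp <- runif(40)
    ll <- rbinom(40, 1, pp)
    expect_equal(select_gate_threshold(pp, ll), brute(pp, ll))
  }
})

test_that("the polynomial stage solves least squares on the fixed basis", {
  set.seed(43)
  X <- cbind(log(sample(5:10, 100, TRUE)), log(runif(100, 50, 2000)),
             log(runif(100, 0.01, 0.2)))
  expo <- saarbg:::poly_basis_exponents()
  expect_identical(nrow(expo), 20L)
  truth <- rnorm(20)
  y <- as.numeric(saarbg:::poly_design(X, expo) %*% truth)
  fit <- fit_polynomial_stage(X, y)
  expect_lt(max(abs(fit$coefficients - truth)), 1e-8)

  # normal equations: residuals orthogonal to every basis column
  y2 <- y + rnorm(100)
  fit2 <- fit_polynomial_stage(X, y2)
  D <- saarbg:::poly_design(X, expo)
  resid <- y2 - as.numeric(D %*% fit2$coefficients)
  expect_lt(max(abs(crossprod(D, resid))), 1e-7)

  expect_error(fit_polynomial_stage(X[1:15, ], y2[1:15]), "more observations")
  Xdup <- X
  Xdup[, 3] <- Xdup[, 2]          # collinear covariates
  expect_error(fit_polynomial_stage(Xdup, y2), "collinear")
})

test_that("two-stage prediction obeys the gate and the back-transform", {
  m <- constant_zi_model("L", 5:7)
  feats <- composition_and_length(
    protein_table(c("a", "b"), c("LLLLLAAAA", "AAAAAAAAA")))
  # gate "all" open and a zero log-prediction give expected count exp(0) = 1
  expect_equal(predict_expected_count(m, feats, 5), c(1, 1))
  expect_error(predict_expected_count(m, feats, 4), "outside")

  # closed gate forces zero
  m$stage1[["5"]] <- list(degenerate = NULL,
                          gate = structure(list(coefficients =
                                                  c(-50, 0, 0),
                                                prevalence = 0.01),
                                           class = "logistic_stage"),
                          threshold = 0.5, prevalence = 0.01)
  expect_equal(predict_expected_count(m, feats, 5), c(0, 0))
  # soft gate multiplies instead
  soft <- predict_expected_count(m, feats, 5, soft = TRUE)
  expect_true(all(soft > 0 & soft < 1e-10))
  # cells that never saw a repeat predict zero
  m$stage1[["6"]] <- list(degenerate = "none")
  expect_equal(predict_expected_count(m, feats, 6), c(0, 0))
})

test_that("pooled predictions track a generative proteome", {
  cfg <- synthetic_config(n_proteins = 1500)
  g <- generate_proteome(cfg, seed = 7)
  tc <- training_config(n_range = 5:8)
  models <- suppressWarnings(train_background(g$proteins, "zirvm", tc,
                                              seed = 7))
  feats <- composition_and_length(g$proteins)
  arr <- saarbg:::count_array(g$proteins, names(models), tc$n_range)
  sc <- saarbg:::score_cells(models, feats, arr, tc)
  ratio <- sc$observed / sc$predicted
  well <- sc$observed >= 100 & sc$predicted > 0
  expect_gt(sum(well), 5)
  expect_true(all(abs(ratio[well] - 1) < 0.15))
})
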