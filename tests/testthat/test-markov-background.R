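test_that("tuple counting drives transition estimates", {
  m0 <- fit_markov("AAC", order = 0)
  expect_equal(m0$context_dist[match("A", AA_STANDARD)], 2 / 3)
  expect_equal(m0$context_dist[match("C", AA_STANDARD)], 1 / 3)
  expect_identical(m0$n_params, 20)
  # ambiguity letters are excluded from the tuple stream
  expect_equal(fit_markov("AAB", order = 0)$context_dist[1], 1)

  # on a two-letter alphabet the counts are fully interpretable
  m0b <- fit_markov("AAB", order = 0, alphabet = c("A", "B"))
  expect_equal(m0b$context_dist, c(2 / 3, 1 / 3))
  m1 <- fit_markov("AAB", order = 1, alphabet = c("A", "B"))
  # tuples: AA and AB -> from context A, next is A or B with probability 1/2
  expect_equal(m1$transitions[1, ], c(0.5, 0.5))
  # context B unseen as a transition source -> smoothed uniform row
  expect_equal(m1$transitions[2, ], c(0.5, 0.5))
  expect_equal(sum(m1$context_dist), 1)

  m3 <- fit_markov(c("ACDEFGHIKL"), order = 3)
  expect_identical(m3$n_params, 160000)
  expect_true(all(abs(rowSums(m3$transitions) - 1) < 1e-12))
  expect_lt(abs(sum(m3$context_dist) - 1), 1e-12)

  expect_error(fit_markov(character(0), order = 0), "empty")
})

test_that("tuples never span protein boundaries", {
  # "AA" + "BB": no AB pair should be counted at order 1
  m <- fit_markov(c("AA", "BB"), order = 1, alphabet = c("A", "B"))
  expect_equal(m$transitions[1, ], c(1, 0))  # A -> A only
  expect_equal(m$transitions[2, ], c(0, 1))  # B -> B only
})

test_that("expected run counts match exhaustive enumeration (orders 0-2)", {
  set.seed(21)
  ab <- c("a", "b")
  # order 0
  for (p in c(0.2, 0.5, 0.8)) {
    m <- markov_model(0, ab, matrix(c(p, 1 - p), 1), c(p, 1 - p))
    for (L in 2:8) for (n in 2:min(L, 4)) {
      expect_equal(expected_saar_count(m, L, "a", n),
                   enumerate_expected_runs(0L, NULL, c(p, 1 - p), L, n),
                   tolerance = 1e-10)
    }
  }
  # orders 1 and 2 with random transition tables
  for (k in 1:2) {
    tr <- matrix(stats::runif(2^k * 2, 0.1, 1), 2^k, 2)
    tr <- tr / rowSums(tr)
    cd <- stats::runif(2^k, 0.1, 1)
    cd <- cd / sum(cd)
    m <- markov_model(k, ab, tr, cd)
    for (L in c(3, 5, 7)) for (n in 2:3) {
      expect_equal(expected_saar_count(m, L, "a", n),
                   enumerate_expected_runs(k, tr, cd, L, n),
                   tolerance = 1e-10)
    }
  }
})

test_that("deterministic and boundary cases of the expectation", {
  ab <- c("a", "b")
  m1 <- markov_model(0, ab, matrix(c(1, 0), 1), c(1, 0))
  expect_equal(expected_saar_count(m1, 5, "a", 5), 1)
  m <- markov_model(0, ab, matrix(c(0.5, 0.5), 1), c(0.5, 0.5))
  expect_equal(expected_saar_count(m, 3, "a", 2), 0.375)
  expect_equal(expected_saar_count(m, 1, "a", 2), 0)   # n > L
})

test_that("order-0 forward recursion equals the closed form", {
  expect_equal(order0_closed_form(0.5, 3, 2), 0.375)
  expect_equal(order0_closed_form(0, 5, 3), 0)
  expect_equal(order0_closed_form(1, 5, 5), 1)
  set.seed(22)
  for (i in 1:100) {
    p <- stats::runif(1, 0.05, 0.95)
    L <- sample(2:40, 1)
    n <- if (L <= 2) 2L else sample(2:min(L, 8), 1)
    m <- markov_model(0, c("a", "b"), matrix(c(p, 1 - p), 1), c(p, 1 - p))
    expect_equal(expected_saar_count(m, L, "a", n),
                 order0_closed_form(p, L, n), tolerance = 1e-12)
  }
})

test_that("expectation is monotone in n and L", {
  tr <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, byrow = TRUE)
  m <- markov_model(1, c("a", "b"), tr, c(0.5, 0.5))
  e <- sapply(2:6, function(n) expected_saar_count(m, 30, "a", n))
  expect_true(all(diff(e) < 0))
  eL <- expected_saar_count(m, c(5, 10, 20, 40, 80), "a", 3)
  expect_true(all(diff(eL) > 0))
})

test_that("simulation is seeded, exact in the deterministic limit, and
           consistent with the exact expectation", {
  ab <- c("a", "b")
  m1 <- markov_model(0, ab, matrix(c(1, 0), 1), c(1, 0))
  expect_identical(unique(simulate_sequences(m1, 6, 5, seed = 1)), "aaaaaa")

  tr <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE)
  m <- markov_model(1, ab, tr, c(0.5, 0.5))
  s1 <- simulate_sequences(m, 20, 50, seed = 9)
  s2 <- simulate_sequences(m, 20, 50, seed = 9)
  expect_identical(s1, s2)

  sims <- simulate_sequences(m, 15, 20000, seed = 10)
  counts <- vapply(sims, function(s) {
    r <- rle(strsplit(s, "")[[1]])
    sum(r$lengths[r$values == "a"] >= 2)
  }, numeric(1))
  mu <- expected_saar_count(m, 15, "a", 2)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("observed/predicted ratio is near 1 for model-matched proteins", {
  set.seed(23)
  # i.i.d. proteins from a known composition; fit order 0 and compare
  f <- AA_BASE_FREQ
  seqs <- vapply(1:300, function(i) {
    paste(sample(AA_STANDARD, 250, TRUE, prob = f), collapse = "")
  }, character(1))
  prot <- protein_table(sprintf("m%03d", 1:300), seqs)
  model <- fit_markov(prot, order = 0)
  rep <- predicted_vs_observed(model, prot, "L", 3, n_reps = 200, seed = 3)
  expect_gt(rep$expected, 0)
  expect_lt(abs(rep$ratio - 1), 3 * rep$sd + 0.01)
  # observed total equals direct recomputation from the count table
  arr <- attr(build_count_table(prot, "L", 2:5), "count_array")
  expect_equal(rep$observed, sum(arr[, "L", "3"]))
  # zero-probability residue: expectation 0 is flagged
  expect_warning(
    out <- predicted_vs_observed(fit_markov("AAAA", 0), prot, "L", 2,
                                 n_reps = 0),
    "zero")
  expect_true(is.na(out$ratio))
})
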