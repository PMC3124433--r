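test_that("the dual-predictor acceptance rule is applied exactly", {
  mk <- function(pos, rel) {
    data.frame(protein_id = "p1", score = rel * 0.5, threshold = 0.5,
               cleavage_pos = pos, stringsAsFactors = FALSE)
  }
  # positions agree, scores at 1.2x and 0.6x their thresholds: accepted
  call <- combine_signal_predictions(mk(20, 1.2), mk(20, 0.6))
  expect_true(call$accepted)
  expect_identical(call$cleavage_pos, 20)
  # positions differ: rejected regardless of scores
  expect_false(combine_signal_predictions(mk(20, 1.5), mk(21, 1.5))$accepted)
  # worse score below half its threshold: rejected
  expect_false(combine_signal_predictions(mk(20, 1.2), mk(20, 0.4))$accepted)
  # neither score reaches its threshold: rejected
  expect_false(combine_signal_predictions(mk(20, 0.9), mk(20, 0.8))$accepted)
  # boundary: worse score at exactly half, better exactly at threshold
  expect_true(combine_signal_predictions(mk(20, 1.0), mk(20, 0.5))$accepted)

  bad <- mk(20, 1.2)
  bad$protein_id <- "p2"
  expect_error(combine_signal_predictions(mk(20, 1.2), bad), "same proteins")
})

test_that("prediction tables round-trip through the TSV schema", {
  g <- generate_proteome(synthetic_config(n_proteins = 40, signal_frac = 0.5),
                         seed = 8)
  calls_tab <- make_signal_calls(g$proteins, seed = 8)
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(calls_tab, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  preds <- read_signal_predictions(tsv)
  expect_identical(nrow(preds), nrow(calls_tab))
  comb <- combine_signal_predictions(preds[preds$method == "nn", ],
                                     preds[preds$method == "hmm", ])
  expect_true(all(comb$accepted))
  # applying the calls reproduces the generator's signal annotation
  fresh <- g$proteins
  fresh$signal_end <- NA_integer_
  annotated <- apply_cleavage_calls(fresh, comb)
  expect_identical(annotated$signal_end, g$proteins$signal_end)

  expect_error(read_signal_predictions({
    f <- tempfile(); writeLines("a\tb", f); f
  }), "lacks column")
})

test_that("splitting at the cleavage site conserves the sequence and
           re-counts runs on each side", {
  p <- protein_table("x", paste0(strrep("K", 18), "LL",
                                 strrep("L", 3), strrep("A", 7)),
                     signal_end = 20L)
  parts <- split_at_cleavage(p)
  expect_identical(nchar(parts$signal$sequence), 20L)
  expect_identical(parts$mature$length, 10L)
  expect_identical(paste0(parts$signal$sequence, parts$mature$sequence),
                   p$sequence)
  # the leucine run spanning the boundary (positions 19..23) is split into
  # a run of 2 in the signal and a run of 3 in the mature part
  expect_identical(find_maximal_runs(p$sequence, "L"), 5L)
  expect_identical(find_maximal_runs(parts$signal$sequence, "L"), 2L)
  expect_identical(find_maximal_runs(parts$mature$sequence[1], "L"), 3L)

  expect_error(protein_table("y", "AAAA", signal_end = 4L), "signal_end")
})

test_that("the enrichment statistic is zero with a maximal p-value when
           whole and mature coincide", {
  set.seed(61)
  prot <- protein_table(sprintf("n%02d", 1:30), vapply(1:30, function(i) {
    paste(sample(c("A", "L", "G", "S"), 120, TRUE), collapse = "")
  }, character(1)))                     # no signal annotations at all
  bg <- structure(list(L = constant_zi_model("L", 5:7)),
                  class = "zi_background")
  cfg <- training_config(n_range = 5:7)
  cv <- fake_cv_report("L", 5:7, list(L = 1 + rnorm(40, 0, 0.1)), cfg)
  res <- enrichment_test(bg, cv, prot, min_observed = 0)
  expect_true(all(res$z == 0))
  expect_true(all(res$p >= 0.5))
  expect_true(all(res$holm_p >= res$p))
  expect_error(enrichment_test(bg, cv, prot, residues = c("L", "A")),
               "no background model")
})

test_that("the one-sided pairwise null keeps the type-I error at the
           nominal level", {
  set.seed(62)
  cfg <- training_config(n_range = 5:5)
  bg <- structure(list(L = constant_zi_model("L", 5:5)),
                  class = "zi_background")
  # proteins whose whole and mature parts differ by a neutral segment:
  # under the constant background, both ratios estimate the same quantity
  rejections <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    seqs <- vapply(1:25, function(j) {
      paste(sample(c("A", "L", "G"), 80, TRUE, prob = c(.45, .2, .35)),
            collapse = "")
    }, character(1))
    prot <- protein_table(sprintf("r%02d", 1:25), seqs,
                          signal_end = rep(c(20L, NA), c(12, 13)))
    cv <- fake_cv_report("L", 5:5, list(L = 1 + rnorm(30, 0, 0.05)), cfg)
    res <- enrichment_test(bg, cv, prot, min_observed = 0)
    if (any(res$p < 0.05, na.rm = TRUE)) rejections <- rejections + 1L
  }
  expect_lte(rejections / n_rep, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("a strong leucine injection into signal peptides is detected
           and a zero effect is not", {
  cfg <- synthetic_config(n_proteins = 500, signal_frac = 0.5,
                          signal_leu_effect = 0.5)
  g <- generate_proteome(cfg, seed = 9)
  parts <- split_at_cleavage(g$proteins)
  tc <- training_config(n_range = 5:8,
                        exclude = setdiff(AA_STANDARD, c("A", "L", "V")))
  bg <- suppressWarnings(train_background(parts$mature, "zirvm", tc,
                                          seed = 9))
  cv <- suppressWarnings(monte_carlo_cv(parts$mature, "zirvm", tc, R = 30,
                                        seed = 9))
  res <- enrichment_test(bg, cv, g$proteins)
  leu5 <- res[res$residue == "L" & res$n == 5, ]
  expect_gt(leu5$ratio_whole, leu5$ratio_mature)
  expect_gt(leu5$z, 3)
  expect_lt(leu5$holm_p, 0.05)
})
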