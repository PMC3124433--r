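test_that("the worked example decomposes into leucine runs of 5 and 2", {
  runs <- find_maximal_runs("ACDFLLLLLGWSLLV", "L")
  expect_identical(runs, c(5L, 2L))
  cc <- cumulative_counts(runs, 6)
  expect_identical(unname(cc), c(2L, 1L, 1L, 1L, 0L))
  fv <- composition_and_length(protein_table("p1", "ACDFLLLLLGWSLLV"))
  expect_equal(fv$f_L, 7 / 15)
  expect_equal(fv$l, 15L)
})

test_that("FASTA reading normalises case, wraps lines, and trims headers", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "ACDFLL", "LLLGWSLLV",
               ">p2", "acd"), fa)
  p <- read_protein_fasta(fa)
  expect_identical(p$id, c("p1", "p2"))
  expect_identical(p$sequence, c("ACDFLLLLLGWSLLV", "ACD"))
  expect_identical(p$length, c(15L, 3L))

  writeLines(character(0), fa)
  expect_identical(nrow(read_protein_fasta(fa)), 0L)

  writeLines(c("ACDEF", ">p1", "ACD"), fa)
  expect_error(read_protein_fasta(fa), "line 1")

  writeLines(c(">empty", "", ">p2", "ACD"), fa)
  expect_warning(p2 <- read_protein_fasta(fa), "empty")
  expect_identical(p2$id, "p2")
})

test_that("maximal runs match a naive scan on random sequences", {
  set.seed(11)
  letters4 <- c("A", "L", "G", "S")
  for (i in 1:100) {
    s <- paste(sample(letters4, 200, replace = TRUE,
                      prob = c(0.4, 0.35, 0.15, 0.1)), collapse = "")
    for (a in c("A", "L")) {
      expect_identical(find_maximal_runs(s, a), naive_run_scan(s, a))
    }
  }
  expect_identical(find_maximal_runs("AAAA", "A"), 4L)
  expect_identical(find_maximal_runs("AAAA", "C"), integer(0))
  expect_error(find_maximal_runs("AAAA", "X"), "standard amino-acid")
  expect_error(find_maximal_runs("AAAA", "AL"), "standard amino-acid")
})

test_that("runs of two concatenated sequences separated by another letter
           are the union of the parts", {
  set.seed(12)
  for (i in 1:20) {
    s1 <- paste(sample(c("A", "L", "G"), 50, TRUE), collapse = "")
    s2 <- paste(sample(c("A", "L", "G"), 50, TRUE), collapse = "")
    joined <- paste0(s1, "W", s2)
    for (a in c("A", "L")) {
      expect_identical(sort(find_maximal_runs(joined, a)),
                       sort(c(find_maximal_runs(s1, a),
                              find_maximal_runs(s2, a))))
    }
  }
})

test_that("cumulative counts are monotone and sum back to occurrences", {
  expect_identical(unname(cumulative_counts(integer(0), 8)), rep(0L, 7))
  set.seed(13)
  for (i in 1:50) {
    runs <- sample(1:9, sample(0:8, 1), replace = TRUE)
    nmax <- 12
    cc <- cumulative_counts(runs, nmax)
    expect_true(all(diff(cc) <= 0))
    # identity over n >= 1: c(1) = number of runs, and sum of c(n) over all
    # n equals the total residue occurrence count
    c1 <- sum(runs >= 1)
    expect_identical(c1 + sum(cc), as.integer(sum(runs)))
  }
  expect_error(cumulative_counts(c(2, 3), 1), "n_max")
})

test_that("composition handles ambiguity letters and pure sequences", {
  fv <- composition_and_length(protein_table("a", "AAAA"))
  expect_equal(fv$f_A, 1)
  expect_equal(sum(fv[paste0("f_", AA_STANDARD)]), 1)
  fv2 <- composition_and_length(protein_table("b", "AX"))
  expect_equal(fv2$f_A, 0.5)
  expect_equal(fv2$l, 2L)
  expect_equal(sum(fv2[paste0("f_", AA_STANDARD)]), 0.5)
  # ambiguity letters break runs but count towards length
  expect_identical(find_maximal_runs("LLXLL", "L"), c(2L, 2L))
})

test_that("count tables agree with per-protein recomputation", {
  p1 <- protein_table("p1", "ACDFLLLLLGWSLLV")
  tab <- build_count_table(p1, "L", 2:6)
  expect_identical(tab$count[tab$n == 5], 1L)
  expect_identical(tab$count[tab$n == 2], 2L)

  empty <- build_count_table(protein_table(character(0), character(0)),
                             "L", 2:5)
  expect_identical(nrow(empty), 0L)

  set.seed(14)
  seqs <- vapply(1:200, function(i) {
    paste(sample(AA_STANDARD, 80, TRUE), collapse = "")
  }, character(1))
  prot <- protein_table(sprintf("r%03d", 1:200), seqs)
  residues <- c("A", "L", "S")
  tab <- build_count_table(prot, residues, 2:6)
  for (i in sample(200, 25)) {
    for (a in residues) {
      runs <- naive_run_scan(seqs[i], a)
      for (n in 2:6) {
        got <- tab$count[tab$protein_id == prot$id[i] &
                           tab$residue == a & tab$n == n]
        expect_identical(got, as.integer(sum(runs >= n)))
      }
    }
  }
  # cumulative identity on the table: c(n) non-increasing in n
  arr <- attr(tab, "count_array")
  expect_true(all(apply(arr, c(1, 2), function(v) all(diff(v) <= 0))))
})
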