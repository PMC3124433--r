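# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: naive scans, exhaustive enumeration, and
# direct textbook formulas.

# position-by-position scan for maximal runs of one letter
naive_run_scan <- function(sequence, residue) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  runs <- integer(0)
  cur <- 0L
  for (ch in c(chars, "")) {           # sentinel flushes the last run
    if (identical(ch, residue)) {
      cur <- cur + 1L
    } else {
      if (cur > 0L) runs <- c(runs, cur)
      cur <- 0L
    }
  }
  runs
}

# exact expected count of maximal runs >= n of letter index 1, by summing
# over every possible string of length L under the chain's probability law
enumerate_expected_runs <- function(order, trans, ctx_dist, L, n,
                                    alphabet_size = 2L) {
  A <- alphabet_size
  grid <- as.matrix(expand.grid(rep(list(seq_len(A)), L)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    s <- grid[r, ]
    if (order == 0L) {
      p <- prod(ctx_dist[s])
    } else {
      ctx0 <- 0L
      for (j in seq_len(min(order, L))) ctx0 <- ctx0 * A + (s[j] - 1L)
      if (L < order) {
        # marginal of a truncated context: sum ctx_dist over completions
        sel <- seq_len(A^order)
        keep <- rep(TRUE, length(sel))
        for (j in seq_len(L)) {
          letter <- ((sel - 1L) %/% A^(order - j)) %% A + 1L
          keep <- keep & letter == s[j]
        }
        p <- sum(ctx_dist[keep])
      } else {
        p <- ctx_dist[ctx0 + 1L]
        if (L > order) {
          for (j in seq(order + 1L, L)) {
            ctx <- 0L
            for (q in seq(j - order, j - 1L)) ctx <- ctx * A + (s[q] - 1L)
            p <- p * trans[ctx + 1L, s[j]]
          }
        }
      }
    }
    rl <- rle(s)
    total <- total + p * sum(rl$lengths[rl$values == 1L] >= n)
  }
  total
}

# textbook step-down Holm adjustment, written independently of p.adjust
manual_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, p[ord] * (m - seq_len(m) + 1))
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# kernel ridge regression oracle on the same Gaussian design
ridge_oracle <- function(Xtr, ytr, Xte, gamma, lambda = 1e-2) {
  d2 <- function(X, Y) {
    outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  }
  K <- exp(-gamma * pmax(d2(Xtr, Xtr), 0))
  a <- solve(K + lambda * diag(nrow(K)), ytr - mean(ytr))
  mean(ytr) + as.numeric(exp(-gamma * pmax(d2(Xte, Xtr), 0)) %*% a)
}

# small deterministic protein set with leucine runs only
leucine_only_proteins <- function(n = 40L) {
  seqs <- vapply(seq_len(n), function(i) {
    body <- paste(rep(c("A", "G", "S", "T", "P", "D"), length.out = 60 + i),
                  collapse = "")
    run <- paste(rep("L", 5L + i %% 4L), collapse = "")
    paste0(substr(body, 1, 30), run, substr(body, 31, nchar(body)))
  }, character(1))
  protein_table(sprintf("lp%02d", seq_len(n)), seqs)
}

# degenerate zero-inflated model predicting a constant count of 1 for every
# protein (gate always open); used to unit-test the enrichment statistics
constant_zi_model <- function(residue, n_range) {
  stage1 <- lapply(stats::setNames(as.character(n_range), n_range),
                   function(n) list(degenerate = "all", gate = NULL,
                                    threshold = NULL, prevalence = 1))
  stage2 <- structure(list(coefficients = rep(0, 20),
                           exponents = saarbg:::poly_basis_exponents(),
                           degree = 3L, n_params = 20L),
                      class = "poly_stage")
  saarbg:::zi_model(residue, n_range, stage1, stage2, "zipol")
}

# minimal cv_report-like object with a given score matrix per cell
fake_cv_report <- function(residues, n_range, scores_list, cfg) {
  R <- length(scores_list[[1]])
  sc <- array(NA_real_, dim = c(R, length(residues), length(n_range)),
              dimnames = list(NULL, residues, n_range))
  for (a in residues) for (nj in as.character(n_range)) {
    sc[, a, nj] <- scores_list[[a]]
  }
  structure(list(scores = sc, cfg = cfg, R = R), class = "cv_report")
}
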