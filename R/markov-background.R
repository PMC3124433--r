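#' Construct a Markov sequence model
#'
#' Low-level constructor for a Markov chain over a residue alphabet. Most
#' users will obtain models from [fit_markov()]; the constructor is exposed
#' so that models with known transition probabilities can be built directly
#' (e.g. for simulation studies on small alphabets).
#'
#' @param order Markov order `k` (0 to 3).
#' @param alphabet Character vector of single letters.
#' @param transitions Matrix of conditional probabilities of the next letter
#'   given the k-letter context: `A^k` rows (contexts, first letter most
#'   significant in the row ordering) by `A` columns (next letter). For
#'   `order = 0` a single-row matrix of marginal probabilities.
#' @param context_dist Probability of each k-letter context (length `A^k`);
#'   for `order = 0`, the marginal letter distribution (length `A`).
#' @param tuple_counts Optional integer vector of (k+1)-tuple counts the
#'   model was estimated from.
#' @return An object of class `markov_model` with elements `order`,
#'   `alphabet`, `transitions`, `context_dist`, `tuple_counts`, `n_params`
#'   (`= A^(k+1)`; 20 parameters at order 0, 160,000 at order 3 on the
#'   standard alphabet).
#' @export
markov_model <- function(order, alphabet, transitions, context_dist,
                         tuple_counts = NULL) {
  stopifnot(order %in% 0:3)
  A <- length(alphabet)
  ncx <- A^order
  transitions <- matrix(as.numeric(transitions), nrow = max(ncx, 1L), ncol = A)
  stopifnot(all(transitions >= 0))
  rs <- rowSums(transitions)
  if (any(abs(rs - 1) > 1e-8)) {
    stop("each transition row must sum to 1", call. = FALSE)
  }
  context_dist <- as.numeric(context_dist)
  expected_len <- if (order == 0L) A else ncx
  stopifnot(length(context_dist) == expected_len,
            abs(sum(context_dist) - 1) < 1e-8, all(context_dist >= 0))
  structure(list(order = as.integer(order), alphabet = as.character(alphabet),
                 transitions = transitions, context_dist = context_dist,
                 tuple_counts = tuple_counts, n_params = A^(order + 1)),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("Markov chain of order %d over %d letters (%s parameters)\n",
              x$order, length(x$alphabet),
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

# integer codes of a sequence; letters outside the alphabet become NA
encode_sequence <- function(sequence, alphabet) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], alphabet)
}

# indices (1-based) of all m-tuples fully inside the alphabet; cc is the
# concatenated code vector with NA separators so tuples never span proteins
tuple_indices <- function(cc, m, A) {
  M <- length(cc) - m + 1L
  if (M < 1L) return(integer(0))
  idx <- rep(0, M)
  ok <- rep(TRUE, M)
  for (j in seq_len(m)) {
    x <- cc[j:(j + M - 1L)]
    ok <- ok & !is.na(x)
    x[is.na(x)] <- 1L
    idx <- idx * A + (x - 1L)
  }
  (idx + 1L)[ok]
}

#' Fit a Markov chain to a protein set
#'
#' Estimates transition probabilities of a Markov chain of order `k` from
#' the (k+1)-tuple frequencies of a sequence set. Tuples never span two
#' proteins, and letters outside the alphabet (ambiguity codes) interrupt
#' the tuple stream. The context distribution is the empirical k-tuple
#' frequency over all sequence positions. Contexts that never occur in
#' training receive a uniform (add-one smoothed) transition row; estimates
#' for observed contexts are untouched maximum-likelihood ratios.
#'
#' @param proteins Protein table ([protein_table()]) or character vector of
#'   sequences.
#' @param order Markov order `k` in 0..3.
#' @param alphabet Residue alphabet (default: the 20 standard letters).
#' @return A [markov_model()].
#' @examples
#' m <- fit_markov(c("AAB", "ABA"), order = 0, alphabet = c("A", "B"))
#' m$context_dist  # marginal letter frequencies
#' @export
fit_markov <- function(proteins, order, alphabet = AA_STANDARD) {
  stopifnot(order %in% 0:3)
  seqs <- if (is.data.frame(proteins)) proteins$sequence else proteins
  if (length(seqs) == 0L) stop("empty training set", call. = FALSE)
  A <- length(alphabet)
  codes <- lapply(seqs, encode_sequence, alphabet = alphabet)
  cc <- unlist(lapply(codes, function(x) c(x, NA_integer_)), use.names = FALSE)
  m <- order + 1L
  tc <- tabulate(tuple_indices(cc, m, A), nbins = A^m)
  if (sum(tc) == 0L) {
    stop("training set contains no usable ", m, "-tuples", call. = FALSE)
  }
  # transition rows: counts of next letter within each k-context
  cnt <- matrix(tc, nrow = A)           # rows: next letter, cols: context
  trans <- t(cnt)
  tot <- rowSums(trans)
  unseen <- tot == 0
  trans[unseen, ] <- 1 / A              # add-one smoothing for unseen contexts
  trans[!unseen, ] <- trans[!unseen, , drop = FALSE] / tot[!unseen]
  if (order == 0L) {
    ctx_dist <- tc / sum(tc)
    trans <- matrix(ctx_dist, nrow = 1)
  } else {
    kt <- tabulate(tuple_indices(cc, order, A), nbins = A^order)
    ctx_dist <- kt / sum(kt)
  }
  markov_model(order, alphabet, trans, ctx_dist, tuple_counts = tc)
}

# Propagation view of a model: contexts of length kc = max(k, 1), a
# transition matrix T (ncx x A) giving P(next letter | context), the initial
# context distribution d0 over kc-contexts, and the index map of context
# shifts. Order 0 is embedded as a single-letter context with row-constant
# transitions so that the forward recursion below covers all orders.
markov_prop <- function(model) {
  A <- length(model$alphabet)
  k <- model$order
  kc <- max(k, 1L)
  ncx <- A^kc
  if (k == 0L) {
    T <- matrix(model$transitions[1, ], nrow = ncx, ncol = A, byrow = TRUE)
    d0 <- model$context_dist
  } else {
    T <- model$transitions
    d0 <- model$context_dist
  }
  # shift(ctx, b): drop the most significant letter, append b
  base <- ((seq_len(ncx) - 1L) %% A^(kc - 1L)) * A
  shift <- outer(base, seq_len(A) - 1L, "+") + 1L   # ncx x A
  list(A = A, kc = kc, ncx = ncx, T = T, d0 = d0, shift = shift)
}

# letter (code) at position p (1..kc) of every context index
context_letter <- function(ncx, A, kc, p) {
  ((seq_len(ncx) - 1L) %/% A^(kc - p)) %% A + 1L
}

# P(next m letters all equal a | context), for every context; list over m=0..n
run_prob_from_context <- function(prop, a_code, n) {
  r <- vector("list", n + 1L)
  r[[1]] <- rep(1, prop$ncx)
  sa <- prop$shift[, a_code]
  Ta <- prop$T[, a_code]
  for (m in seq_len(n)) r[[m + 1L]] <- Ta * r[[m]][sa]
  r
}

# Per-start-position probabilities that a maximal run of >= n consecutive
# letters 'a' begins at position i, for i = 1..Lmax; the expected count for
# a length-L sequence is the sum of the first L - n + 1 terms.
run_start_terms <- function(model, a, n, Lmax) {
  prop <- markov_prop(model)
  a_code <- match(a, model$alphabet)
  if (is.na(a_code)) stop("residue not in model alphabet", call. = FALSE)
  A <- prop$A; kc <- prop$kc; ncx <- prop$ncx
  r <- run_prob_from_context(prop, a_code, n)
  terms <- numeric(Lmax)
  # i = 1: the first n letters are all 'a'
  if (n >= kc) {
    all_a <- sum((rep(a_code, kc) - 1L) * A^(kc - seq_len(kc))) + 1L
    terms[1] <- prop$d0[all_a] * r[[n - kc + 1L]][all_a]
  } else {
    lead_a <- rep(TRUE, ncx)
    for (p in seq_len(n)) lead_a <- lead_a & context_letter(ncx, A, kc, p) == a_code
    terms[1] <- sum(prop$d0[lead_a])
  }
  # 2 <= i <= kc: the non-'a' boundary letter lies inside the initial block
  for (i in seq_len(min(kc, Lmax))[-1]) {
    j <- i - 1L
    cond <- context_letter(ncx, A, kc, j) != a_code
    for (p in seq(j + 1L, min(j + n, kc))) {
      cond <- cond & context_letter(ncx, A, kc, p) == a_code
    }
    m_extra <- max(0L, j + n - kc)
    terms[i] <- sum(prop$d0[cond] * r[[m_extra + 1L]][cond])
  }
  # i > kc: forward recursion over the context ending at position i - 1
  if (Lmax > kc) {
    last_not_a <- context_letter(ncx, A, kc, kc) != a_code
    w <- ifelse(last_not_a, r[[n + 1L]], 0)
    Pt <- Matrix::sparseMatrix(
      i = as.vector(prop$shift),
      j = rep(seq_len(ncx), times = A),
      x = as.vector(prop$T),
      dims = c(ncx, ncx)
    )
    d <- prop$d0
    for (t in seq(kc, Lmax - 1L)) {
      terms[t + 1L] <- sum(d * w)
      if (t < Lmax - 1L) d <- as.numeric(Pt %*% d)
    }
  }
  terms
}

#' Expected number of maximal runs under a Markov model
#'
#' Exact expected number of maximal runs of residue `a` with length at least
#' `n` in a random sequence of length `L` drawn from the model. The
#' computation sums, over start positions `i`, the probability of the event
#' that position `i` opens a run of at least `n` copies of `a` (i.e. `i = 1`
#' or the preceding letter differs from `a`), propagating position marginals
#' by a forward recursion over k-letter contexts initialised at the
#' empirical context distribution.
#'
#' @param model A [markov_model()].
#' @param L Sequence length (scalar or vector; vectorised over `L`).
#' @param a Residue letter.
#' @param n Minimal run length (`n >= 2`). Lengths `L < n` yield 0.
#' @return Numeric vector of expected counts, one per element of `L`.
#' @examples
#' m <- markov_model(0, c("a", "b"), matrix(c(0.5, 0.5), 1), c(0.5, 0.5))
#' expected_saar_count(m, 3, "a", 2)  # 0.375
#' @export
expected_saar_count <- function(model, L, a, n) {
  stopifnot(n >= 2)
  L <- as.integer(L)
  out <- numeric(length(L))
  valid <- L >= n
  if (!any(valid)) return(out)
  terms <- run_start_terms(model, a, n, max(L))
  cum <- cumsum(terms)
  out[valid] <- cum[L[valid] - n + 1L]
  out
}

#' Closed-form order-0 expected run count
#'
#' For an i.i.d. sequence where residue `a` has probability `p`, the expected
#' number of maximal runs of length at least `n` in a length-`L` sequence is
#' `p^n * (1 + (L - n) * (1 - p))`: one term for a run starting at the first
#' position plus `L - n` interior start positions each requiring a preceding
#' non-`a` letter. Serves as an analytic cross-check of the forward
#' recursion in the order-0 limit.
#'
#' @param p Residue probability in `[0, 1]`.
#' @param L Sequence length.
#' @param n Minimal run length (`n <= L`).
#' @return Expected count (numeric).
#' @export
order0_closed_form <- function(p, L, n) {
  stopifnot(p >= 0, p <= 1, n <= L)
  p^n * (1 + (L - n) * (1 - p))
}

#' Simulate sequences from a Markov model
#'
#' Draws independent sequences of length `L` from the chain: the initial
#' context is drawn from the model's context distribution, subsequent
#' letters from the transition probabilities. Reproducible under a fixed
#' seed.
#'
#' @param model A [markov_model()].
#' @param L Sequence length.
#' @param n_reps Number of sequences.
#' @param seed Integer RNG seed.
#' @return Character vector of `n_reps` sequences.
#' @export
simulate_sequences <- function(model, L, n_reps, seed) {
  stopifnot(n_reps >= 1, L >= 1)
  set.seed(as.integer(seed))
  prop <- markov_prop(model)
  mat <- simulate_letter_matrix(prop, rep(L, n_reps))
  apply(mat, 1L, function(row) paste(prop_letters(model)[row], collapse = ""))
}

prop_letters <- function(model) model$alphabet

# letters (codes) for chains of the given lengths; matrix chains x max(len),
# positions beyond a chain's length are NA. Uses the current RNG stream.
simulate_letter_matrix <- function(prop, lengths) {
  nch <- length(lengths)
  Lmax <- max(lengths)
  out <- matrix(NA_integer_, nch, Lmax)
  ctx <- sample.int(prop$ncx, nch, replace = TRUE, prob = prop$d0)
  for (p in seq_len(min(prop$kc, Lmax))) {
    out[, p] <- context_letter(prop$ncx, prop$A, prop$kc, p)[ctx]
  }
  if (Lmax > prop$kc) {
    cumT <- t(apply(prop$T, 1L, cumsum))
    for (t in seq(prop$kc + 1L, Lmax)) {
      u <- stats::runif(nch)
      nxt <- rowSums(u > cumT[ctx, , drop = FALSE]) + 1L
      out[, t] <- nxt
      ctx <- prop$shift[cbind(ctx, nxt)]
    }
  }
  for (i in seq_len(nch)) {
    if (lengths[i] < Lmax) out[i, seq(lengths[i] + 1L, Lmax)] <- NA_integer_
  }
  out
}

# counts of maximal runs of residue code a_code with length >= n per chain
count_runs_in_matrix <- function(mat, lengths, a_code, n) {
  nch <- nrow(mat)
  run <- integer(nch)
  cnt <- integer(nch)
  for (t in seq_len(ncol(mat))) {
    active <- t <= lengths
    isa <- active & !is.na(mat[, t]) & mat[, t] == a_code
    run <- ifelse(isa, run + 1L, 0L)
    cnt <- cnt + (run == n)
  }
  cnt
}

#' Observed versus predicted repeat counts under a Markov model
#'
#' Pools, over a protein set, the observed cumulative counts of maximal runs
#' of residue `a` with length at least `n` and the exact model expectation
#' at each protein's length, and reports their ratio. The ratio's model
#' standard deviation is estimated by Monte Carlo: each protein's count is
#' simulated `n_reps` times from the model and the standard deviation of the
#' pooled simulated/expected ratio is taken. The pooled construction (sum of
#' observed over sum of expected) is used because per-protein ratios are
#' undefined for repeat-free proteins.
#'
#' @param model A [markov_model()].
#' @param proteins Protein table.
#' @param a Residue letter.
#' @param n Minimal run length.
#' @param n_reps Monte-Carlo replicates for the standard deviation
#'   (default 1000; `0` skips the simulation and reports `NA`).
#' @param seed Integer RNG seed for the simulation.
#' @return One-row `data.frame`: `residue`, `n`, `observed`, `expected`,
#'   `ratio`, `sd`.
#' @export
predicted_vs_observed <- function(model, proteins, a, n, n_reps = 1000,
                                  seed = 1) {
  check_residue_in <- match(a, model$alphabet)
  if (is.na(check_residue_in)) stop("residue not in model alphabet",
                                    call. = FALSE)
  obs <- sum(vapply(proteins$sequence,
                    function(s) sum(find_maximal_runs_any(s, a) >= n),
                    numeric(1)))
  lens <- proteins$length
  terms <- run_start_terms(model, a, n, max(lens))
  cum <- cumsum(terms)
  expv <- ifelse(lens >= n, cum[pmax(lens - n + 1L, 1L)], 0)
  expected_total <- sum(expv)
  if (expected_total == 0) {
    warning("expected total is zero; ratio undefined", call. = FALSE)
    ratio <- NA_real_
  } else {
    ratio <- obs / expected_total
  }
  sdv <- NA_real_
  if (n_reps > 0 && expected_total > 0) {
    set.seed(as.integer(seed))
    prop <- markov_prop(model)
    a_code <- match(a, model$alphabet)
    ratios <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      mat <- simulate_letter_matrix(prop, lens)
      ratios[r] <- sum(count_runs_in_matrix(mat, lens, a_code, n)) /
        expected_total
    }
    sdv <- stats::sd(ratios)
  }
  data.frame(residue = a, n = as.integer(n), observed = obs,
             expected = expected_total, ratio = ratio, sd = sdv,
             stringsAsFactors = FALSE)
}

# run finder that tolerates residues outside the standard alphabet guard
# (internal; used where the model alphabet may be non-standard)
find_maximal_runs_any <- function(sequence, residue) {
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]])
  as.integer(r$lengths[r$values == residue])
}
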