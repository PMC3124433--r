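#' Training configuration for the zero-inflated background models
#'
#' Bundles the subsampling and binning parameters of the two-stage training
#' procedure. Stage 1 (the logistic gate) is fitted per repeat length on up
#' to `stage1_cap` proteins. Stage 2 (the conditional count regressor) is
#' fitted per residue on a weighted subsample that balances observations in
#' bins of protein length, residue composition and repeat length, with the
#' total capped at `stage2_cap` points.
#'
#' @param n_range Repeat lengths to model (default 5..10, the range over
#'   which run counts are genuinely informative; shorter runs are expected
#'   by chance for typical protein lengths).
#' @param stage1_cap Subsample cap per presence fit.
#' @param stage2_cap Total cap of the balanced stage-2 subsample.
#' @param length_bins,comp_bins Number of quantile bins of log protein
#'   length and log residue composition used for balancing (each repeat
#'   length is additionally its own bin).
#' @param exclude Residues excluded from training (default tryptophan,
#'   whose longer repeats are too rare to validate).
#' @param soft_gate Combine the stages as the soft mixture `p * E[c | c > 0]`
#'   (default) instead of the hard classification gate. The thresholded
#'   gate conditions the count stage on the proteins most likely to contain
#'   a repeat — exactly where the conditional count surface is highest — so
#'   whenever the presence classes overlap appreciably its pooled
#'   predictions acquire a residue-dependent selection bias; the mixture is
#'   immune to this and keeps pooled ratios calibrated at moderate sample
#'   sizes. Set `FALSE` for strict thresholded gating (thresholds are
#'   fitted and stored either way).
#' @param rvm_method Optimisation route for the RVM stage.
#' @return Object of class `training_config`.
#' @export
training_config <- function(n_range = 5:10, stage1_cap = 1e5,
                            stage2_cap = 2000L, length_bins = 4L,
                            comp_bins = 4L, exclude = "W",
                            soft_gate = TRUE,
                            rvm_method = c("fast", "em")) {
  n_bins <- length_bins * comp_bins * length(n_range)
  if (stage2_cap < n_bins) {
    stop("stage2_cap (", stage2_cap, ") must be at least the number of bins (",
         n_bins, ")", call. = FALSE)
  }
  structure(list(n_range = sort(as.integer(n_range)),
                 stage1_cap = as.integer(stage1_cap),
                 stage2_cap = as.integer(stage2_cap),
                 length_bins = as.integer(length_bins),
                 comp_bins = as.integer(comp_bins),
                 exclude = as.character(exclude),
                 soft_gate = isTRUE(soft_gate),
                 rvm_method = match.arg(rvm_method)),
            class = "training_config")
}

# quantile bin index (1..k) of x; constant x collapses to one bin
quantile_bins <- function(x, k) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1)))
  if (length(br) < 3L) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE))
}

#' Balanced subsample of training points
#'
#' Draws, without replacement, a subsample that equalises the number of
#' observations across bins (up to each bin's availability) with the total
#' capped at `cap`: rows are drawn round-robin, one per bin per round, in a
#' seeded random within-bin order. Corrects for the highly skewed abundance
#' of repeat observations across lengths and compositions.
#'
#' @param bin Integer or factor vector of bin memberships, one per row.
#' @param cap Total subsample cap.
#' @param seed Integer RNG seed.
#' @return Integer vector of selected row indices (sorted).
#' @export
balanced_subsample <- function(bin, cap, seed) {
  n <- length(bin)
  if (n == 0L) stop("empty table", call. = FALSE)
  set.seed(as.integer(seed))
  ord <- sample.int(n)                    # random within-bin order
  bin_ord <- as.integer(factor(bin[ord]))
  rank_in_bin <- stats::ave(seq_along(ord), bin_ord, FUN = seq_along)
  keep <- order(rank_in_bin, sample.int(n))[seq_len(min(cap, n))]
  sort(ord[keep])
}

# stage-2 training rows for one residue: (protein, n) cells with count >= 1
stage2_rows <- function(arr, features, residue, n_range) {
  cnt <- arr[, residue, , drop = FALSE]
  dim(cnt) <- dim(arr)[c(1, 3)]
  idx <- which(cnt >= 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  l <- features$l[idx[, 1]]
  f_a <- features[[paste0("f_", residue)]][idx[, 1]]
  n <- n_range[idx[, 2]]
  list(x = stage2_covariates(n, l, f_a), y = log(cnt[idx]),
       n = n, l = l, f_a = f_a, protein = idx[, 1])
}

# train one residue's zero-inflated model from precomputed features and the
# count array (proteins x residues x n)
train_zi_residue <- function(residue, features, arr, kind, cfg, seed) {
  n_range <- cfg$n_range
  l <- features$l
  f_a <- features[[paste0("f_", residue)]]
  x1 <- stage1_covariates(l, f_a)
  stage1 <- list()
  for (j in seq_along(n_range)) {
    n <- n_range[j]
    lab <- as.numeric(arr[, residue, j] >= 1L)
    cell <- list(degenerate = NULL, gate = NULL, threshold = NULL,
                 prevalence = mean(lab))
    if (all(lab == 0)) {
      cell$degenerate <- "none"
    } else if (all(lab == 1)) {
      cell$degenerate <- "all"
    } else {
      rows <- seq_along(lab)
      if (length(rows) > cfg$stage1_cap) {
        set.seed(as.integer(seed) + j)
        rows <- sample(rows, cfg$stage1_cap)
      }
      gate <- fit_presence_stage(x1[rows, , drop = FALSE], lab[rows],
                                 cell = sprintf("%s,n=%d", residue, n))
      p <- predict(gate, x1[rows, , drop = FALSE])
      cell$gate <- gate
      cell$threshold <- select_gate_threshold(p, lab[rows])
    }
    stage1[[as.character(n)]] <- cell
  }
  s2 <- stage2_rows(arr, features, residue, n_range)
  if (is.null(s2)) return(NULL)
  bin <- interaction(quantile_bins(log(s2$l), cfg$length_bins),
                     quantile_bins(log(s2$f_a + composition_eps(s2$l)),
                                   cfg$comp_bins),
                     s2$n, drop = TRUE)
  keep <- balanced_subsample(bin, cfg$stage2_cap, seed)
  x2 <- s2$x[keep, , drop = FALSE]
  y2 <- s2$y[keep]
  stage2 <- if (kind == "zirvm") {
    fit_rvm_stage(x2, y2, method = cfg$rvm_method)
  } else {
    fit_polynomial_stage(x2, y2)
  }
  # retransformation (smearing) factors: exp(E[log c]) underestimates
  # E[c | c >= 1] wherever the conditional counts are dispersed; the mean
  # exponentiated residual per repeat length corrects this on the count
  # scale (near 1 at lengths where almost every positive count is 1)
  resid <- y2 - predict(stage2, x2)
  n2 <- s2$n[keep]
  smear <- vapply(split(exp(resid), n2), mean, numeric(1))
  smear[!is.finite(smear)] <- 1
  zi_model(residue, n_range, stage1, stage2, kind,
           meta = list(stage2_n = length(y2), seed = seed, smear = smear))
}

train_background_core <- function(features, arr, kind, cfg, seed) {
  residues <- dimnames(arr)[[2]]
  models <- list()
  for (a in residues) {
    any_pos <- sum(arr[, a, ]) > 0
    if (!any_pos) {
      warning("residue ", a, " has no repeat-containing protein at any ",
              "modelled length; skipped", call. = FALSE)
      next
    }
    m <- tryCatch(train_zi_residue(a, features, arr, kind, cfg, seed),
                  error = function(e) {
                    warning("residue ", a, " skipped: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(m)) models[[a]] <- m
  }
  structure(models, class = "zi_background")
}

#' Train per-residue zero-inflated background models
#'
#' For each residue (except exclusions), fits the two-stage model: a
#' logistic presence gate per repeat length with an error-balancing
#' classification threshold, then the conditional count regressor (RVM or
#' polynomial) on a balanced subsample of the repeat-containing
#' observations. Residues with no repeat-containing protein at any modelled
#' length are skipped with a warning.
#'
#' @param proteins Protein table ([protein_table()]).
#' @param kind `"zirvm"` (RVM count stage) or `"zipol"` (polynomial).
#' @param cfg A [training_config()].
#' @param seed Integer RNG seed (subsampling).
#' @return Object of class `zi_background`: a named list of [zi_model]
#'   objects, one per trained residue.
#' @export
train_background <- function(proteins, kind = c("zirvm", "zipol"),
                             cfg = training_config(), seed = 1) {
  kind <- match.arg(kind)
  residues <- setdiff(AA_STANDARD, cfg$exclude)
  features <- composition_and_length(proteins)
  arr <- count_array(proteins, residues, cfg$n_range)
  train_background_core(features, arr, kind, cfg, seed)
}

#' @export
print.zi_background <- function(x, ...) {
  cat(sprintf("Zero-inflated background: %d residue model(s) (%s)\n",
              length(x), paste(names(x), collapse = "")))
  invisible(x)
}

# pooled observed and predicted totals per (residue, n) cell for a protein
# subset described by its features and count array slice
score_cells <- function(models, features, arr, cfg) {
  residues <- names(models)
  n_range <- cfg$n_range
  obs <- pred <- matrix(NA_real_, length(residues), length(n_range),
                        dimnames = list(residues, n_range))
  for (a in residues) {
    for (j in seq_along(n_range)) {
      obs[a, j] <- sum(arr[, a, j])
      if (n_range[j] %in% models[[a]]$n_range) {
        pred[a, j] <- sum(predict_expected_count(models[[a]], features,
                                                 n_range[j],
                                                 soft = cfg$soft_gate))
      }
    }
  }
  list(observed = obs, predicted = pred)
}

#' Monte-Carlo cross-validation of the background models
#'
#' Repeats `R` independent random splits of the protein set into a training
#' fraction (default two thirds) and a held-out test set; per repetition and
#' (residue, repeat length) cell, the test score is the pooled ratio of
#' observed to predicted repeat counts on the test set. Scores centred on 1
#' indicate a well-calibrated background. The per-cell score standard
#' deviation estimates the model uncertainty, and an empirical p-value
#' compares the score distribution to the perfect score of 1.
#'
#' @param proteins Protein table.
#' @param kind `"zirvm"` or `"zipol"`.
#' @param cfg A [training_config()].
#' @param R Number of repetitions (default 100).
#' @param train_frac Training fraction per split (default 2/3).
#' @param seed Integer RNG master seed.
#' @return Object of class `cv_report`: `scores` (array R x residue x n,
#'   `NA` where a cell's predicted total was zero), `mean`, `sd`, `p`
#'   (two-sided empirical p-value against 1), `rmse` (per-residue log-scale
#'   RMSE over repeat lengths), `observed_total` per cell, plus the
#'   configuration.
#' @export
monte_carlo_cv <- function(proteins, kind = c("zirvm", "zipol"),
                           cfg = training_config(), R = 100L,
                           train_frac = 2 / 3, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(R >= 2)
  residues <- setdiff(AA_STANDARD, cfg$exclude)
  features <- composition_and_length(proteins)
  arr <- count_array(proteins, residues, cfg$n_range)
  np <- nrow(proteins)
  n_train <- round(train_frac * np)
  scores <- array(NA_real_, dim = c(R, length(residues), length(cfg$n_range)),
                  dimnames = list(NULL, residues, cfg$n_range))
  obs_sum <- pred_sum <- matrix(0, length(residues), length(cfg$n_range),
                                dimnames = list(residues, cfg$n_range))
  for (r in seq_len(R)) {
    rep_seed <- (as.integer(seed) + 104729L * r) %% 2147483563L
    set.seed(rep_seed)
    tr <- sample.int(np, n_train)
    te <- setdiff(seq_len(np), tr)
    models <- suppressWarnings(train_background_core(
      features[tr, , drop = FALSE], arr[tr, , , drop = FALSE],
      kind, cfg, rep_seed))
    sc <- score_cells(models, features[te, , drop = FALSE],
                      arr[te, , , drop = FALSE], cfg)
    for (a in names(models)) {
      ok <- !is.na(sc$predicted[a, ]) & sc$predicted[a, ] > 0
      scores[r, a, ok] <- sc$observed[a, ok] / sc$predicted[a, ok]
      obs_sum[a, ] <- obs_sum[a, ] + sc$observed[a, ]
      pred_sum[a, ] <- pred_sum[a, ] + sc$predicted[a, ]
    }
  }
  mean_sc <- apply(scores, c(2, 3), mean, na.rm = TRUE)
  sd_sc <- apply(scores, c(2, 3), stats::sd, na.rm = TRUE)
  p <- apply(scores, c(2, 3), function(s) {
    s <- s[is.finite(s)]
    if (length(s) < 2L) return(NA_real_)
    empirical_pvalue(s, reference = 1, sided = "two")
  })
  rmse <- vapply(residues, function(a) {
    valid <- pred_sum[a, ] > 0 | obs_sum[a, ] > 0
    if (!any(valid)) return(NA_real_)
    tryCatch(rmse_log(obs_sum[a, valid], pred_sum[a, valid]),
             error = function(e) NA_real_)
  }, numeric(1))
  structure(list(scores = scores, mean = mean_sc, sd = sd_sc, p = p,
                 rmse = rmse, observed_total = apply(arr, c(2, 3), sum),
                 R = R, train_frac = train_frac, kind = kind, cfg = cfg,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Monte-Carlo CV report: %d repetitions, %d residues, n = %s\n",
              x$R, nrow(x$mean), paste(range(x$cfg$n_range), collapse = "..")))
  invisible(x)
}

#' Empirical p-value of a score distribution against a reference
#'
#' Add-one empirical p-value: with `R` scores, the two-sided p-value is
#' `min(1, 2 * (min(#\{s <= ref\}, #\{s >= ref\}) + 1) / (R + 1))`; the
#' one-sided variants use the stated tail. The add-one convention keeps p
#' strictly positive for finite `R`.
#'
#' @param scores Numeric vector (length >= 2).
#' @param reference Reference value (default 1, the perfect pooled ratio).
#' @param sided `"two"`, `"greater"` (tail above the reference) or
#'   `"less"`.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(scores, reference = 1,
                             sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  scores <- scores[is.finite(scores)]
  R <- length(scores)
  stopifnot(R >= 2)
  lo <- sum(scores <= reference)
  hi <- sum(scores >= reference)
  p <- switch(sided,
              two = 2 * (min(lo, hi) + 1) / (R + 1),
              greater = (hi + 1) / (R + 1),
              less = (lo + 1) / (R + 1))
  min(1, p)
}

#' Log-scale root mean square error of observed versus predicted counts
#'
#' RMSE of `log(observed / predicted)` across repeat lengths, weighting
#' over- and under-prediction symmetrically. Cells with zero observed and
#' zero predicted counts are excluded; a zero on one side only enters
#' through a continuity correction of one half.
#'
#' @param observed,predicted Aligned non-negative vectors (one entry per
#'   repeat length).
#' @return The RMSE (numeric scalar).
#' @export
rmse_log <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted),
            all(observed >= 0), all(predicted >= 0))
  both_zero <- observed == 0 & predicted == 0
  o <- observed[!both_zero]
  p <- predicted[!both_zero]
  if (length(o) == 0L) stop("no valid cells for RMSE", call. = FALSE)
  o[o == 0] <- 0.5
  p[p == 0] <- 0.5
  sqrt(mean(log(o / p)^2))
}

#' Holm step-down multiple-testing adjustment
#'
#' Familywise-error adjustment across the repeat lengths tested per
#' residue (or any p-value family): sort ascending, multiply the i-th by
#' `m - i + 1`, enforce monotonicity, cap at 1.
#'
#' @param p_values Vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "holm")
}
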