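#' Read signal-peptide predictor output
#'
#' Parses the simple tab-delimited schema used for predictor outputs: one
#' row per protein per prediction method with columns `protein_id`,
#' `method`, `score`, `threshold`, `cleavage_pos` (1-based position of the
#' last signal-peptide residue).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with the five columns above.
#' @export
read_signal_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "method", "score", "threshold", "cleavage_pos")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("signal prediction table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(df$score >= 0), all(df$threshold > 0),
            all(df$cleavage_pos >= 1))
  df[, need]
}

#' Combine two signal-peptide predictions into a conservative call
#'
#' A prediction is accepted only when both methods agree on the cleavage
#' site, at least one score meets its default threshold, and the worse
#' score reaches at least half its threshold. Vectorised: both inputs are
#' tables with columns `protein_id`, `score`, `threshold`, `cleavage_pos`,
#' matched by protein identifier.
#'
#' @param pred_a,pred_b Prediction tables (one row per protein each),
#'   covering the same proteins.
#' @return A `data.frame` with columns `protein_id`, `accepted` (logical)
#'   and `cleavage_pos` (`NA` where not accepted).
#' @export
combine_signal_predictions <- function(pred_a, pred_b) {
  if (!setequal(pred_a$protein_id, pred_b$protein_id) ||
      anyDuplicated(pred_a$protein_id) || anyDuplicated(pred_b$protein_id)) {
    stop("prediction tables must cover the same proteins exactly once",
         call. = FALSE)
  }
  b <- pred_b[match(pred_a$protein_id, pred_b$protein_id), ]
  rel_a <- pred_a$score / pred_a$threshold
  rel_b <- b$score / b$threshold
  accepted <- pred_a$cleavage_pos == b$cleavage_pos &
    pmax(rel_a, rel_b) >= 1 & pmin(rel_a, rel_b) >= 0.5
  data.frame(protein_id = pred_a$protein_id, accepted = accepted,
             cleavage_pos = ifelse(accepted, pred_a$cleavage_pos,
                                   NA_integer_),
             stringsAsFactors = FALSE)
}

#' Annotate proteins with accepted cleavage calls
#'
#' Sets `signal_end` for proteins with an accepted call; calls at or beyond
#' the protein length are rejected with an error.
#'
#' @param proteins Protein table.
#' @param calls Output of [combine_signal_predictions()].
#' @return The protein table with `signal_end` filled in.
#' @export
apply_cleavage_calls <- function(proteins, calls) {
  idx <- match(proteins$id, calls$protein_id)
  pos <- ifelse(!is.na(idx) & calls$accepted[idx],
                calls$cleavage_pos[idx], NA_integer_)
  bad <- !is.na(pos) & pos >= proteins$length
  if (any(bad)) {
    stop("cleavage position at or beyond protein length for: ",
         paste(proteins$id[bad], collapse = ", "), call. = FALSE)
  }
  proteins$signal_end <- as.integer(pos)
  proteins
}

#' Split proteins at the signal-peptide cleavage site
#'
#' Separates each annotated protein into its signal peptide (positions
#' `1..signal_end`) and mature sequence (`signal_end + 1 .. length`);
#' proteins without a `signal_end` annotation contribute an empty signal
#' segment and an unchanged mature sequence. Concatenating the two parts
#' restores the original sequence.
#'
#' @param proteins Protein table with `signal_end` set where applicable.
#' @return A list with `signal` (a `data.frame` of `id`, `sequence` for
#'   annotated proteins) and `mature` (a protein table of the mature
#'   sequences of all proteins, ids retained).
#' @export
split_at_cleavage <- function(proteins) {
  has <- !is.na(proteins$signal_end)
  signal <- data.frame(
    id = proteins$id[has],
    sequence = substr(proteins$sequence[has], 1L, proteins$signal_end[has]),
    stringsAsFactors = FALSE)
  mature_seq <- proteins$sequence
  mature_seq[has] <- substr(proteins$sequence[has],
                            proteins$signal_end[has] + 1L,
                            proteins$length[has])
  list(signal = signal, mature = protein_table(proteins$id, mature_seq))
}

#' Deviation of a protein set from a background model
#'
#' First-phase check of the use case: per (residue, repeat length) cell,
#' the pooled observed/predicted ratio of the study set is compared
#' two-sidedly to the cross-validation score distribution of the background
#' model, with Holm correction across repeat lengths per residue. Rejection
#' indicates that the study set's repeat statistics are not captured by the
#' background (no common background distribution).
#'
#' @param background A `zi_background` ([train_background()]).
#' @param cv_report The background's [monte_carlo_cv()] report (supplies
#'   the null score distribution).
#' @param proteins Study protein table.
#' @return A `data.frame`: `residue`, `n`, `ratio`, `p`, `holm_p`.
#' @export
deviation_from_background <- function(background, cv_report, proteins) {
  cfg <- cv_report$cfg
  features <- composition_and_length(proteins)
  arr <- count_array(proteins, names(background), cfg$n_range)
  sc <- score_cells(background, features, arr, cfg)
  out <- expand.grid(residue = names(background), n = cfg$n_range,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$ratio <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    a <- out$residue[i]; jn <- as.character(out$n[i])
    if (isTRUE(sc$predicted[a, jn] > 0)) {
      out$ratio[i] <- sc$observed[a, jn] / sc$predicted[a, jn]
      s <- cv_report$scores[, a, jn]
      s <- s[is.finite(s)]
      if (length(s) >= 2L) {
        out$p[i] <- empirical_pvalue(s, reference = out$ratio[i],
                                     sided = "two")
      }
    }
  }
  out$holm_p <- NA_real_
  for (a in unique(out$residue)) {
    sel <- out$residue == a
    out$holm_p[sel] <- holm_adjust(out$p[sel])
  }
  out
}

#' Repeat enrichment in signal peptides versus mature sequences
#'
#' Tests, per residue and repeat length, whether whole proteins (including
#' the signal peptide) carry more repeats than their mature parts, relative
#' to a background model trained on mature sequences of the same protein
#' class. Both pooled observed/predicted ratios are computed against the
#' same background; their difference is reported in units of the model
#' standard deviation (the cross-validation score SD). The one-sided
#' empirical p-value compares the observed ratio difference to a null
#' distribution of pairwise differences between cross-validation scores,
#' and is Holm-adjusted across repeat lengths per residue.
#'
#' @param background A `zi_background` trained on the mature sequences.
#' @param cv_report [monte_carlo_cv()] report of the background on the
#'   mature sequences (null score distribution and model SD).
#' @param proteins Protein table with `signal_end` annotations (e.g. from
#'   [apply_cleavage_calls()] or the synthetic generator).
#' @param residues Residues to test (default: all residues with a trained
#'   background model).
#' @param min_observed Minimal pooled observed count on the mature side for
#'   a cell to be testable; emptier cells have no meaningful empirical
#'   ratio and are reported with `NA` p-values (the same support logic that
#'   excludes tryptophan from model validation).
#' @return A `data.frame`: `residue`, `n`, `ratio_whole`, `ratio_mature`,
#'   `z` (difference in model SDs), `p` (one-sided), `holm_p`.
#' @export
enrichment_test <- function(background, cv_report, proteins,
                            residues = names(background),
                            min_observed = 10) {
  if (length(residues) == 0L) {
    stop("empty background: no residue models available", call. = FALSE)
  }
  missing_bg <- setdiff(residues, names(background))
  if (length(missing_bg)) {
    stop("no background model for residue(s): ",
         paste(missing_bg, collapse = ", "), call. = FALSE)
  }
  cfg <- cv_report$cfg
  background <- background[residues]
  class(background) <- "zi_background"
  parts <- split_at_cleavage(proteins)
  feats_whole <- composition_and_length(proteins)
  feats_mature <- composition_and_length(parts$mature)
  arr_whole <- count_array(proteins, residues, cfg$n_range)
  arr_mature <- count_array(parts$mature, residues, cfg$n_range)
  sc_whole <- score_cells(background, feats_whole, arr_whole, cfg)
  sc_mature <- score_cells(background, feats_mature, arr_mature, cfg)
  out <- expand.grid(residue = residues, n = cfg$n_range,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$ratio_whole <- out$ratio_mature <- out$z <- out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    a <- out$residue[i]; jn <- as.character(out$n[i])
    pw <- sc_whole$predicted[a, jn]
    pm <- sc_mature$predicted[a, jn]
    if (!isTRUE(pw > 0) || !isTRUE(pm > 0) ||
        sc_mature$observed[a, jn] < min_observed) next
    rw <- sc_whole$observed[a, jn] / pw
    rm <- sc_mature$observed[a, jn] / pm
    out$ratio_whole[i] <- rw
    out$ratio_mature[i] <- rm
    d_obs <- rw - rm
    s <- cv_report$scores[, a, jn]
    s <- s[is.finite(s)]
    if (length(s) >= 2L) {
      sd_model <- stats::sd(s)
      out$z[i] <- if (d_obs == 0) 0 else d_obs / sd_model
      dm <- outer(s, s, "-")
      d_null <- dm[row(dm) != col(dm)]    # all ordered pairs r != q
      out$p[i] <- (sum(d_null >= d_obs) + 1) / (length(d_null) + 1)
    }
  }
  out$holm_p <- NA_real_
  for (a in unique(out$residue)) {
    sel <- out$residue == a
    out$holm_p[sel] <- holm_adjust(out$p[sel])
  }
  out
}
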