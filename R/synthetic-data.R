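#' Configuration of the synthetic proteome generator
#'
#' Describes a proteome with the statistical structure the background
#' models assume: log-normal protein lengths, per-protein compositional
#' variation around a base composition (Dirichlet draw), and a zero-inflated
#' homopolymer-run injection process. Per protein and residue, an injection
#' channel opens with probability `inject_prob`; when open, a Poisson number
#' of runs is injected whose mean scales with protein length and the
#' protein's frequency of that residue. Run lengths follow a bimodal law: a
#' bulk of doublets and triplets plus an expanded component centred well
#' beyond the local-dependency range. The scaling ties repeat abundance to
#' length and composition — the multivariate dependence the regression
#' models must capture — the closed channel produces the large excess of
#' repeat-free proteins (zero inflation), and the expanded component
#' produces maximal runs far beyond what local sequence statistics
#' predict.
#'
#' Optionally, a fraction of proteins receives an N-terminal
#' signal-peptide-like segment (charged start, hydrophobic core, polar end)
#' with a controllable leucine-run effect size: with probability
#' `signal_leu_effect` a leucine run of length at least 5 is embedded in the
#' hydrophobic core.
#'
#' @param n_proteins Number of proteins.
#' @param length_meanlog,length_sdlog Log-normal length law (default:
#'   median 330 residues, sdlog 0.45).
#' @param min_length Lower truncation of the length law.
#' @param base_freq Base residue composition (named, sums to 1).
#' @param dirichlet_conc Concentration of the per-protein Dirichlet
#'   composition draw (larger = less variation).
#' @param inject_prob Per-(protein, residue) probability that the run
#'   injection channel is open (zero-inflation control); scalar or named
#'   per-residue vector.
#' @param inject_mean Poisson mean of injected runs at the reference length
#'   and base composition.
#' @param inject_ref_length Reference length for the injection-mean scaling.
#' @param run_tail Tail parameter rho in (0, 1) of the bulk component:
#'   bulk injected runs are doublets or triplets, length `2` with
#'   probability `1 - rho` and `3` with probability `rho`.
#' @param long_frac Weight of the expanded-run component: with this
#'   probability an injected run is drawn as `long_min + Poisson(long_mean)`
#'   instead of from the bulk. The resulting bimodal length law has a
#'   continuation probability that rises towards the expanded length scale
#'   before decaying — the signature of slippage-driven repeat expansion —
#'   and is exactly the regime in which sequence models fitted to local
#'   tuple statistics under-predict long runs at every order.
#' @param long_min,long_mean Minimum length and Poisson mean of the
#'   expanded-run component (default: lengths 5 + Poisson(1), so expanded
#'   runs centre on 5-7 residues).
#' @param signal_frac Fraction of proteins receiving a signal peptide.
#' @param signal_len_mean,signal_len_sd Normal law of the signal length,
#'   truncated to `[15, 35]`.
#' @param signal_leu_effect Effect size delta: probability that a signal
#'   peptide carries an embedded leucine run of length >= 5.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 5000L,
                             length_meanlog = log(330), length_sdlog = 0.45,
                             min_length = 30L,
                             base_freq = AA_BASE_FREQ,
                             dirichlet_conc = 100,
                             inject_prob = 0.15,
                             inject_mean = 2,
                             inject_ref_length = 300,
                             run_tail = 0.55,
                             long_frac = 0.25,
                             long_min = 5L,
                             long_mean = 1,
                             signal_frac = 0,
                             signal_len_mean = 22, signal_len_sd = 4,
                             signal_leu_effect = 0) {
  stopifnot(abs(sum(base_freq) - 1) < 1e-6, all(base_freq > 0),
            run_tail > 0, run_tail < 1,
            long_frac >= 0, long_frac <= 1, long_min >= 2, long_mean >= 0,
            all(inject_prob >= 0), all(inject_prob <= 1),
            signal_frac >= 0, signal_frac <= 1,
            signal_leu_effect >= 0, signal_leu_effect <= 1)
  pi_a <- rep_len(inject_prob, length(AA_STANDARD))
  if (!is.null(names(inject_prob))) {
    pi_a <- inject_prob[AA_STANDARD]
    pi_a[is.na(pi_a)] <- 0
  }
  names(pi_a) <- AA_STANDARD
  structure(list(n_proteins = as.integer(n_proteins),
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 min_length = as.integer(min_length),
                 base_freq = base_freq[AA_STANDARD],
                 dirichlet_conc = dirichlet_conc,
                 inject_prob = pi_a, inject_mean = inject_mean,
                 inject_ref_length = inject_ref_length,
                 run_tail = run_tail, long_frac = long_frac,
                 long_min = as.integer(long_min), long_mean = long_mean,
                 signal_frac = signal_frac,
                 signal_len_mean = signal_len_mean,
                 signal_len_sd = signal_len_sd,
                 signal_leu_effect = signal_leu_effect),
            class = "synthetic_config")
}

# P(injected run length >= n) under the bulk + expanded mixture
run_tail_prob <- function(cfg, n) {
  stopifnot(n >= 2)
  bulk <- if (n <= 2) 1 else if (n == 3) cfg$run_tail else 0
  (1 - cfg$long_frac) * bulk +
    cfg$long_frac * stats::ppois(n - cfg$long_min - 1, cfg$long_mean,
                                 lower.tail = FALSE)
}

# counter-based per-protein seed: regenerating protein i alone is stable
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 100000) * 100003 + i * 7919) %%
    2147483629L
}

# place k non-overlapping runs of given lengths uniformly in 1..l;
# returns data.frame(start, length) of the placements that fit
place_runs <- function(l, lengths, occupied, max_tries = 50L) {
  placed <- data.frame(start = integer(0), length = integer(0))
  skipped <- 0L
  for (len in lengths) {
    if (len > l) { skipped <- skipped + 1L; next }
    done <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(l - len + 1L, 1L)
      span <- s:(s + len - 1L)
      if (!any(occupied[span])) {
        occupied[span] <- TRUE
        placed <- rbind(placed, data.frame(start = s, length = len))
        done <- TRUE
        break
      }
    }
    if (!done) skipped <- skipped + 1L
  }
  list(placed = placed, occupied = occupied, skipped = skipped)
}

#' Generate a synthetic proteome with ground truth
#'
#' Draws a seeded proteome under a [synthetic_config()]: per protein, a
#' Dirichlet composition around the base frequencies, an i.i.d. sequence of
#' log-normal length, and injected homopolymer runs that overwrite
#' non-overlapping positions (overwriting keeps the length law exact;
#' overlapping proposals are resampled and, if repeatedly infeasible,
#' skipped and logged). Each protein derives its own RNG stream from the
#' master seed, so regeneration is stable. When `signal_frac > 0`, signal
#' peptides are attached via [attach_signal_peptides()].
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer master seed.
#' @return A list: `proteins` (protein table) and `truth` (list with the
#'   per-protein `composition` matrix, the `injections` table of residue /
#'   start / length, the number of `skipped` infeasible injections, the
#'   `signal` table when signal peptides were attached, and the config).
#' @export
generate_proteome <- function(cfg = synthetic_config(), seed = 1) {
  np <- cfg$n_proteins
  seqs <- character(np)
  comp <- matrix(0, np, 20, dimnames = list(NULL, AA_STANDARD))
  inj <- vector("list", np)
  skipped <- 0L
  base <- cfg$base_freq
  for (i in seq_len(np)) {
    set.seed(derive_seed(seed, i))
    l <- max(cfg$min_length,
             round(stats::rlnorm(1, cfg$length_meanlog, cfg$length_sdlog)))
    g <- stats::rgamma(20, shape = cfg$dirichlet_conc * base)
    f <- g / sum(g)
    comp[i, ] <- f
    codes <- sample.int(20, l, replace = TRUE, prob = f)
    occupied <- rep(FALSE, l)
    rows <- NULL
    for (a in seq_len(20)) {
      if (cfg$inject_prob[a] <= 0) next
      if (stats::runif(1) > cfg$inject_prob[a]) next
      lam <- cfg$inject_mean * (l / cfg$inject_ref_length) * (f[a] / base[a])
      k <- stats::rpois(1, lam)
      if (k == 0) next
      expanded <- stats::runif(k) < cfg$long_frac
      lens <- ifelse(expanded,
                     cfg$long_min + stats::rpois(k, cfg$long_mean),
                     2L + (stats::runif(k) < cfg$run_tail))
      pl <- place_runs(l, lens, occupied)
      occupied <- pl$occupied
      skipped <- skipped + pl$skipped
      if (nrow(pl$placed)) {
        for (r in seq_len(nrow(pl$placed))) {
          span <- pl$placed$start[r]:(pl$placed$start[r] +
                                        pl$placed$length[r] - 1L)
          codes[span] <- a
        }
        pl$placed$residue <- AA_STANDARD[a]
        pl$placed$protein <- i
        rows <- rbind(rows, pl$placed)
      }
    }
    inj[[i]] <- rows
    seqs[i] <- paste(AA_STANDARD[codes], collapse = "")
  }
  injections <- do.call(rbind, inj[!vapply(inj, is.null, logical(1))])
  if (is.null(injections)) {
    injections <- data.frame(start = integer(0), length = integer(0),
                             residue = character(0), protein = integer(0))
  }
  proteins <- protein_table(sprintf("sp%05d", seq_len(np)), seqs)
  truth <- list(composition = comp, injections = injections,
                skipped = skipped, config = cfg, seed = seed)
  if (cfg$signal_frac > 0) {
    sig <- attach_signal_peptides(proteins, cfg, seed = derive_seed(seed, 0L))
    proteins <- sig$proteins
    truth$signal <- sig$truth
  }
  list(proteins = proteins, truth = truth)
}

# signal-peptide composition blocks
SIGNAL_CORE_FREQ <- c(
  A = 0.18, C = 0.01, D = 0.001, E = 0.001, F = 0.09, G = 0.05, H = 0.005,
  I = 0.10, K = 0.001, L = 0.30, M = 0.01, N = 0.005, P = 0.02, Q = 0.005,
  R = 0.001, S = 0.05, T = 0.04, V = 0.13, W = 0.01, Y = 0.01)
SIGNAL_CORE_FREQ <- SIGNAL_CORE_FREQ / sum(SIGNAL_CORE_FREQ)

#' Attach synthetic signal peptides to a proteome
#'
#' Prepends to a random subset of proteins an N-terminal signal-peptide-like
#' segment: an initiator methionine with a short positively charged start,
#' a hydrophobic core enriched in A/L/I/V/F, and a short polar stretch
#' before the cleavage site. With probability `signal_leu_effect` a leucine
#' run of length at least 5 overwrites part of the core. The cleavage
#' boundary is recorded in `signal_end` and in the returned ground truth.
#' Prepending (rather than overwriting) leaves the mature sequence exactly
#' as generated, so backgrounds trained on mature parts see the unmodified
#' generator law.
#'
#' @param proteins Protein table.
#' @param cfg A [synthetic_config()] with `signal_frac > 0`.
#' @param seed Integer seed.
#' @return A list: `proteins` (with prepended segments and `signal_end`
#'   set) and `truth` (`data.frame` of protein id, signal length, and the
#'   embedded leucine-run length, 0 when none).
#' @export
attach_signal_peptides <- function(proteins, cfg, seed = 1) {
  stopifnot(cfg$signal_frac > 0)
  np <- nrow(proteins)
  n_sig <- round(cfg$signal_frac * np)
  set.seed(as.integer(seed))
  which_sig <- sort(sample.int(np, n_sig))
  truth <- data.frame(id = character(0), signal_length = integer(0),
                      leu_run = integer(0))
  for (i in which_sig) {
    len <- round(stats::rnorm(1, cfg$signal_len_mean, cfg$signal_len_sd))
    len <- min(35L, max(15L, len))
    n_len <- sample(2:4, 1)              # charged start (after Met)
    c_len <- 3L                          # polar pre-cleavage stretch
    h_len <- len - 1L - n_len - c_len    # hydrophobic core
    n_part <- sample(c("K", "R", "N", "S"), n_len, replace = TRUE,
                     prob = c(0.4, 0.4, 0.1, 0.1))
    h_part <- sample(AA_STANDARD, h_len, replace = TRUE,
                     prob = SIGNAL_CORE_FREQ)
    leu_run <- 0L
    if (stats::runif(1) < cfg$signal_leu_effect) {
      leu_run <- min(h_len, 5L + stats::rgeom(1, 0.5))
      if (leu_run >= 5L) {
        s <- sample.int(h_len - leu_run + 1L, 1L)
        h_part[s:(s + leu_run - 1L)] <- "L"
      } else {
        leu_run <- 0L
      }
    }
    c_part <- sample(c("A", "S", "G"), c_len, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
    segment <- paste(c("M", n_part, h_part, c_part), collapse = "")
    proteins$sequence[i] <- paste0(segment, proteins$sequence[i])
    proteins$length[i] <- nchar(proteins$sequence[i])
    proteins$signal_end[i] <- as.integer(len)
    truth <- rbind(truth, data.frame(id = proteins$id[i],
                                     signal_length = len,
                                     leu_run = leu_run))
  }
  list(proteins = proteins, truth = truth)
}

#' Ground-truth predictor calls for a synthetic proteome
#'
#' Emits the dual-predictor table (neural-network-like and HMM-like rows)
#' for the proteins carrying a synthetic signal peptide, with agreeing
#' cleavage sites and scores satisfying the acceptance rule, so the
#' synthetic data can exercise the prediction-combination path.
#'
#' @param proteins Protein table with `signal_end` set for signal-bearing
#'   proteins.
#' @param seed Integer seed for the score jitter.
#' @return A `data.frame` in the [read_signal_predictions()] schema.
#' @export
make_signal_calls <- function(proteins, seed = 1) {
  set.seed(as.integer(seed))
  has <- which(!is.na(proteins$signal_end))
  if (!length(has)) {
    return(data.frame(protein_id = character(0), method = character(0),
                      score = numeric(0), threshold = numeric(0),
                      cleavage_pos = integer(0)))
  }
  nn <- data.frame(protein_id = proteins$id[has], method = "nn",
                   score = round(0.5 * (1 + stats::runif(length(has))), 3),
                   threshold = 0.5,
                   cleavage_pos = proteins$signal_end[has],
                   stringsAsFactors = FALSE)
  hm <- nn
  hm$method <- "hmm"
  hm$score <- round(0.5 * (0.6 + 0.8 * stats::runif(length(has))), 3)
  rbind(nn, hm)
}
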