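# log-composition guard: eps = 1/(2l) so that log(f + eps) is finite for
# proteins lacking the residue, shrinking with protein length
composition_eps <- function(l) 1 / (2 * l)

# stage-1 covariate matrix for one residue: (log l, log(f_a + eps))
stage1_covariates <- function(l, f_a) {
  cbind(log_l = log(l), log_f = log(f_a + composition_eps(l)))
}

# stage-2 covariate matrix: (log n, log l, log(f_a + eps))
stage2_covariates <- function(n, l, f_a) {
  cbind(log_n = log(n), log_l = log(l), log_f = log(f_a + composition_eps(l)))
}

#' Fit the logistic presence gate
#'
#' Maximum-likelihood logistic regression of the probability that a protein
#' has at least one repeat of a given residue and length, on covariates
#' (typically log length and log composition). One fit per (residue,
#' repeat-length) cell; this stage absorbs the many proteins with zero
#' repeats (the zero inflation).
#'
#' @param x Covariate matrix (rows = proteins), e.g. from the internal
#'   stage-1 construction `(log l, log(f_a + eps))`.
#' @param labels 0/1 vector: protein has at least one repeat.
#' @param cell Optional label (e.g. `"L,n=5"`) used in error messages.
#' @return Object of class `logistic_stage` with elements `coefficients`
#'   (intercept first) and `prevalence`.
#' @export
fit_presence_stage <- function(x, labels, cell = NULL) {
  x <- as.matrix(x)
  labels <- as.numeric(labels)
  stopifnot(nrow(x) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("single-class presence data",
         if (!is.null(cell)) paste0(" in cell ", cell), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(
    stats::glm.fit(X, labels, family = stats::binomial(),
                   control = stats::glm.control(maxit = 50)))
  beta <- stats::coef(fit)
  beta[is.na(beta)] <- 0      # aliased (constant) covariates drop out
  structure(list(coefficients = beta,
                 prevalence = mean(labels)),
            class = "logistic_stage")
}

#' @export
predict.logistic_stage <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata))
  as.numeric(stats::plogis(X %*% object$coefficients))
}

#' Select the balanced classification threshold
#'
#' Chooses the gate threshold that balances positive and negative prediction
#' errors: among candidate thresholds (the observed probabilities), the one
#' minimising `|false positives - false negatives|` is returned, ties broken
#' by the smallest such threshold. Predictions are positive when the
#' probability is greater than or equal to the threshold.
#'
#' @param probabilities Fitted presence probabilities.
#' @param labels Aligned 0/1 labels.
#' @return The selected threshold (numeric scalar).
#' @export
select_gate_threshold <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  labels <- as.numeric(labels)
  ord <- order(probabilities)
  p_s <- probabilities[ord]
  lab_s <- labels[ord]
  first <- !duplicated(p_s)
  cand <- p_s[first]
  # at threshold t: FP = negatives with p >= t, FN = positives with p < t;
  # cumulative counts strictly below each candidate give both in O(n log n)
  neg_below <- c(0, cumsum(lab_s == 0))[which(first)]
  pos_below <- c(0, cumsum(lab_s == 1))[which(first)]
  fp <- sum(labels == 0) - neg_below
  fn <- pos_below
  imbalance <- abs(fp - fn)
  cand[which.min(imbalance)]   # which.min takes the first (smallest t) tie
}

# full polynomial basis of total degree <= 3 in 3 covariates (20 terms)
poly_basis_exponents <- function(degree = 3L, nvar = 3L) {
  grid <- expand.grid(rep(list(0:degree), nvar))
  grid <- grid[rowSums(grid) <= degree, , drop = FALSE]
  grid <- grid[order(rowSums(grid), grid[, 3], grid[, 2], grid[, 1]), ,
               drop = FALSE]
  as.matrix(grid)
}

poly_design <- function(x, exponents) {
  out <- matrix(1, nrow(x), nrow(exponents))
  for (j in seq_len(nrow(exponents))) {
    for (v in seq_len(ncol(exponents))) {
      e <- exponents[j, v]
      if (e > 0) out[, j] <- out[, j] * x[, v]^e
    }
  }
  colnames(out) <- apply(exponents, 1, function(e) {
    if (all(e == 0)) return("1")
    paste0(mapply(function(v, k) if (k == 0) "" else
      if (k == 1) v else paste0(v, "^", k),
      c("x1", "x2", "x3"), e, USE.NAMES = FALSE), collapse = "")
  })
  out
}

#' Fit the polynomial count stage
#'
#' Least-squares fit of the conditional (log) repeat count on a fixed
#' polynomial basis of total degree 3 in the three log-scale covariates
#' (repeat length, protein length, residue composition); the basis (20
#' terms) is identical across residues.
#'
#' @param x Covariate matrix with three columns `(log n, log l, log f_a)`.
#' @param y Response vector (log cumulative counts).
#' @param degree Total polynomial degree (default 3).
#' @return Object of class `poly_stage` with `coefficients` and the basis
#'   `exponents`.
#' @export
fit_polynomial_stage <- function(x, y, degree = 3L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(ncol(x) == 3L, nrow(x) == length(y), all(is.finite(y)))
  expo <- poly_basis_exponents(degree, 3L)
  if (nrow(x) <= nrow(expo)) {
    stop("need more observations (", nrow(x), ") than basis terms (",
         nrow(expo), ")", call. = FALSE)
  }
  D <- poly_design(x, expo)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[seq(qrD$rank + 1L, ncol(D))]]
    stop("rank-deficient polynomial design; collinear terms: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrD, y)
  structure(list(coefficients = coefs, exponents = expo, degree = degree,
                 n_params = length(coefs)),
            class = "poly_stage")
}

#' @export
predict.poly_stage <- function(object, newdata, ...) {
  D <- poly_design(as.matrix(newdata), object$exponents)
  as.numeric(D %*% object$coefficients)
}

# assemble the per-residue two-stage model; stage1 is a list over repeat
# lengths (coefficients + threshold, or a degenerate marker when training
# data had a single class), stage2 an rvm_stage or poly_stage
zi_model <- function(residue, n_range, stage1, stage2, kind, meta = list()) {
  structure(list(residue = residue, n_range = as.integer(n_range),
                 stage1 = stage1, stage2 = stage2, kind = kind, meta = meta),
            class = "zi_model")
}

#' @export
print.zi_model <- function(x, ...) {
  cat(sprintf("Zero-inflated %s model for residue %s (n = %s; %d parameters)\n",
              toupper(x$kind), x$residue,
              paste(range(x$n_range), collapse = ".."),
              zi_n_params(x)))
  invisible(x)
}

# total retained parameter count: gate coefficients and thresholds plus the
# count-stage weights
zi_n_params <- function(model) {
  s1 <- sum(vapply(model$stage1, function(s) {
    if (is.null(s$gate)) 0L else length(s$gate$coefficients) + 1L
  }, integer(1)))
  s1 + model$stage2$n_params
}

#' Expected repeat count from a zero-inflated model
#'
#' Two-stage prediction for one repeat length: the logistic gate yields the
#' presence probability; proteins at or above the gate threshold receive the
#' exponentiated count-stage prediction, all others zero (hard gate). With
#' `soft = TRUE` the gate instead multiplies the conditional prediction by
#' the presence probability.
#'
#' @param model A `zi_model` (one residue), e.g. from [train_background()].
#' @param features Feature table from [composition_and_length()] (columns
#'   `l` and `f_<residue>`), one row per protein.
#' @param n Repeat length; must lie in the model's trained range.
#' @param soft Use the soft mixture `p * E[c | c > 0]` instead of the hard
#'   gate.
#' @return Numeric vector of expected cumulative counts (>= 0), one per row
#'   of `features`.
#' @export
predict_expected_count <- function(model, features, n, soft = FALSE) {
  if (!n %in% model$n_range) {
    stop("repeat length ", n, " outside the trained range ",
         paste(range(model$n_range), collapse = ".."), call. = FALSE)
  }
  l <- features$l
  f_a <- features[[paste0("f_", model$residue)]]
  s1 <- model$stage1[[as.character(n)]]
  if (identical(s1$degenerate, "none")) {
    return(numeric(length(l)))           # no repeat-containing protein seen
  }
  if (identical(s1$degenerate, "all")) {
    p1 <- rep(1, length(l))
    open <- rep(TRUE, length(l))
  } else {
    p1 <- predict(s1$gate, stage1_covariates(l, f_a))
    open <- p1 >= s1$threshold
  }
  logc <- predict(model$stage2, stage2_covariates(rep(n, length(l)), l, f_a))
  sm <- model$meta$smear[as.character(n)]
  if (is.null(sm) || !is.finite(sm)) sm <- 1
  cnt <- exp(pmin(logc, 30)) * sm
  if (soft) p1 * cnt else ifelse(open, cnt, 0)
}
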