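# Evaluation statistics: overlap scores, regression, Bland-Altman,
# cutoff derivation, contingency agreement, cross-validation folds.

#' Segmentation overlap scores
#'
#' Dice, recall and precision from voxel counts:
#' `dice = 2 TP / (2 TP + FP + FN)`, `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)`. Two empty masks score Dice 1 by convention.
#'
#' @param pred,truth logical 3-D arrays on one grid.
#' @return A list of class `seg_scores` with `dice`, `recall`, `precision`.
#' @export
seg_scores <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth))
    stop("masks must share a grid", call. = FALSE)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(list(
    dice = dice,
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp)),
    class = "seg_scores")
}

#' Ordinary least-squares fit
#'
#' Simple linear regression of `y` on `x` with R^2 reported as the squared
#' Pearson correlation, as used to relate SPECT and planar quantities.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list of class `regression_fit` with `slope`, `intercept`,
#'   `r_squared`, `n`, `p_value` (slope t-test).
#' @export
linfit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant; slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a summary warning
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = unname(sm$r.squared),
                 n = length(x),
                 p_value = unname(sm$coefficients[2, 4])),
            class = "regression_fit")
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`: bias (mean difference), SD of the differences,
#' limits of agreement `bias +- 1.96 sd`, and a two-sided one-sample t-test
#' of the mean difference against zero as the test for systematic error.
#' Constant differences (sd = 0) yield degenerate limits, flagged.
#'
#' @param x,y paired numeric vectors, length >= 3 after removing
#'   non-finite pairs.
#' @return A list of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `p_systematic`, `n`, `degenerate`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must be paired (equal length)", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  d <- (x - y)[ok]
  if (length(d) < 3) stop("need at least 3 pairs", call. = FALSE)
  bias <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  p <- if (degenerate) {
    if (bias == 0) 1 else 0
  } else stats::t.test(d)$p.value
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 p_systematic = p, n = length(d), degenerate = degenerate),
            class = "bland_altman_result")
}

#' Map a planar washout cutoff to the SPECT scale
#'
#' Evaluates the regression of SPECT washout on planar washout at the planar
#' cutoff and rounds to the nearest integer percent (the granularity at
#' which such cutoffs are quoted clinically).
#'
#' @param fit a [linfit()] result for SPECT WR (y) on planar WR (x).
#' @param planar_cutoff planar cutoff, percent.
#' @param digits rounding digits (default 0, nearest integer percent).
#' @return The SPECT cutoff in percent; a zero-slope fit returns the
#'   intercept with attribute `degenerate = TRUE`.
#' @export
derive_spect_cutoff <- function(fit, planar_cutoff, digits = 0) {
  stopifnot(inherits(fit, "regression_fit"))
  val <- round(fit$slope * planar_cutoff + fit$intercept, digits)
  if (fit$slope == 0) attr(val, "degenerate") <- TRUE
  val
}

#' Normal/abnormal agreement table
#'
#' Cross-tabulates paired SPECT and planar washout rates against their
#' cutoffs. Boundary conventions follow the two axes' column headers
#' literally and asymmetrically: a SPECT value equal to its cutoff is
#' normal (`<= cutoff`), a planar value equal to its cutoff is abnormal
#' (`>= cutoff`). Pairs with an undefined member are excluded and counted.
#'
#' @param spect_wr,planar_wr paired washout rates, percent.
#' @param spect_cutoff,planar_cutoff cutoffs, percent.
#' @return A list of class `contingency_2x2`: `counts` (2x2 matrix, rows
#'   SPECT normal/abnormal, columns planar normal/abnormal), `percent`
#'   (cell percentages of the grand total), `n`, `n_excluded`,
#'   `percent_agreement`.
#' @export
agreement_table <- function(spect_wr, planar_wr, spect_cutoff,
                            planar_cutoff) {
  if (length(spect_wr) != length(planar_wr))
    stop("paired vectors required", call. = FALSE)
  ok <- is.finite(spect_wr) & is.finite(planar_wr)
  s_ab <- spect_wr[ok] > spect_cutoff    # SPECT: > cutoff is abnormal
  p_ab <- planar_wr[ok] >= planar_cutoff # planar: >= cutoff is abnormal
  counts <- matrix(c(sum(!s_ab & !p_ab), sum(!s_ab & p_ab),
                     sum(s_ab & !p_ab), sum(s_ab & p_ab)),
                   2, 2, byrow = TRUE,
                   dimnames = list(spect = c("normal", "abnormal"),
                                   planar = c("normal", "abnormal")))
  n <- sum(counts)
  structure(list(counts = counts,
                 percent = 100 * counts / n,
                 n = n, n_excluded = sum(!ok),
                 percent_agreement = 100 * (counts[1, 1] + counts[2, 2]) / n),
            class = "contingency_2x2")
}

#' Agreement from printed table counts
#'
#' Convenience constructor for a [agreement_table()]-style result directly
#' from the four cell counts `(a, b; c, d)` (rows SPECT normal/abnormal,
#' columns planar normal/abnormal).
#'
#' @param a,b,c,d cell counts.
#' @return A `contingency_2x2`.
#' @export
agreement_from_counts <- function(a, b, c, d) {
  counts <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE,
                   dimnames = list(spect = c("normal", "abnormal"),
                                   planar = c("normal", "abnormal")))
  n <- sum(counts)
  structure(list(counts = counts, percent = 100 * counts / n, n = n,
                 n_excluded = 0L,
                 percent_agreement = 100 * (a + d) / n),
            class = "contingency_2x2")
}

#' Random cross-validation folds
#'
#' Seeded random partition of study ids into `k` folds whose sizes differ by
#' at most one.
#'
#' @param study_ids vector of ids.
#' @param k number of folds (default 4), `k <= length(study_ids)`.
#' @param seed integer seed.
#' @return A list of class `fold_spec` with `k` and `assignment` (named
#'   integer vector, id -> fold).
#' @export
make_folds <- function(study_ids, k = 4L, seed = 0L) {
  n <- length(study_ids)
  if (k > n) stop("k must not exceed the number of studies", call. = FALSE)
  assignment <- with_seed(seed, {
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    sample(rep(seq_len(k), sizes))
  })
  names(assignment) <- as.character(study_ids)
  structure(list(k = as.integer(k), assignment = assignment),
            class = "fold_spec")
}
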