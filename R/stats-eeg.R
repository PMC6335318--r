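#' Benjamini-Hochberg FDR control
#'
#' Rejects all hypotheses with sorted p-value rank `i <= max{k : p(k) <=
#' k q / m}`. The rejection set is always a prefix of the sorted
#' p-values and grows monotonically in `q`.
#'
#' @param p vector of p-values in `[0, 1]` (`NA`s never rejected).
#' @param q target false discovery rate.
#' @return An object of class `fdr_result`: `p`, `rejected` (logical),
#'   `q`, `method = "BH"`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  rejected <- rep(FALSE, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m) {
    ord <- order(p[idx])
    ps <- p[idx][ord]
    k <- which(ps <= seq_len(m) * q / m)
    if (length(k)) rejected[idx[ord[seq_len(max(k))]]] <- TRUE
  }
  structure(list(p = p, rejected = rejected, q = q, method = "BH"),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> %d/%d rejected at q=%g (%s)\n",
              sum(x$rejected), length(x$p), x$q, x$method))
  invisible(x)
}

#' Paired t-tests of dispersion curves per centre frequency
#'
#' Two-sided paired t-test per centre frequency between two conditions'
#' per-subject dispersion curves, with BH-FDR across frequencies.
#' Frequencies with zero variance of the paired differences yield `NaN`
#' with a warning.
#'
#' @param x,y subjects x frequencies matrices (same dimensions), e.g.
#'   stacked `dispersion` vectors from [dispersion_curve()].
#' @param q FDR level.
#' @return List with `t`, `p` (per frequency), `fdr` (an `fdr_result`),
#'   and `mean_diff`.
#' @export
paired_t_per_frequency <- function(x, y, q = 0.05) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("x and y must have equal dimensions")
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 subjects")
  d <- x - y
  md <- colMeans(d)
  sdd <- apply(d, 2, stats::sd)
  if (any(sdd == 0))
    warning(sum(sdd == 0), " frequency(ies) with zero difference variance; t undefined there")
  tval <- md / (sdd / sqrt(n))
  tval[sdd == 0] <- NaN
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  list(t = tval, p = p, fdr = fdr_bh(p, q), mean_diff = md)
}

#' Balanced two-way crossed ANOVA
#'
#' Classical fixed-effects two-way ANOVA with interaction for a balanced
#' design (equal replicates per cell), computed from the closed-form
#' sums of squares. Replicates are typically subjects; they enter as
#' residual replicates, not as a factor, so the error degrees of freedom
#' are `ab(r - 1)` (e.g. 2 conditions x 60 electrodes x 5 subjects gives
#' df (1, 59, 59, 480)).
#'
#' @param y response vector.
#' @param a,b factor vectors (coerced) of the same length as `y`.
#' @return An object of class `anova_table`: a data.frame with rows
#'   A, B, A:B, Residuals and columns `ss`, `df`, `ms`, `F`, `p`.
#' @export
anova2_balanced <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  if (length(y) != length(a) || length(y) != length(b))
    stop("y, a, b must have equal length")
  tab <- table(a, b)
  r <- tab[1]
  if (any(tab != r)) stop("unbalanced design: equal cell counts required")
  na <- nlevels(a); nb <- nlevels(b); N <- length(y)
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ss_a <- nb * r * sum((ma - gm)^2)
  ss_b <- na * r * sum((mb - gm)^2)
  ss_ab <- r * sum((mab - outer(ma, rep(1, nb)) -
                      outer(rep(1, na), mb) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_e <- ss_tot - ss_a - ss_b - ss_ab
  df <- c(na - 1, nb - 1, (na - 1) * (nb - 1), na * nb * (r - 1))
  ss <- c(ss_a, ss_b, ss_ab, max(0, ss_e))
  ms <- ifelse(df > 0, ss / df, NA)
  mse <- ms[4]
  Fv <- if (df[4] > 0 && mse > 0) ms[1:3] / mse else rep(Inf, 3)
  Fv[ms[1:3] == 0] <- 0
  pv <- if (df[4] > 0) stats::pf(Fv, df[1:3], df[4], lower.tail = FALSE)
        else rep(NA_real_, 3)
  out <- data.frame(effect = c("A", "B", "A:B", "Residuals"),
                    ss = ss, df = df,
                    ms = c(ms[1:3], mse),
                    F = c(Fv, NA), p = c(pv, NA),
                    stringsAsFactors = FALSE)
  structure(out, class = c("anova_table", "data.frame"))
}

#' Absolute left-right differences per electrode pair
#'
#' `|left - right|` of a per-electrode band value for every symmetric
#' non-midline pair of the montage. Pairs with a missing member are
#' skipped.
#'
#' @param values named per-electrode values (square microvolts).
#' @param mont an `eeg_montage`.
#' @return Named vector (names `left-right`), with attribute
#'   `"amplifier"`.
#' @export
lr_abs_difference <- function(values, mont) {
  p <- mont$pairs
  have <- p$left %in% names(values) & p$right %in% names(values)
  if (any(!have))
    qc_log("lr", sum(!have), " pair(s) skipped (missing member)")
  p <- p[have, , drop = FALSE]
  if (!nrow(p)) stop("no complete electrode pairs")
  out <- abs(values[p$left] - values[p$right])
  names(out) <- paste(p$left, p$right, sep = "-")
  attr(out, "amplifier") <- p$amplifier
  out
}

#' Signed left-right differences per electrode pair
#'
#' @inheritParams lr_abs_difference
#' @return Named vector `left - right` with attribute `"amplifier"`.
#' @export
lr_signed_difference <- function(values, mont) {
  p <- mont$pairs
  have <- p$left %in% names(values) & p$right %in% names(values)
  p <- p[have, , drop = FALSE]
  if (!nrow(p)) stop("no complete electrode pairs")
  out <- values[p$left] - values[p$right]
  names(out) <- paste(p$left, p$right, sep = "-")
  attr(out, "amplifier") <- p$amplifier
  out
}

#' Per-pair condition x hemisphere ANOVAs
#'
#' For every symmetric electrode pair, a 2 (condition) x 2 (left/right)
#' ANOVA over subjects as replicates (df (1, 1, 1, 4(r-1))), with BH-FDR
#' across pairs applied separately per effect.
#'
#' @param left,right arrays subjects x pairs x conditions of band values
#'   (square microvolts); `dimnames[[2]]` name the pairs.
#' @param q FDR level.
#' @return List with `tables` (one `anova_table` per pair), `p` (pairs x
#'   effects matrix), `fdr` (list of `fdr_result` per effect).
#' @export
per_pair_anova <- function(left, right, q = 0.05) {
  stopifnot(all(dim(left) == dim(right)), length(dim(left)) == 3L)
  n_sub <- dim(left)[1]; n_pair <- dim(left)[2]; n_cond <- dim(left)[3]
  if (n_cond != 2L) stop("exactly two conditions required")
  pair_names <- dimnames(left)[[2]]
  if (is.null(pair_names)) pair_names <- paste0("pair", seq_len(n_pair))
  tables <- vector("list", n_pair); names(tables) <- pair_names
  pmat <- matrix(NA_real_, n_pair, 3,
                 dimnames = list(pair_names, c("condition", "electrode", "interaction")))
  for (k in seq_len(n_pair)) {
    y <- c(left[, k, 1], left[, k, 2], right[, k, 1], right[, k, 2])
    cond <- rep(rep(c("c1", "c2"), each = n_sub), 2)
    side <- rep(c("L", "R"), each = 2 * n_sub)
    tab <- anova2_balanced(y, cond, side)
    tables[[k]] <- tab
    pmat[k, ] <- tab$p[1:3]
  }
  fdr <- lapply(seq_len(3), function(j) fdr_bh(pmat[, j], q))
  names(fdr) <- colnames(pmat)
  list(tables = tables, p = pmat, fdr = fdr)
}

#' One-sample t-tests of signed left-right differences, by amplifier
#'
#' Per pair, a two-sided one-sample t-test of the subject-wise signed
#' left-minus-right band difference against zero; BH-FDR within each
#' amplifier group; group mean differences reported as the mean absolute
#' left-right difference over the group's pairs.
#'
#' @param diffs subjects x pairs matrix of signed left-right differences
#'   (square microvolts).
#' @param amplifier integer (1/2) per pair.
#' @param q FDR level.
#' @return List with `mean_diff` (per pair), `t`, `p`, `fdr` (list per
#'   amplifier), `group_mean_diff` (mean |difference| per amplifier).
#' @export
lr_onesample_t <- function(diffs, amplifier, q = 0.05) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 2L) stop("need at least 2 subjects")
  md <- colMeans(diffs)
  sdd <- apply(diffs, 2, stats::sd)
  if (any(sdd == 0)) warning("zero-variance pair(s); t undefined there")
  tval <- md / (sdd / sqrt(n))
  tval[sdd == 0] <- NaN
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  amps <- sort(unique(amplifier))
  fdr <- lapply(amps, function(a) fdr_bh(p[amplifier == a], q))
  names(fdr) <- paste0("amp", amps)
  gmd <- vapply(amps, function(a) mean(abs(md[amplifier == a])), numeric(1))
  names(gmd) <- paste0("amp", amps)
  list(mean_diff = md, t = tval, p = p, fdr = fdr, group_mean_diff = gmd)
}

#' Percentile bootstrap on paired differences
#'
#' Resamples subjects with replacement, takes the mean difference per
#' resample, and reports the percentile of zero in the bootstrap
#' distribution with a mid-rank convention for ties at zero (so
#' identical conditions give exactly 50%).
#'
#' @param x,y paired per-subject values.
#' @param B number of bootstrap resamples.
#' @param seed RNG seed.
#' @return An object of class `bootstrap_result`: `B`, `seed`,
#'   `statistic` (per-resample mean differences), `percentile_of_zero`
#'   (percent).
#' @export
percentile_bootstrap_diff <- function(x, y, B = 10000L, seed = 1L) {
  d <- x - y
  n <- length(d)
  if (n < 2L) stop("need at least 2 subjects")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
  stat <- rowMeans(matrix(d[idx], B, n))
  pct <- 100 * (sum(stat < 0) + 0.5 * sum(stat == 0)) / B
  structure(list(B = B, seed = seed, statistic = stat,
                 percentile_of_zero = pct),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> B=%d, percentile of zero = %.1f%%\n",
              x$B, x$percentile_of_zero))
  invisible(x)
}

#' Mean instantaneous head movement per run
#'
#' Instantaneous movement at volume `v` is the Euclidean norm of the
#' difference in the three translation parameters between volumes `v`
#' and `v - 1` (mm); rotations are not included. The run summary is the
#' mean over volumes.
#'
#' @param mp a [motion_params()].
#' @return Mean instantaneous movement, mm.
#' @export
movement_summary <- function(mp) {
  tr <- mp$params[, 1:3, drop = FALSE]
  if (nrow(tr) < 2L) stop("need at least 2 volumes")
  steps <- sqrt(rowSums(diff(tr)^2))
  mean(steps)
}
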