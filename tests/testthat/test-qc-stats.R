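brute_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(ks)) rej[ord[seq_len(max(ks))]] <- TRUE
  rej
}

test_that("BH-FDR matches its definition and p.adjust", {
  expect_false(any(fdr_bh(rep(1, 10))$rejected))
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04))$rejected))
  set.seed(13)
  for (i in 1:50) {
    m <- sample(3:40, 1)
    p <- runif(m)^sample(1:3, 1)
    r <- fdr_bh(p, 0.05)
    expect_identical(r$rejected, brute_bh(p, 0.05))
    expect_identical(r$rejected, p.adjust(p, "BH") <= 0.05)
  }
  # rejection set is a prefix of the sorted p-values, monotone in q
  p <- runif(30)
  r1 <- fdr_bh(p, 0.02)$rejected
  r2 <- fdr_bh(p, 0.10)$rejected
  expect_true(all(r2[r1]))
})

test_that("paired t per frequency matches t.test and handles degeneracy", {
  set.seed(14)
  x <- matrix(rnorm(5 * 8), 5, 8)
  expect_warning(r0 <- paired_t_per_frequency(x, x), "zero difference")
  expect_true(all(is.nan(r0$t)))
  y <- x + matrix(rnorm(5 * 8, sd = 0.5), 5, 8)
  r <- paired_t_per_frequency(x, y)
  for (j in c(1, 5, 8)) {
    tt <- t.test(x[, j], y[, j], paired = TRUE)
    expect_equal(unname(r$t[j]), unname(tt$statistic))
    expect_equal(unname(r$p[j]), tt$p.value)
  }
  d <- c(0.2, -0.1, 0.4, 0.0, 0.3)
  r2 <- paired_t_per_frequency(matrix(d, 5, 1), matrix(0, 5, 1))
  expect_equal(unname(r2$t[1]), mean(d) / (sd(d) / sqrt(5)))
})

test_that("balanced two-way ANOVA reproduces hand and model-fit results", {
  # all-constant input: zero SS and F
  y <- rep(3, 12)
  a <- rep(c("x", "y"), each = 6); b <- rep(c("u", "v", "w"), 4)
  tab <- anova2_balanced(y, a, b)
  expect_true(all(tab$ss[1:3] == 0))
  expect_true(all(tab$F[1:3] == 0))
  # 2x2 with 2 replicates, hand-computed sums of squares
  y2 <- c(1, 1, 1, 1, 2, 2, 1, 1)  # +1 for A=2,B=1
  a2 <- c(1, 1, 1, 1, 2, 2, 2, 2)
  b2 <- c(1, 1, 2, 2, 1, 1, 2, 2)
  # cell means: (1,1)=1 (1,2)=1 (2,1)=2 (2,2)=1; grand 1.25
  tab2 <- anova2_balanced(y2, a2, b2)
  expect_equal(tab2$ss, c(0.5, 0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(tab2$df, c(1, 1, 1, 4))
  expect_error(anova2_balanced(y2[-1], a2[-1], b2[-1]), "unbalanced")
})

test_that("ANOVA agrees with the projection-based linear-model oracle", {
  set.seed(15)
  for (i in 1:200) {
    na <- sample(2:4, 1); nb <- sample(2:5, 1); r <- sample(2:4, 1)
    a <- factor(rep(seq_len(na), each = nb * r))
    b <- factor(rep(rep(seq_len(nb), each = r), na))
    y <- rnorm(na * nb * r)
    tab <- anova2_balanced(y, a, b)
    or <- anova(lm(y ~ a * b))
    expect_equal(tab$ss, or$`Sum Sq`, tolerance = 1e-8)
    expect_equal(tab$df, or$Df)
    expect_equal(tab$F[1:3], or$`F value`[1:3], tolerance = 1e-8)
    expect_equal(tab$p[1:3], or$`Pr(>F)`[1:3], tolerance = 1e-8)
  }
})

test_that("the study design degrees of freedom arise by construction", {
  set.seed(16)
  # 2 conditions x 60 electrodes x 5 subjects
  tab <- anova2_balanced(rnorm(600), rep(1:2, each = 300),
                         rep(rep(1:60, each = 5), 2))
  expect_equal(tab$df, c(1, 59, 59, 480))
  # 2 conditions x 26 pairs x 5 subjects
  tab <- anova2_balanced(rnorm(260), rep(1:2, each = 130),
                         rep(rep(1:26, each = 5), 2))
  expect_equal(tab$df, c(1, 25, 25, 208))
  # 2 conditions x 2 hemispheres x 5 subjects
  tab <- anova2_balanced(rnorm(20), rep(1:2, each = 10),
                         rep(rep(1:2, each = 5), 2))
  expect_equal(tab$df, c(1, 1, 1, 16))
})

test_that("left-right differences follow the montage pairing", {
  mont <- tiny_montage()
  v <- setNames(rep(2, length(mont$labels)), mont$labels)
  expect_true(all(lr_abs_difference(v, mont) == 0))
  v["F3"] <- 2; v["F4"] <- 5
  d <- lr_abs_difference(v, mont)
  expect_equal(unname(d["F3-F4"]), 3)
  s <- lr_signed_difference(v, mont)
  expect_equal(unname(s["F3-F4"]), -3)
  expect_equal(attr(d, "amplifier"),
               mont$pairs$amplifier)
})

test_that("per-pair ANOVAs have df (1,1,1,16) and control type-I error", {
  set.seed(17)
  n_sub <- 5; n_pair <- 26
  left <- array(rnorm(n_sub * n_pair * 2), c(n_sub, n_pair, 2))
  right <- array(rnorm(n_sub * n_pair * 2), c(n_sub, n_pair, 2))
  res <- per_pair_anova(left, right)
  expect_equal(res$tables[[1]]$df, c(1, 1, 1, 16))
  expect_equal(dim(res$p), c(n_pair, 3L))
  # null simulation: FDR rejections rare under no effect
  reps <- 300
  any_rej <- logical(reps)
  for (i in seq_len(reps)) {
    l <- array(rnorm(n_sub * 6 * 2), c(n_sub, 6, 2))
    r <- array(rnorm(n_sub * 6 * 2), c(n_sub, 6, 2))
    pr <- per_pair_anova(l, r)
    any_rej[i] <- any(pr$fdr$condition$rejected)
  }
  # P(any false rejection) <= q under independence; binomial slack
  expect_lte(mean(any_rej), 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
})

test_that("one-sample left-right t-tests report group mean differences", {
  z <- matrix(0, 5, 4)
  r0 <- suppressWarnings(lr_onesample_t(z, c(1, 1, 2, 2)))
  expect_true(all(r0$mean_diff == 0))
  expect_false(any(sapply(r0$fdr, function(f) any(f$rejected))))
  d <- c(4, 5, 4.5, 5.5, 4.0)
  r <- lr_onesample_t(cbind(d, d), c(1, 2))
  tt <- t.test(d)
  expect_equal(unname(r$t[1]), unname(tt$statistic))
  expect_equal(unname(r$p[1]), tt$p.value)
  expect_equal(unname(r$group_mean_diff), c(mean(d), mean(d)))
})

test_that("the percentile bootstrap follows its tie and sign conventions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(percentile_bootstrap_diff(x, x, B = 500)$percentile_of_zero, 50)
  expect_equal(percentile_bootstrap_diff(x + 10, x, B = 500)$percentile_of_zero, 0)
  set.seed(99)
  y <- x + rnorm(5)
  r1 <- percentile_bootstrap_diff(y, x, B = 1000, seed = 4)
  r2 <- percentile_bootstrap_diff(y, x, B = 1000, seed = 4)
  expect_identical(r1$statistic, r2$statistic)
})

test_that("the bootstrap percentile matches its null sampling distribution", {
  # Oracle (40,000-rep simulation of the same statistic): with n = 5
  # standard-normal differences, P(percentile of zero in (2.5, 97.5)) =
  # 0.835 +/- 0.002 -- all-positive or all-negative samples alone (2 *
  # 2^-5 = 6.25%) already fall outside. The implementation must
  # reproduce that coverage, here within 3 binomial SEs of 500 reps.
  set.seed(18)
  reps <- 500
  inside <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(5); y <- rnorm(5)
    pct <- percentile_bootstrap_diff(x, y, B = 400, seed = i)$percentile_of_zero
    inside[i] <- pct > 2.5 && pct < 97.5
  }
  expect_gt(mean(inside), 0.835 - 0.05)
  expect_lt(mean(inside), 0.835 + 0.05)
})

test_that("movement summaries are translation-norm means", {
  mp <- motion_params(matrix(0.3, 10, 6))
  expect_equal(movement_summary(mp), 0)
  stepping <- motion_params(cbind(seq(0, 0.9, by = 0.1), 0, 0, 0, 0, 0))
  expect_equal(movement_summary(stepping), 0.1)
  set.seed(19)
  par6 <- matrix(rnorm(60), 10, 6)
  mp2 <- motion_params(par6)
  brute <- mean(sapply(2:10, function(v)
    sqrt(sum((par6[v, 1:3] - par6[v - 1, 1:3])^2))))
  expect_equal(movement_summary(mp2), brute)
})
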