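test_that("repeated-measures ANOVA matches the hand SS decomposition and aov", {
  x <- matrix(c(10, 12, 14, 11,
                11, 14, 15, 13,
                12, 15, 17, 14), ncol = 3L,
              dimnames = list(NULL, c("a", "b", "c")))
  res <- rm_anova(x)
  # explicit sums-of-squares oracle
  gm <- mean(x); n <- nrow(x); k <- ncol(x)
  ss_prot <- n * sum((colMeans(x) - gm)^2)
  ss_sub <- k * sum((rowMeans(x) - gm)^2)
  ss_err <- sum((x - gm)^2) - ss_prot - ss_sub
  f_oracle <- (ss_prot / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(res$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(unname(res$df), c(2, 6))

  # cross-check against aov with subject as error stratum
  df <- data.frame(y = as.vector(x),
                   protocol = factor(rep(colnames(x), each = n)),
                   subject = factor(rep(seq_len(n), k)))
  fit <- summary(stats::aov(y ~ protocol + Error(subject), data = df))
  tab <- fit[["Error: Within"]][[1L]]
  expect_equal(res$statistic, tab[["F value"]][1L], tolerance = 1e-10)
  expect_equal(res$p_value, tab[["Pr(>F)"]][1L], tolerance = 1e-10)

  # permuting subject order changes nothing
  expect_equal(rm_anova(x[c(3, 1, 4, 2), ])$statistic, res$statistic)

  # identical columns -> F = 0, p = 1
  same <- matrix(rep(c(1, 5, 9), 3L), ncol = 3L)
  expect_equal(rm_anova(same)$statistic, 0)
  expect_equal(rm_anova(same)$p_value, 1)
  expect_error(rm_anova(x[, 1, drop = FALSE]), "at least 2")
})

test_that("paired t with Holm matches base R and the step-down definition", {
  set.seed(10)
  x <- matrix(rnorm(30), ncol = 3L)
  x[, 2] <- x[, 2] + 1
  res <- paired_t_holm(x)
  for (r in res) {
    tt <- stats::t.test(x[, r$pair[1L]], x[, r$pair[2L]], paired = TRUE)
    expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)
    expect_gte(r$adjusted_p, r$p_value)
  }
  # Holm's step-down by hand: {0.01, 0.02, 0.2} -> {0.03, 0.04, 0.2}
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.2), "holm"),
               c(0.03, 0.04, 0.2))
  # a column against itself is degenerate with t = 0, p = 1
  same <- cbind(x[, 1], x[, 1])
  r0 <- paired_t_holm(same, pairs = list(c(1L, 2L)))[[1L]]
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_true(r0$degenerate)
})

test_that("Friedman statistic matches the brute-force ranking oracle", {
  x <- matrix(c(1, 2, 3, 2,
                2, 3, 1, 3,
                3, 1, 2, 1), ncol = 3L)
  res <- friedman_rm(x, exact = FALSE)
  # brute-force: rank each row, classical statistic (no ties present)
  rk <- t(apply(x, 1L, rank))
  rj <- colSums(rk)
  n <- nrow(x); k <- ncol(x)
  stat_oracle <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  expect_equal(res$statistic, stat_oracle, tolerance = 1e-12)
  # cross-check against base R on tie-free data
  base <- stats::friedman.test(x)
  expect_equal(res$statistic, unname(base$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, base$p.value, tolerance = 1e-12)

  # identical columns -> zero statistic
  expect_equal(friedman_rm(matrix(rep(1:4, 3L), ncol = 3L))$statistic, 0)
})

test_that("the exact Friedman path matches a 1e5-replicate permutation null", {
  set.seed(20)
  x <- matrix(c(2, 3, 1, 4,
                3, 4, 2, 4,
                1, 2, 2, 3), ncol = 3L)   # includes within-row ties
  res <- friedman_rm(x)                    # n = 4 -> exact path
  expect_match(res$method, "exact")
  p_mc <- friedman_mc_oracle(x, nrep = 1e5, seed = 7)
  se <- sqrt(res$p_value * (1 - res$p_value) / 1e5)
  expect_lt(abs(res$p_value - p_mc), 4 * se + 1e-6)
  # the chi-square path agrees with the exact one to first order
  approx <- friedman_rm(x, exact = FALSE)
  expect_equal(approx$statistic, res$statistic)
})

test_that("Wilcoxon signed-rank matches exact enumeration and base R", {
  d_x <- c(3.1, -0.7, 2.4, 1.8, -1.2, 0.9)
  x <- d_x; y <- rep(0, 6L)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$p_value, wilcoxon_enum_oracle(d_x), tolerance = 1e-12)
  base <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(res$statistic, unname(base$statistic))
  expect_equal(res$p_value, base$p.value, tolerance = 1e-12)

  # antisymmetry: swapping the pair flips the statistic, keeps the p
  swapped <- wilcoxon_signed_rank(y, x)
  n <- res$n_used
  expect_equal(swapped$statistic, n * (n + 1) / 2 - res$statistic)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)

  # zeros are dropped
  resz <- wilcoxon_signed_rank(c(x, 5), c(y, 5))
  expect_equal(resz$n_zeros, 1L)
  expect_equal(resz$p_value, res$p_value, tolerance = 1e-12)

  # tie-corrected normal path agrees with base R's continuity-corrected one
  set.seed(30)
  xt <- round(rnorm(40), 1); yt <- round(rnorm(40), 1)
  xt <- xt[xt != yt]; yt <- yt[seq_along(xt)]
  rest <- wilcoxon_signed_rank(xt, yt)
  baset <- suppressWarnings(stats::wilcox.test(xt, yt, paired = TRUE,
                                               exact = FALSE, correct = TRUE))
  expect_equal(rest$p_value, baset$p.value, tolerance = 1e-10)

  # all-zero differences flagged degenerate
  dz <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(dz$degenerate)
  expect_equal(dz$p_value, 1)

  # Holm family over the three pairwise comparisons
  m <- cbind(a = rnorm(12), b = rnorm(12) + 2, c = rnorm(12))
  wh <- wilcoxon_holm(m)
  expect_length(wh, 3L)
  for (r in wh) expect_gte(r$adjusted_p, r$p_value)
})

test_that("Cohen's kappa matches hand arithmetic and the printed scale", {
  perfect <- diag(c(10, 20, 30, 5))
  kp <- cohen_kappa(perfect)
  expect_equal(kp$kappa, 1)
  expect_identical(kp$label, "near-perfect")

  # hand oracle: [[20, 5], [10, 15]] -> p_o = 0.7, p_e = 0.5, kappa = 0.4
  tb <- matrix(c(20, 10, 5, 15), 2L, 2L)
  k2 <- cohen_kappa(tb)
  expect_equal(k2$p_o, 0.7)
  expect_equal(k2$p_e, 0.5)
  expect_equal(k2$kappa, 0.4)
  expect_identical(k2$label, "fair")

  # printed boundaries are closed above
  expect_identical(pocsrecon:::.kappa_label(0.60), "moderate")
  expect_identical(pocsrecon:::.kappa_label(0.63), "substantial")
  expect_identical(pocsrecon:::.kappa_label(0.80), "substantial")
  expect_identical(pocsrecon:::.kappa_label(0.81), "near-perfect")

  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2L)), "p_e = 1")
  expect_error(cohen_kappa(matrix(1:6, 2L, 3L)), "square")
})

test_that("Holm controls the family-wise error under the global null", {
  set.seed(40)
  nrep <- 300L
  fwer_hits <- 0L
  for (b in seq_len(nrep)) {
    m <- matrix(rnorm(20 * 3), ncol = 3L)
    res <- wilcoxon_holm(m)
    if (any(vapply(res, `[[`, numeric(1), "adjusted_p") < 0.05))
      fwer_hits <- fwer_hits + 1L
  }
  # true FWER <= 0.05; allow 3 binomial SEs of Monte-Carlo slack
  expect_lt(fwer_hits / nrep, 0.09)
})
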