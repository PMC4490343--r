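test_that("Mauchly's test matches the base mlm implementation", {
  set.seed(1)
  Y <- matrix(rnorm(20 * 4), 20, 4); Y[, 2] <- Y[, 2] * 2
  mt <- mauchly_test(rm_dataset(Y))
  ref <- stats::mauchly.test(stats::lm(Y ~ 1), X = ~1)
  expect_equal(mt$W, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mt$p, ref$p.value, tolerance = 1e-10)
  expect_identical(mt$df, 5)  # k(k-1)/2 - 1

  # k = 2: sphericity holds trivially
  m2 <- mauchly_test(rm_dataset(Y[, 1:2]))
  expect_identical(m2$W, 1); expect_identical(m2$p, 1)
  expect_error(mauchly_test(rm_dataset(Y[1:3, ])), "singular|subjects")
})

test_that("Mauchly's test is calibrated under sphericity and detects violations", {
  set.seed(31)
  rej <- 0; B <- 2000
  for (i in seq_len(B)) {
    Y <- matrix(rnorm(20 * 4), 20, 4) + rnorm(20)  # compound symmetry
    rej <- rej + (mauchly_test(rm_dataset(Y))$p < 0.05)
  }
  expect_gt(rej / B, 0.03); expect_lt(rej / B, 0.07)

  set.seed(32)
  pow <- 0; B2 <- 300
  for (i in seq_len(B2)) {
    Y <- matrix(rnorm(20 * 4), 20, 4); Y[, 2] <- Y[, 2] * 5  # variance x25
    pow <- pow + (mauchly_test(rm_dataset(Y))$p < 0.05)
  }
  expect_gte(pow / B2, 0.8)
})

test_that("the ANOVA decomposition matches car/anova.mlm and hand arithmetic", {
  set.seed(2)
  Y <- matrix(rnorm(12 * 4), 12, 4) + rep(c(0, 0.5, 0.2, 0), each = 12)
  a <- rm_anova(rm_dataset(Y), force_gg = TRUE)
  s <- summary(car::Anova(stats::lm(Y ~ 1), idata = data.frame(cond = factor(1:4)),
                          idesign = ~cond), multivariate = FALSE)
  expect_equal(a$F, unname(s$univariate.tests[2, "F value"]), tolerance = 1e-8)
  expect_equal(a$epsilon, unname(s$pval.adjustments[1, "GG eps"]), tolerance = 1e-8)
  expect_equal(a$p, unname(s$pval.adjustments[1, "Pr(>F[GG])"]), tolerance = 1e-8)

  # 3 x 3 integer table: spreadsheet-style decomposition
  Yi <- rbind(c(2, 4, 6), c(1, 5, 6), c(3, 6, 9))
  grand <- mean(Yi)
  ss_cond <- 3 * sum((colMeans(Yi) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(Yi) - grand)^2)
  ss_err <- sum((Yi - grand)^2) - ss_cond - ss_subj
  F_hand <- (ss_cond / 2) / (ss_err / 4)
  ai <- rm_anova(rm_dataset(Yi))
  expect_equal(ai$F, F_hand, tolerance = 1e-12)
  expect_equal(ai$p_uncorrected, pf(F_hand, 2, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  # degenerate cases
  a0 <- rm_anova(rm_dataset(matrix(5, 6, 3)))
  expect_identical(a0$F, 0); expect_identical(a0$p, 1)
  Yd <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)  # pure condition effect
  ainf <- rm_anova(rm_dataset(Yd))
  expect_identical(ainf$F, Inf); expect_identical(ainf$p, 0)
})

test_that("ANOVA results are invariant to shifts and well relabeling", {
  set.seed(3)
  Y <- matrix(rnorm(10 * 4), 10, 4) %*% ar1_chol(4, 0.6)
  a1 <- rm_anova(rm_dataset(Y), force_gg = TRUE)
  a2 <- rm_anova(rm_dataset(Y + 7), force_gg = TRUE)
  a3 <- rm_anova(rm_dataset(Y[sample(10), ]), force_gg = TRUE)
  for (f in c("F", "epsilon", "p", "sphericity_p")) {
    expect_equal(a1[[f]], a2[[f]], tolerance = 1e-10)
    expect_equal(a1[[f]], a3[[f]], tolerance = 1e-10)
  }
  # epsilon bounds over random covariances
  for (i in 1:20) {
    k <- sample(3:6, 1)
    Yr <- matrix(rnorm(12 * k), 12, k) %*% ar1_chol(k, runif(1, 0, 0.9))
    eps <- rm_anova(rm_dataset(Yr), force_gg = TRUE)$epsilon
    expect_gte(eps, 1 / (k - 1) - 1e-10); expect_lte(eps, 1 + 1e-10)
  }
})

test_that("GG correction restores type-I control under AR(1) correlation", {
  L <- ar1_chol(5, 0.7)
  set.seed(41)
  rej_gg <- rej_unc <- 0; B <- 2000
  for (i in seq_len(B)) {
    Y <- matrix(rnorm(15 * 5), 15, 5) %*% L
    a <- rm_anova(rm_dataset(Y), force_gg = TRUE)
    rej_gg <- rej_gg + (a$p < 0.05)
    rej_unc <- rej_unc + (a$p_uncorrected < 0.05)
  }
  expect_gt(rej_gg / B, 0.03); expect_lt(rej_gg / B, 0.07)
  # the uncorrected test is anticonservative here; GG pulls it back down
  expect_gt(rej_unc / B, 0.055)
  expect_gt(rej_unc, rej_gg)
})

test_that("the conditional GG rule follows Mauchly's verdict", {
  set.seed(42)
  # spherical data: correction should usually stay off
  Y <- matrix(rnorm(20 * 4), 20, 4)
  a <- rm_anova(rm_dataset(Y))
  expect_identical(a$corrected, a$sphericity_p < 0.05)
  # grossly non-spherical data: correction kicks in
  Yn <- matrix(rnorm(20 * 4), 20, 4) %*% diag(c(1, 6, 1, 1))
  an <- rm_anova(rm_dataset(Yn))
  expect_true(an$corrected)
  expect_lt(an$sphericity_p, 0.05)
  expect_equal(an$df_effect, an$epsilon * 3, tolerance = 1e-10)
  expect_equal(an$df_error, an$epsilon * 3 * 19, tolerance = 1e-10)
})

test_that("Dunnett adjusted p-values match a direct Monte-Carlo oracle", {
  set.seed(5)
  Y <- matrix(rnorm(15 * 4), 15, 4); Y[, 3] <- Y[, 3] + 0.9
  colnames(Y) <- c("baseline", "a", "b", "c")
  dn <- dunnett_test(rm_dataset(Y))
  # oracle: simulate max |T| of the multivariate t directly
  D <- Y[, -1] - Y[, 1]
  R <- cor(D); df <- 14
  set.seed(6)
  Z <- mvtnorm::rmvnorm(2e5, sigma = R)
  Tm <- Z / sqrt(stats::rchisq(2e5, df) / df)
  maxT <- apply(abs(Tm), 1, max)
  for (j in 1:3) {
    p_mc <- mean(maxT >= abs(dn$table$t[j]))
    expect_equal(dn$table$p_adj[j], p_mc, tolerance = 0.012)
  }
  expect_true(all(dn$table$p_adj >= dn$table$p_raw - 1e-9))
})

test_that("Dunnett handles the all-equal case and is monotone in the shift", {
  Y <- cbind(baseline = c(1, 2, 3, 4, 5), c1 = c(1, 2, 3, 4, 5),
             c2 = c(1, 2, 3, 4, 5))
  dn <- dunnett_test(rm_dataset(Y))
  expect_true(all(dn$table$p_adj > 0.5))

  set.seed(7)
  noise <- matrix(rnorm(12 * 4, sd = 1), 12, 4)
  Ym <- cbind(0, 0.3, 0.8, 1.5) [rep(1, 12), ] + noise
  colnames(Ym) <- c("baseline", "lo", "mid", "hi")
  dm <- dunnett_test(rm_dataset(Ym))
  expect_true(all(diff(dm$table$p_adj) <= 1e-9))  # larger shift, smaller p
})

test_that("Dunnett controls the familywise error rate", {
  set.seed(51)
  fwe <- 0; B <- 2000
  for (i in seq_len(B)) {
    Y <- matrix(rnorm(20 * 4), 20, 4)
    fwe <- fwe + (min(dunnett_test(rm_dataset(Y))$table$p_adj) < 0.05)
  }
  expect_gte(fwe / B, 0.035); expect_lte(fwe / B, 0.065)
})

test_that("dataset validation catches incomplete or tiny designs", {
  expect_error(rm_dataset(matrix(c(1, NA, 3, 4, 5, 6), 3, 2)), "complete")
  expect_error(rm_dataset(matrix(1:4, 2, 2)), "wells")
  expect_error(rm_dataset(matrix(1:6, 6, 1)), "conditions")
  expect_error(rm_dataset(matrix(1:12, 4, 3), baseline = "zz"), "baseline")
})
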