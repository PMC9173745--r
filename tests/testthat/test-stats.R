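test_that("rm_anova matches the explicit sums-of-squares oracle (one within factor)", {
  # 4 subjects x 3 trials with additive subject and trial structure + residuals
  y <- rbind(c(10, 12, 14),
             c(11, 13, 16),
             c(9, 12, 13),
             c(12, 13, 15))
  d <- data.frame(subject = factor(rep(1:4, 3)),
                  trial = factor(rep(1:3, each = 4)),
                  y = as.vector(y))
  res <- rm_anova(d, "y", within = "trial")
  want <- oracle_rm_F(y)
  expect_equal(res$value[res$effect == "trial"], want$F, tolerance = 1e-8)
  expect_equal(res$df1[res$effect == "trial"], want$df1)
  expect_equal(res$df2[res$effect == "trial"], want$df2)
})

test_that("a 2-level within factor is trivially spherical: epsilon 1, uncorrected", {
  set.seed(51)
  d <- expand.grid(subject = factor(1:8), trial = factor(1:2))
  d$y <- rnorm(16)
  res <- rm_anova(d, "y", within = "trial")
  expect_equal(res$correction[res$effect == "trial"], "none")
  expect_equal(res$epsilon[res$effect == "trial"], 1)
})

test_that("constant response yields F = 0 for every effect", {
  d <- expand.grid(subject = factor(1:6), trial = factor(1:3))
  d$group <- factor(rep(c("a", "b"), 9)[as.integer(d$subject)])
  d$y <- 7
  res <- rm_anova(d, "y", within = "trial", between = "group")
  expect_true(all(res$value == 0))
  expect_true(all(res$p == 1))
})

test_that("Greenhouse-Geisser correction shrinks df and never lowers p", {
  set.seed(52)
  n <- 10; t <- 5
  # strongly non-spherical (one condition much noisier) with a real trial
  # effect, so the check sits in the rejection region where the correction
  # is conservative
  base <- rnorm(n)
  y <- cbind(base + rnorm(n, sd = 0.1),
             base + rnorm(n, sd = 0.1) + 2,
             base + rnorm(n, sd = 0.1) + 4,
             base + rnorm(n, sd = 0.1) + 6,
             rnorm(n, sd = 4) + 8)
  d <- data.frame(subject = factor(rep(1:n, t)),
                  trial = factor(rep(1:t, each = n)),
                  y = as.vector(y))
  always <- rm_anova(d, "y", within = "trial", sphericity_alpha = 1)
  never <- rm_anova(d, "y", within = "trial", sphericity_alpha = 0)
  a <- always[always$effect == "trial", ]
  u <- never[never$effect == "trial", ]
  expect_equal(a$correction, "greenhouse_geisser")
  expect_equal(u$correction, "none")
  expect_true(a$epsilon <= 1)
  expect_equal(a$df1, u$df1 * a$epsilon, tolerance = 1e-8)
  expect_equal(a$df2, u$df2 * a$epsilon, tolerance = 1e-8)
  expect_equal(a$value, u$value, tolerance = 1e-10)  # F itself unchanged
  expect_gte(a$p, u$p)
})

test_that("rm_anova names the unbalanced factor on missing cells", {
  d <- expand.grid(subject = factor(1:4), trial = factor(1:3))
  d$y <- rnorm(12)
  expect_error(rm_anova(d[-1, ], "y", within = "trial"),
               "missing cells.*trial")
})

test_that("Welch ANOVA matches the textbook formula and the t^2 identity", {
  g3 <- list(a = c(1, 2, 3), b = c(2, 3, 4.5), c = c(3, 4, 5.5, 7))
  res <- welch_anova(g3)
  want <- oracle_welch(g3)
  expect_equal(res$value, want$W, tolerance = 1e-10)
  expect_equal(res$df1, want$df1)
  expect_equal(res$df2, want$df2, tolerance = 1e-8)
  expect_equal(res$p, want$p, tolerance = 1e-10)

  # identical groups: W = 0
  expect_equal(welch_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))$value, 0)

  # two groups: W equals the square of Welch's t
  x <- c(1.2, 3.1, 0.8, 2.2); y <- c(4.1, 5.3, 3.9)
  res2 <- welch_anova(list(x, y))
  tt <- t.test(x, y)
  expect_equal(res2$value, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$df2, unname(tt$parameter), tolerance = 1e-8)

  expect_error(welch_anova(list(c(1, 1, 1), c(1, 2, 3))), "zero within-group")
  expect_error(welch_anova(list(c(1, 2))), "at least 2 groups")
})

test_that("Welch W approaches the classical F as variances equalize", {
  set.seed(53)
  n <- 20000
  x <- rnorm(n); x <- (x - mean(x)) / sd(x)        # exactly mean 0, var 1
  groups <- list(x, x + 0.02, x + 0.05)            # identical variances
  W <- welch_anova(groups)$value
  g <- factor(rep(1:3, each = n))
  F_classic <- unname(summary(aov(unlist(groups) ~ g))[[1]]$`F value`[1])
  expect_equal(W, F_classic, tolerance = 1e-4)
})

test_that("paired t on differences with df = n - 1", {
  res <- paired_t(c(3, 5), c(1, 2))
  expect_equal(res$value, 5)
  expect_equal(res$df1, 1)
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3) ), "zero-variance")
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero-variance")
  # antisymmetry
  set.seed(54)
  x <- rnorm(10); y <- rnorm(10)
  a <- paired_t(x, y); b <- paired_t(y, x)
  expect_equal(a$value, -b$value)
  expect_equal(a$p, b$p)
})

test_that("Bonferroni post hocs multiply p by the comparison count, capped at 1", {
  set.seed(55)
  g <- list(a = rnorm(6), b = rnorm(6) + 3, c = rnorm(6))
  res <- posthoc_pairwise(g, "bonferroni")
  expect_equal(nrow(res), 3)
  expect_equal(res$p, pmin(1, 3 * res$p_unadjusted))
  # equal samples: t = 0, raw p = 1, adjusted capped at 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res2 <- posthoc_pairwise(same, "bonferroni")
  expect_equal(res2$value, 0)
  expect_equal(res2$p, 1)
})

test_that("Tukey post hocs cover all pairs with p in [0, 1]", {
  set.seed(56)
  g <- list(a = rnorm(8), b = rnorm(8) + 2, c = rnorm(8))
  res <- posthoc_pairwise(g, "tukey")
  expect_equal(nrow(res), 3)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_lt(res$p[res$effect == "b vs a"], 0.05)
})

test_that("split-plot rm_anova detects a between-group effect it should", {
  set.seed(57)
  d <- expand.grid(subject = factor(1:12), trial = factor(1:4))
  d$group <- factor(ifelse(as.integer(d$subject) <= 6, "ctl", "trt"))
  d$y <- rnorm(48, sd = 0.5) + ifelse(d$group == "trt", 2, 0) +
    as.numeric(d$trial) * 0.3
  res <- rm_anova(d, "y", within = "trial", between = "group")
  expect_true(all(c("group", "trial", "group:trial") %in% res$effect))
  expect_lt(res$p[res$effect == "group"], 0.01)
  expect_lt(res$p[res$effect == "trial"], 0.05)
})
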