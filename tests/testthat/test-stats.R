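test_that("ICC(2,1) matches the two-way ANOVA decomposition and a frozen reference", {
  # random pairs against the aov() mean-squares oracle
  set.seed(40)
  for (i in 1:20) {
    x <- rnorm(20, 50, 10)
    y <- x + rnorm(20, 1, 4)
    r <- icc_2_1(x, y)
    expect_equal(r$icc, ref_icc21_aov(x, y), tolerance = 1e-10)
  }
  # frozen reference (independently computed with another implementation)
  x <- c(37.114818, 46.523106, 44.783712, 62.734732, 68.245206, 34.886921,
         51.105080, 42.392038, 43.301030, 52.745197, 39.767280, 31.806021,
         43.322102, 49.407020, 58.801659, 52.685129, 49.804206, 44.750530,
         35.906686, 31.660108)
  y <- c(38.323247, 52.295239, 42.223064, 68.734388, 77.697971, 31.404911,
         50.433977, 37.286023, 39.087338, 55.904878, 33.141268, 36.880324,
         48.956478, 51.196069, 61.881668, 63.533811, 52.905961, 49.407923,
         48.755191, 18.988017)
  r <- icc_2_1(x, y)
  expect_equal(r$icc, 0.8591663526, tolerance = 1e-8)
  expect_equal(round(c(r$ci_low, r$ci_high), 2), c(0.68, 0.94))
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)
})

test_that("ICC(2,1) model properties: perfect agreement, bias penalty, degeneracy", {
  x <- c(1, 2, 3, 4, 5, 6)
  r <- icc_2_1(x, x)
  expect_equal(r$icc, 1)
  # a large constant offset is penalised by absolute agreement
  rb <- icc_2_1(x, x + 10)
  expect_lt(rb$icc, 0.3)
  # affine common rescaling leaves ICC unchanged
  set.seed(41)
  a <- rnorm(15); b <- a + rnorm(15, 0, 0.5)
  expect_equal(icc_2_1(a, b)$icc, icc_2_1(10 + 3 * a, 10 + 3 * b)$icc,
               tolerance = 1e-10)
  # zero between-subject variance is flagged, not an error
  rz <- icc_2_1(rep(1, 5), rep(1, 5))
  expect_true(is.na(rz$icc))
  expect_match(rz$flag, "variance")
})

test_that("Bland-Altman summaries follow the closed form", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  r <- bland_altman(x, y)
  expect_equal(r$bias, 0)
  expect_equal(c(r$loa_low, r$loa_high), c(0, 0))
  # diffs {-1, 1}: bias 0, LoA = +/- 1.96 * sample sd = +/- 1.96 * sqrt(2)
  r2 <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(r2$bias, 0)
  expect_equal(r2$loa_high, 1.96 * sqrt(2))
  expect_equal(r2$loa_low, -1.96 * sqrt(2))
  # homogeneity: scaling both measurements scales bias and LoA
  set.seed(42)
  a <- rnorm(10); b <- rnorm(10)
  r1 <- bland_altman(a, b); r3 <- bland_altman(3 * a, 3 * b)
  expect_equal(r3$bias, 3 * r1$bias)
  expect_equal(r3$loa_high, 3 * r1$loa_high)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("rm_anova matches aov() Error-strata on a balanced within-subject design", {
  set.seed(43)
  n <- 12
  d <- expand.grid(subject = factor(1:n), model = factor(c("a", "b", "c")),
                   muscle = factor(c("m1", "m2")))
  d$dice <- 0.9 + rep(rnorm(n, 0, 0.03), 6) +
    0.02 * (d$model == "b") - 0.01 * (d$muscle == "m2") + rnorm(nrow(d), 0, 0.01)
  got <- rm_anova(d, dv = "dice", subject = "subject", factors = c("model", "muscle"))
  fit <- summary(stats::aov(dice ~ model * muscle +
                              Error(subject / (model * muscle)), data = d))
  pick <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, ]
  }
  for (case in list(c("Error: subject:model", "model"),
                    c("Error: subject:muscle", "muscle"),
                    c("Error: subject:model:muscle", "model:muscle"))) {
    ref <- pick(case[1], case[2])
    row <- got[got$effect == case[2], ]
    expect_equal(row$f, ref[["F value"]], tolerance = 1e-8)
    expect_equal(row$p, ref[["Pr(>F)"]], tolerance = 1e-8)
    expect_equal(row$ss, ref[["Sum Sq"]], tolerance = 1e-8)
  }
})

test_that("rm_anova reduces to the squared paired t for two conditions", {
  set.seed(44)
  n <- 15
  x <- rnorm(n, 10, 2); y <- x + rnorm(n, 0.5, 1)
  d <- data.frame(subject = factor(rep(1:n, 2)),
                  cond = factor(rep(c("a", "b"), each = n)),
                  v = c(x, y))
  a <- rm_anova(d, dv = "v", subject = "subject", factors = "cond")
  t <- paired_t(x, y)
  expect_equal(a$f[1], t$t^2, tolerance = 1e-10)
  expect_equal(a$p[1], t$p, tolerance = 1e-10)
})

test_that("rm_anova null structure, conservation, and error handling", {
  set.seed(45)
  n <- 10
  d <- expand.grid(subject = factor(1:n), cond = factor(c("a", "b", "c")))
  # subject offsets plus double-centred noise: condition effect exactly null
  e <- matrix(rnorm(n * 3), n, 3)
  e <- e - rowMeans(e) - rep(colMeans(e), each = n) + mean(e)
  d$v <- rep(rnorm(n), 3) + as.vector(e)
  a <- rm_anova(d, dv = "v", subject = "subject", factors = "cond")
  expect_lt(a$f[1], 1e-10)
  expect_gt(a$p[1], 0.999)
  # decomposition conserves the total sum of squares
  d$v <- d$v + rnorm(nrow(d), 0, 0.5)
  a2 <- rm_anova(d, dv = "v", subject = "subject", factors = "cond")
  ss_subj <- sum(paraseg:::effect_values(d, "v", "subject")^2)
  ss_tot <- sum((d$v - mean(d$v))^2)
  ss_err <- sum(paraseg:::effect_values(d, "v", c("subject", "cond"))^2)
  expect_equal(a2$ss[1] + ss_subj + ss_err, ss_tot, tolerance = 1e-9)
  # incomplete designs are rejected, not imputed
  expect_error(rm_anova(d[-1, ], dv = "v", subject = "subject", factors = "cond"),
               "complete")
})

test_that("a planted model effect is recovered at the cohort's sample size", {
  # two models x six muscles, 30 subjects, one model better by construction
  set.seed(46)
  n <- 30
  d <- expand.grid(subject = factor(1:n), model = factor(c("better", "worse")),
                   muscle = factor(1:6))
  subj_eff <- rnorm(n, 0, 0.02)
  d$dice <- 0.92 + subj_eff[d$subject] - 0.02 * (d$model == "worse") +
    rnorm(nrow(d), 0, 0.01)
  a <- rm_anova(d, dv = "dice", subject = "subject", factors = c("model", "muscle"))
  expect_lt(a$p[a$effect == "model"], 0.01)
  # and the post-hoc paired t recovers the direction
  wide_b <- tapply(d$dice[d$model == "better"], d$subject[d$model == "better"], mean)
  wide_w <- tapply(d$dice[d$model == "worse"], d$subject[d$model == "worse"], mean)
  t <- paired_t(wide_b, wide_w)
  expect_lt(t$p, 0.05)
  expect_gt(t$t, 0)
})

test_that("paired_t follows the closed form and is antisymmetric", {
  x <- c(5, 6, 7, 8, 9); y <- c(5, 6, 7, 8, 9)
  r <- paired_t(x, y)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  set.seed(47)
  a <- rnorm(12); b <- a + rnorm(12, 0.3)
  d <- a - b
  r2 <- paired_t(a, b)
  expect_equal(r2$t, mean(d) / (sd(d) / sqrt(length(d))), tolerance = 1e-12)
  r3 <- paired_t(b, a)
  expect_equal(r3$t, -r2$t)
  expect_equal(r3$p, r2$p)
  # zero-variance differences flagged
  r4 <- paired_t(a, a + 1)
  expect_match(r4$flag, "zero-variance")
})

test_that("assumption checks behave correctly on known distributions", {
  set.seed(48)
  r <- assumption_checks(rnorm(500))
  expect_gt(r$shapiro_p, 0.001)
  expect_lt(abs(r$skewness), 0.2)
  expect_lt(abs(r$kurtosis), 0.6)
  expect_equal(nrow(r$qq), 500)
  # exponential residuals: skewness near the distributional constant 2
  re <- assumption_checks(rexp(4000))
  expect_equal(re$skewness, 2, tolerance = 0.35)
  # 2 conditions: Mauchly trivially satisfied and skipped with a note
  tab2 <- matrix(rnorm(40), 20, 2)
  r2 <- assumption_checks(rnorm(20), repeated = tab2)
  expect_true(is.na(r2$mauchly_w))
  expect_match(r2$note, "trivially")
  # 3+ conditions: Mauchly matches stats::mauchly.test
  tab3 <- matrix(rnorm(90), 30, 3)
  r3 <- assumption_checks(rnorm(30), repeated = tab3)
  ref <- mauchly.test(lm(tab3 ~ 1), X = ~1)
  expect_equal(r3$mauchly_w, unname(ref$statistic))
  expect_equal(r3$mauchly_p, ref$p.value)
})
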