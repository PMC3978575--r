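test_that("weighted percentiles follow the mid-rank weighted CDF", {
  # hand-computed from 100*(W(<v) + W(=v)/2)/W: {10 w=1, 20 w=3}, W = 4
  expect_equal(weighted_percentiles(c(10, 20), c(1, 3)), c(12.5, 62.5))

  # equal weights reduce to unweighted mid-rank percentiles
  set.seed(2)
  v <- sample(1:1000, 50)
  expect_equal(weighted_percentiles(v),
               100 * (rank(v) - 0.5) / length(v))

  # a record with weight 2 is exactly two unit-weight copies
  expect_equal(unique(weighted_percentiles(c(5, 5, 7), c(1, 1, 1))),
               weighted_percentiles(c(5, 7), c(2, 1)))

  # ties share one percentile
  p <- weighted_percentiles(c(3, 3, 9), c(1, 2, 1))
  expect_identical(p[1], p[2])
  expect_error(weighted_percentiles(numeric(0)), "non-empty")
  expect_error(weighted_percentiles(1:3, c(0, 0, 0)), "weights")
})

test_that("quintile-decile groups use left-closed boundaries", {
  expect_identical(as.character(assign_density_group(
    c(0, 10, 20, 39.9, 40, 60, 79.9, 80, 85, 90, 95, 100))),
    c("Q1", "Q1", "Q2", "Q2", "Q3", "Q4", "Q4", "D9", "D9", "D10", "D10",
      "D10"))
  expect_error(assign_density_group(101), "\\[0, 100\\]")
  expect_error(assign_density_group(-0.1), "\\[0, 100\\]")
})

test_that("uniform percentiles yield 20/20/20/20/10/10 group shares", {
  set.seed(5)
  u <- runif(50000) * 100
  shares <- as.numeric(table(assign_density_group(u))) / 50000
  expect_equal(shares, c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1), tolerance = 0.05)
  expect_true(all(abs(shares - c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1)) < 0.01))
})

test_that("tumour classification follows the protocol cut points", {
  out <- classify_tumour(c("microinvasive", "15", "15.1", "3.2"))
  expect_equal(out$size_mm, c(0.1, 15, 15.1, 3.2))
  expect_identical(out$category, c("small", "small", "large", "small"))
  expect_error(classify_tumour(0), "positive")
  expect_error(classify_tumour(-3), "positive")
})

test_that("the 2x2 logistic OR matches ad/bc with the Woolf interval", {
  a <- 30L; b <- 70L; cc <- 60L; d <- 240L   # cases/controls x D10/Q1
  rec <- rbind(toy_records(rep("interval", a), "D10"),
               toy_records(rep("interval", b), "Q1"),
               toy_records(rep("control", cc), "D10"),
               toy_records(rep("control", d), "Q1"))
  rec$woman_id <- sprintf("W%04d", seq_len(nrow(rec)))
  ot <- fit_outcome_model(rec, cases = "interval",
                          covariates = character(0),
                          group_col = "density_group")
  or_cf <- a * d / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- qnorm(0.975)
  d10 <- ot[ot$group == "D10", ]
  expect_equal(d10$or, or_cf, tolerance = 1e-7)
  expect_equal(d10$ci_low, exp(log(or_cf) - z * se), tolerance = 1e-6)
  expect_equal(d10$ci_high, exp(log(or_cf) + z * se), tolerance = 1e-6)
  expect_identical(ot$or[ot$group == "Q1"], 1)
  expect_identical(d10$n_cases, a)
  expect_identical(d10$n_controls, cc)
})

test_that("equal case/control odds across groups give ORs of one", {
  # same 3:10 case:control ratio in every group -> all ORs exactly 1
  groups <- rep(c("Q1", "Q2", "Q3", "Q4", "D9", "D10"), each = 13)
  outcome <- rep(c(rep("interval", 3), rep("control", 10)), times = 6)
  rec <- toy_records(outcome, groups)
  rec$density_group <- groups
  ot <- fit_outcome_model(rec, cases = "interval",
                          covariates = character(0),
                          group_col = "density_group")
  expect_equal(ot$or, rep(1, 6), tolerance = 1e-8)
})

test_that("complete separation raises an explicit error naming the term", {
  rec <- rbind(toy_records(rep("interval", 40), "Q1"),
               toy_records(rep("control", 60), "Q1"),
               toy_records(rep("interval", 25), "D10"))
  rec$woman_id <- sprintf("W%04d", seq_len(nrow(rec)))
  expect_error(fit_outcome_model(rec, cases = "interval",
                                 covariates = character(0),
                                 group_col = "density_group"),
               "density_group")
})

test_that("a designed density effect is recovered with covering CI", {
  spec <- cohort_spec(n_women = 50000, seed = 71,
                      density_logor = list(small = log(2), large = log(2),
                                           interval = log(3)))
  co <- generate_cohort(spec)
  ot <- fit_outcome_model(co, cases = "interval")
  d10 <- ot[ot$group == "D10", ]
  expect_lt(d10$ci_low, 3)
  expect_gt(d10$ci_high, 3)
})

test_that("interaction terms with screening round can be fitted", {
  co <- generate_cohort(cohort_spec(n_women = 30000, seed = 73))
  ot <- fit_outcome_model(co, cases = c("small_screen_detected",
                                        "large_screen_detected", "interval"),
                          interaction = TRUE)
  m <- attr(ot, "model")
  expect_true(any(grepl("screening_round.*density_group|density_group.*screening_round",
                        names(coef(m)))))
})

test_that("programme sensitivity is the pure odds transform", {
  expect_equal(sensitivity_from_odds(0.25), 80)
  expect_equal(sensitivity_from_odds(0), 100)
  expect_equal(sensitivity_from_odds(1), 50)

  co <- generate_cohort(cohort_spec(n_women = 40000, seed = 81))
  st <- predict_sensitivity(co)
  expect_equal(st$sensitivity, 100 / (1 + st$interval_odds))
  expect_true(all(st$ci_low <= st$sensitivity & st$sensitivity <= st$ci_high))
  expect_true(all(st$sensitivity >= 0 & st$sensitivity <= 100))
})

test_that("AUC equals brute-force pair counting, ties halved", {
  # listed small sample: case 3 beats controls 1 and 2, loses to 5;
  # each case 5 beats 1 and 2 and ties 5 -> (2 + 2.5 + 2.5)/9 = 7/9
  cases <- c(3, 5, 5); controls <- c(1, 2, 5)
  r <- roc_auc(cases, controls)
  expect_equal(r$auc, 7 / 9)
  expect_equal(r$auc, oracle_auc(cases, controls))

  expect_equal(roc_auc(c(10, 11), c(1, 2))$auc, 1)
  expect_equal(roc_auc(rep(4, 5), rep(4, 7))$auc, 0.5)

  set.seed(33)
  for (i in 1:50) {
    x <- sample(1:8, sample(2:10, 1), replace = TRUE)
    y <- sample(1:8, sample(2:10, 1), replace = TRUE)
    expect_equal(roc_auc(x, y)$auc, oracle_auc(x, y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  x <- rnorm(80, 1); y <- rnorm(120)
  ours <- roc_auc(x, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 80), rep(0, 120)), predictor = c(x, y),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("ROC curve points span the unit square monotonically", {
  set.seed(45)
  r <- roc_auc(rnorm(30, 1), rnorm(50))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
})

test_that("the Cuzick trend statistic matches the hand computation", {
  # 3 groups of 3, values strictly increasing with group, no ties:
  # T = 1*(1+2+3) + 2*(4+5+6) + 3*(7+8+9) = 108, E[T] = 90, Var = 45
  vals <- 1:9
  grp <- factor(rep(c("low", "mid", "high"), each = 3),
                levels = c("low", "mid", "high"))
  cz <- cuzick_trend_test(vals, grp)
  expect_equal(cz$statistic, 108)
  expect_equal(cz$z, 18 / sqrt(45))
  expect_gt(cz$z, 0)

  # degenerate input: all values identical
  tt <- trend_and_rank_tests(rep(5, 9), grp)
  expect_equal(tt$cuzick$z, 0)
  expect_equal(tt$kruskal_wallis$h, 0)
  expect_equal(tt$kruskal_wallis$p_value, 1)
  expect_error(cuzick_trend_test(1:3, factor(c("a", "a", "a"),
                                             levels = c("a", "b"))),
               "at least one member")
})

test_that("with two groups Kruskal-Wallis is the squared rank-sum z", {
  set.seed(51)
  vals <- sample(1:1000, 40)          # distinct -> no tie correction
  grp <- rep(c("g1", "g2"), c(15, 25))
  tt <- trend_and_rank_tests(vals, grp)
  r <- rank(vals)
  w <- sum(r[grp == "g1"])
  n1 <- 15; n2 <- 25; N <- 40
  z_w <- (w - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(tt$kruskal_wallis$h, z_w^2, tolerance = 1e-12)
})

test_that("identical measures agree perfectly", {
  set.seed(61)
  a <- rlnorm(500, 10, 0.8)
  rep <- compare_measures(a, a)
  expect_equal(rep$r, 1)
  expect_equal(rep$bland_altman$mean_diff, 0)
  expect_equal(rep$perfect_agreement_pct, 100)
  expect_equal(sum(rep$cross_classification), 100)
})

test_that("independent measures show null agreement levels", {
  set.seed(62)
  n <- 20000
  a <- rlnorm(n, 10, 0.8)
  b <- rlnorm(n, 9.8, 0.7)
  rep <- compare_measures(a, b)
  expect_lt(abs(rep$r), 0.03)
  # P(same group) = 4*0.2^2 + 2*0.1^2 = 18% under independence
  expect_lt(abs(rep$perfect_agreement_pct - 18), 1.5)
})

test_that("within-one agreement matches a brute-force cell scan", {
  set.seed(63)
  a <- rlnorm(800, 10, 0.8)
  b <- a * exp(rnorm(800, 0, 0.4))
  rep <- compare_measures(a, b)
  m <- rep$cross_classification
  brute <- 0
  for (i in 1:6)
    for (j in 1:6)
      if (abs(i - j) <= 1) brute <- brute + m[i, j]
  expect_equal(rep$within_one_pct, brute)
  expect_equal(rep$perfect_agreement_pct, sum(diag(m)))
  expect_equal(sum(m), 100)
})

test_that("degenerate agreement input raises the documented error", {
  expect_error(compare_measures(rep(3, 10), rep(3, 10)),
               "zero-variance")
  expect_error(compare_measures(1:5, 1:4), "paired")
})
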