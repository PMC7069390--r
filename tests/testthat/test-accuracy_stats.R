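# Confusion tables, proportion CIs, likelihood ratios, AUROC, McNemar.

test_that("confusion_table counts the four cells", {
  ct <- confusion_table(c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(1, 1, 1, 1))

  ct2 <- confusion_table(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(c(ct2$fp, ct2$fn, ct2$tn), c(0, 0, 0))

  # 12-subject fixture against a hand count
  scr <- c(T, T, T, F, F, F, T, F, T, F, T, F)
  ref <- c(T, F, T, T, F, F, T, F, F, T, T, F)
  ct3 <- confusion_table(scr, ref)
  expect_equal(ct3$tp, 4)
  expect_equal(ct3$fp, 2)
  expect_equal(ct3$fn, 2)
  expect_equal(ct3$tn, 4)
  expect_equal(ct3$n, 12)

  expect_error(confusion_table(c(TRUE, FALSE), TRUE), "equal length")
  # NA pairs are excluded and reported
  ct4 <- confusion_table(c(TRUE, NA, FALSE), c(TRUE, TRUE, NA))
  expect_equal(ct4$n, 1)
  expect_equal(ct4$n_excluded, 2)
})

test_that("proportion_ci agrees with the stats:: oracles", {
  # wilson == prop.test without continuity correction
  for (k in c(0, 3, 17, 232)) {
    ci <- proportion_ci(k, 347, "wilson")
    want <- prop.test(k, 347, correct = FALSE)$conf.int
    expect_equal(c(ci$ci_low, ci$ci_high), as.numeric(want),
                 tolerance = 1e-9)
  }
  # exact == binom.test (Clopper-Pearson)
  for (k in c(0, 1, 5, 10)) {
    ci <- proportion_ci(k, 10, "exact")
    want <- binom.test(k, 10)$conf.int
    expect_equal(c(ci$ci_low, ci$ci_high), as.numeric(want),
                 tolerance = 1e-9)
  }
  expect_equal(proportion_ci(0, 10, "exact")$ci_low, 0)
  # wald is clipped to [0, 1]
  w <- proportion_ci(1, 10, "wald")
  expect_gte(w$ci_low, 0)
  expect_error(proportion_ci(3, 0), "n must be")
  expect_error(proportion_ci(5, 3), "successes")
  # vectorized
  ci <- proportion_ci(c(1, 2), c(10, 20))
  expect_equal(nrow(ci), 2)
  expect_true(all(ci$ci_low <= ci$estimate & ci$estimate <= ci$ci_high))
})

test_that("validity_metrics computes the four proportions with CIs", {
  ct <- confusion_table(c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, FALSE, TRUE, FALSE))
  v <- validity_metrics(ct)
  expect_equal(v$estimate, rep(0.5, 4))

  perfect <- structure(list(tp = 10, fp = 0, fn = 0, tn = 20, n = 30,
                            n_excluded = 0), class = "confusion_table")
  expect_equal(validity_metrics(perfect)$estimate, rep(1, 4))

  # reconstructed sensitivity cell: 232 of 347 reference-positives
  t347 <- structure(list(tp = 232, fp = 210, fn = 115, tn = 425, n = 982,
                         n_excluded = 0), class = "confusion_table")
  v347 <- validity_metrics(t347)
  sens <- v347[v347$metric == "sensitivity", ]
  expect_equal(round(100 * sens$estimate, 1), 66.9)
  # exactness: sens * (tp + fn) recovers tp as an integer
  expect_equal(sens$estimate * 347, 232, tolerance = 1e-12)

  # zero denominator -> undefined, not 0
  noneg <- confusion_table(c(TRUE, FALSE), c(TRUE, TRUE))
  v0 <- validity_metrics(noneg)
  expect_true(is.na(v0$estimate[v0$metric == "specificity"]))
})

test_that("likelihood ratios and their degenerate flags", {
  ct <- confusion_table(c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, FALSE, TRUE, FALSE))
  lr <- likelihood_ratios(ct)
  expect_equal(lr$estimate, c(1, 1))

  t89 <- structure(list(tp = 8, fp = 1, fn = 2, tn = 9, n = 20,
                        n_excluded = 0), class = "confusion_table")
  lr2 <- likelihood_ratios(t89)
  expect_equal(lr2$estimate[lr2$metric == "lr_pos"], 8)
  expect_equal(lr2$estimate[lr2$metric == "lr_neg"], 2 / 9,
               tolerance = 1e-12)
  # CI by the log-variance formula, checked by hand
  se <- sqrt(1 / 8 - 1 / 10 + 1 / 1 - 1 / 10)
  expect_equal(lr2$ci_low[1], exp(log(8) - qnorm(0.975) * se),
               tolerance = 1e-9)

  perfect <- structure(list(tp = 5, fp = 0, fn = 0, tn = 5, n = 10,
                            n_excluded = 0), class = "confusion_table")
  lrp <- likelihood_ratios(perfect)
  expect_true(all(lrp$degenerate))
  expect_true(is.infinite(lrp$estimate[lrp$metric == "lr_pos"]))
})

test_that("binary-cutoff AUROC is (sens + spec) / 2", {
  ct <- confusion_table(c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(auc_point(ct), 0.5)
  perfect <- structure(list(tp = 5, fp = 0, fn = 0, tn = 5, n = 10,
                            n_excluded = 0), class = "confusion_table")
  expect_equal(auc_point(perfect), 1)
  t67 <- structure(list(tp = 67, fp = 24, fn = 33, tn = 76, n = 200,
                        n_excluded = 0), class = "confusion_table")
  expect_equal(auc_point(t67), 0.715)
})

test_that("empirical AUROC: separation, null, ties and wilcox oracle", {
  expect_equal(auc_empirical(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1)
  expect_error(auc_empirical(1:5, rep(TRUE, 5)), "both classes")

  # labels independent of scores -> 0.5 within 0.02 at n = 1e4
  set.seed(14)
  sc <- rnorm(1e4)
  lb <- runif(1e4) < 0.35
  expect_lt(abs(auc_empirical(sc, lb)$auc - 0.5), 0.02)

  # equals the wilcox rank-sum statistic normalization
  set.seed(15)
  sc2 <- sample(1:8, 30, replace = TRUE)  # heavy ties
  lb2 <- runif(30) < 0.5
  w <- wilcox.test(sc2[lb2], sc2[!lb2], exact = FALSE)$statistic
  expect_equal(auc_empirical(sc2, lb2)$auc,
               unname(w) / (sum(lb2) * sum(!lb2)), tolerance = 1e-12)

  # CI is ordered and clipped
  a <- auc_empirical(sc2, lb2)
  expect_true(a$ci_low <= a$auc && a$auc <= a$ci_high)
})

test_that("McNemar: symmetry, arithmetic, exact tail and oracles", {
  sym <- mcnemar_test(7, 7)
  expect_equal(sym$p_value, 1)

  asym <- mcnemar_test(20, 5, mode = "asymptotic")
  expect_equal(asym$statistic, 9)  # (15)^2 / 25
  expect_equal(asym$p_value,
               mcnemar.test(matrix(c(1, 5, 20, 1), 2), correct = FALSE)$p.value,
               tolerance = 1e-9)

  ex <- mcnemar_test(10, 2, mode = "exact")
  expect_equal(ex$p_value, oracle_mcnemar_exact(10, 2), tolerance = 1e-9)
  expect_equal(ex$p_value, binom.test(2, 12, 0.5)$p.value,
               tolerance = 1e-9)

  # auto mode switches on b + c
  expect_equal(mcnemar_test(10, 2)$mode, "exact")
  expect_equal(mcnemar_test(30, 10)$mode, "asymptotic")

  deg <- mcnemar_test(0, 0)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("adding a correctly classified subject never hurts both
           sensitivity and specificity", {
  set.seed(21)
  for (i in 1:20) {
    scr <- runif(30) < 0.5
    ref <- runif(30) < 0.4
    ct <- confusion_table(scr, ref)
    v <- validity_metrics(ct)$estimate[1:2]
    correct <- runif(1) < 0.5
    ct2 <- confusion_table(c(scr, correct), c(ref, correct))
    v2 <- validity_metrics(ct2)$estimate[1:2]
    expect_true(v2[1] >= v[1] || v2[2] >= v[2])
  }
})
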