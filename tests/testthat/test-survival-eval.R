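make_clin <- function(time, event, ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(time))
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("concordance matches all-pairs enumeration on worked tables", {
  cl <- make_clin(c(2, 4, 6, 8), rep(1L, 4))
  expect_equal(c_index(c(0.9, 0.8, 0.1, 0.2), cl, boot_B = 0)$c_index, 5 / 6)
  expect_equal(c_index(rep(0.5, 4), cl, boot_B = 0)$c_index, 0.5)
  expect_equal(c_index(-cl$time, cl, boot_B = 0)$c_index, 1)
  expect_equal(c_index(cl$time, cl, boot_B = 0)$c_index, 0)
  expect_error(c_index(1:3, make_clin(1:3, c(0L, 0L, 0L)), boot_B = 0),
               "at least one event")
})

test_that("concordance agrees with the survival package on random data", {
  set.seed(5)
  n <- 60
  cl <- make_clin(rexp(n, 0.02), rbinom(n, 1, 0.7))
  risk <- rnorm(n) + 0.02 * max(cl$time) - 0.02 * cl$time
  ours <- c_index(risk, cl, boot_B = 0)$c_index
  ref <- survival::concordance(survival::Surv(cl$time, cl$event) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("concordance symmetry and rank invariance hold", {
  set.seed(6)
  cl <- make_clin(rexp(30, 0.05), rbinom(30, 1, 0.8))
  risk <- rnorm(30)
  c1 <- c_index(risk, cl, boot_B = 0)$c_index
  expect_equal(c1 + c_index(-risk, cl, boot_B = 0)$c_index, 1)
  expect_identical(c1, c_index(exp(2 * risk), cl, boot_B = 0)$c_index)
})

test_that("bootstrap confidence intervals are seed-deterministic", {
  set.seed(7)
  cl <- make_clin(rexp(40, 0.05), rbinom(40, 1, 0.8))
  risk <- rnorm(40)
  r1 <- c_index(risk, cl, boot_B = 100, seed = 3)
  r2 <- c_index(risk, cl, boot_B = 100, seed = 3)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_true(r1$ci_low <= r1$c_index && r1$c_index <= r1$ci_high)
})

test_that("D-index coefficient matches an independent Cox fit", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 80
    risk <- rnorm(n)
    t <- rexp(n, rate = 0.01 * exp(0.8 * risk))
    cl <- make_clin(pmin(t, 100), as.integer(t <= 100))
    ours <- d_index(risk, cl)
    z <- stats::qnorm((rank(risk) - 3 / 8) / (n + 1 / 4)) / sqrt(8 / pi)
    ref <- survival::coxph(survival::Surv(cl$time, cl$event) ~ z,
                           ties = "breslow")
    expect_equal(ours$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(ours$se_beta, sqrt(unname(vcov(ref)[1, 1])),
                 tolerance = 1e-4)
  }
})

test_that("D-index is rank-invariant and centered at 1 under the null", {
  set.seed(9)
  cl <- make_clin(rexp(50, 0.03), rbinom(50, 1, 0.8))
  risk <- rnorm(50)
  d1 <- d_index(risk, cl)
  d2 <- d_index(rank(risk)^3, cl)        # strictly increasing transform
  expect_identical(d1$d_index, d2$d_index)

  ds <- replicate(8, {
    t <- rexp(100, 0.02)
    d_index(rnorm(100), make_clin(pmin(t, 90), as.integer(t <= 90)))$d_index
  })
  expect_gt(mean(ds), 0.8)
  expect_lt(mean(ds), 1.25)
})

test_that("degenerate D-index inputs raise named errors", {
  cl <- make_clin(c(5, 10, 15, 20), rep(1L, 4))
  expect_error(d_index(rep(1, 4), cl), "distinct risk")
  # risk perfectly reverse-ordered with time: monotone partial likelihood
  cl2 <- make_clin(c(1, 2, 3, 100, 110, 120), rep(1L, 6))
  expect_error(d_index(c(60, 50, 40, 30, 20, 10), cl2), "separation|converge")
})

test_that("Kaplan-Meier curves and log-rank match hand enumeration", {
  # 6-patient worked table
  cl <- make_clin(c(5, 8, 12, 6, 9, 14), c(1L, 1L, 0L, 1L, 0L, 1L))
  grp <- stats::setNames(rep(c("high", "low"), each = 3), cl$sample_id)
  km <- km_logrank(grp, cl)
  expect_equal(km$chisq, brute_logrank_chisq(rep(c("high", "low"), each = 3),
                                             cl$time, cl$event),
               tolerance = 1e-9)
  expect_true(km$p_value > 0 && km$p_value < 1)

  # no censoring: product-limit equals the empirical survivor function
  cl2 <- make_clin(c(3, 6, 9, 12), rep(1L, 4))
  km2 <- km_logrank(stats::setNames(c("high", "high", "low", "low"),
                                    cl2$sample_id), cl2)
  hi <- km2$curves[km2$curves$group == "high", ]
  expect_equal(hi$surv, c(0.5, 0))

  # identical samples in both groups: no separation at all
  cl3 <- make_clin(rep(c(4, 7, 11), 2), rep(c(1L, 0L, 1L), 2),
                   ids = sprintf("s%d", 1:6))
  km3 <- km_logrank(stats::setNames(rep(c("high", "low"), 3), cl3$sample_id),
                    cl3)
  expect_equal(km3$chisq, 0, tolerance = 1e-12)
  expect_equal(km3$p_value, 1)

  expect_error(km_logrank(rep("high", 6), cl), "two nonempty groups")
})

test_that("horizon AUC implements the exclusion rule and tie credit", {
  cl <- make_clin(c(10, 20, 50, 70), c(1L, 1L, 0L, 0L))
  expect_equal(auc_horizon(c(0.9, 0.8, 0.2, 0.1), cl)$auc, 1)
  expect_equal(auc_horizon(c(0.9, 0.3, 0.8, 0.4), cl)$auc, 0.5)
  expect_equal(auc_horizon(rep(1, 4), cl)$auc, 0.5)

  # censored before horizon without event is excluded and counted
  cl2 <- make_clin(c(10, 30, 20, 40, 50), c(1L, 0L, 0L, 0L, 0L))
  r <- auc_horizon(c(5, 4, 3, 2, 1), cl2)
  expect_identical(r$n_excluded, 2L)
  expect_identical(r$n_pos, 1L)
  expect_identical(r$n_neg, 2L)
  expect_error(auc_horizon(1:4, make_clin(c(50, 60, 70, 80), rep(0L, 4))),
               "no positive")
})

test_that("weighted signatures score by dot product over present genes", {
  expr <- matrix(c(5, 3, 4, 1, 2, 6), 3, 2,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(unname(score_weighted_signature(c(A = 1), expr)), c(5, 1),
               ignore_attr = TRUE)
  s <- score_weighted_signature(c(A = 2, B = -1, ZZZ = 9), expr)
  expect_equal(unname(s), c(2 * 5 - 3, 2 * 1 - 2), ignore_attr = TRUE)
  expect_identical(attr(s, "coverage")$missing, "ZZZ")
  expect_equal(unname(score_weighted_signature(c(A = 0, C = 0), expr)),
               c(0, 0), ignore_attr = TRUE)
  expect_error(score_weighted_signature(c(Q = 1), expr), "no signature gene")
})
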