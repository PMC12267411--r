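test_that("label windows assign poor / good / excluded correctly", {
  cl <- data.frame(sample_id = c("a", "b", "c"),
                   time = c(24, 70, 40), event = c(1, 0, 0))
  sel <- select_training_labels(cl)
  expect_identical(sel$labels$label, c("poor", "good", "excluded"))

  # boundary semantics: recurrence AT 36 months is poor, event-free AT 60 good
  cl2 <- data.frame(sample_id = c("x", "y", "z", "w"),
                    time = c(36, 60, 36.5, 59), event = c(1, 0, 1, 0))
  expect_identical(select_training_labels(cl2)$labels$label,
                   c("poor", "good", "excluded", "excluded"))

  cl3 <- data.frame(sample_id = c("a", "b"), time = c(10, 20), event = c(1, 1))
  expect_error(select_training_labels(cl3), "no good-prognosis")
})

test_that("balanced accuracy is (sensitivity + specificity) / 2", {
  truth <- rep(c("poor", "good"), each = 4)
  pred <- c("poor", "poor", "poor", "good",   # TP=3 FN=1
            "poor", "poor", "good", "good")   # FP=2 TN=2
  expect_equal(balanced_accuracy(truth, pred), 0.625)
  expect_equal(balanced_accuracy(truth, rep("poor", 8)), 0.5)
  expect_equal(balanced_accuracy(truth, truth), 1)
  expect_error(balanced_accuracy(rep("poor", 4), rep("poor", 4)),
               "both classes")
})

test_that("every retained member beat the threshold on its held-out split", {
  co <- small_cohort(seed = 21)
  sel <- apply_label_windows(co$clinical)
  ps <- compute_pathway_scores(co$expr, co$sets)
  model <- train_pianos(ps, sel, B = 12, seed = 3,
                        ktsp_config = list(k_grid = c(1L, 3L)))
  expect_true(all(vapply(model$members, `[[`, 0, "ba") > 0.6))
  aud <- model$audit
  expect_identical(sum(aud$retained), length(model$members))
  expect_true(all(aud$ba[aud$retained] > 0.6))
  expect_identical(model$tau, length(model$members) %/% 2L)
})

test_that("training is seed-deterministic", {
  co <- small_cohort(seed = 22)
  sel <- apply_label_windows(co$clinical)
  ps <- compute_pathway_scores(co$expr, co$sets)
  m1 <- train_pianos(ps, sel, B = 6, seed = 9,
                     ktsp_config = list(k_grid = c(1L, 3L)))
  m2 <- train_pianos(ps, sel, B = 6, seed = 9,
                     ktsp_config = list(k_grid = c(1L, 3L)))
  expect_identical(m1, m2)
  m3 <- train_pianos(ps, sel, B = 6, seed = 10,
                     ktsp_config = list(k_grid = c(1L, 3L)))
  expect_false(identical(m1$audit$seed, m3$audit$seed))
})

test_that("B = 1 on a separable cohort gives one member and tau = 0", {
  rs <- random_scores(8, 10, 10, seed = 30)
  X <- rs$X
  X["P001", ] <- ifelse(rs$labels == "poor", 2, -2)
  X["P002", ] <- -X["P001", ] + rnorm(20, sd = 0.01)
  cl <- data.frame(sample_id = colnames(X),
                   time = ifelse(rs$labels == "poor", 12, 80),
                   event = ifelse(rs$labels == "poor", 1L, 0L))
  sel <- select_training_labels(cl)
  model <- train_pianos(X, sel, B = 1, seed = 1,
                        ktsp_config = list(k_grid = 1L))
  expect_length(model$members, 1L)
  expect_identical(model$tau, 0L)
})

test_that("risk grouping is strictly greater-than tau", {
  # 35 single-pair members over disjoint pathway pairs, tau = 17
  pairs <- lapply(1:35, function(i) {
    data.frame(greater = sprintf("A%02d", i), lesser = sprintf("B%02d", i),
               delta = 1, gamma = 1, stringsAsFactors = FALSE)
  })
  members <- lapply(pairs, function(p) {
    m <- pianos:::new_ktsp_model(p, 1L)
    m$ba <- 0.9
    m
  })
  ens <- pianos:::new_pianos_ensemble(members, B = 35, split_fraction = 0.7,
                                      ba_threshold = 0.6, tau = 17L, seed = 1)
  v18 <- c(stats::setNames(rep(c(2, 0), c(18, 17)), sprintf("A%02d", 1:35)),
           stats::setNames(rep(1, 35), sprintf("B%02d", 1:35)))
  p18 <- predict_pianos(ens, v18)
  expect_identical(p18$score, 18L)
  expect_identical(p18$group, "high")
  v17 <- c(stats::setNames(rep(c(2, 0), c(17, 18)), sprintf("A%02d", 1:35)),
           stats::setNames(rep(1, 35), sprintf("B%02d", 1:35)))
  p17 <- predict_pianos(ens, v17)
  expect_identical(p17$score, 17L)
  expect_identical(p17$group, "low")
  v0 <- c(stats::setNames(rep(0, 35), sprintf("A%02d", 1:35)),
          stats::setNames(rep(1, 35), sprintf("B%02d", 1:35)))
  expect_identical(predict_pianos(ens, v0)$group, "low")
})

test_that("an ensemble of identical members equals its single member", {
  co <- small_cohort(seed = 23)
  sel <- apply_label_windows(co$clinical)
  ps <- compute_pathway_scores(co$expr, co$sets)
  one <- train_pianos(ps, sel, B = 1, seed = 2,
                      ktsp_config = list(k_grid = c(1L, 3L)))
  member <- one$members[[1]]
  clones <- pianos:::new_pianos_ensemble(rep(list(member), 5), B = 5,
                                         split_fraction = 0.7,
                                         ba_threshold = 0.6, tau = 2L,
                                         seed = 1)
  votes <- predict_ktsp(member, ps$scores)
  grp <- predict_pianos(clones, ps$scores)
  expect_identical(grp$group == "high", unname(votes == "poor"))
})

test_that("flipping one member's orientation shifts s by exactly one", {
  co <- small_cohort(seed = 24)
  sel <- apply_label_windows(co$clinical)
  ps <- compute_pathway_scores(co$expr, co$sets)
  model <- train_pianos(ps, sel, B = 5, seed = 2,
                        ktsp_config = list(k_grid = 1L))
  s0 <- predict_pianos(model, ps$scores)$score
  flipped <- model
  pr <- flipped$members[[1]]$pairs
  flipped$members[[1]]$pairs <- data.frame(greater = pr$lesser,
                                           lesser = pr$greater,
                                           delta = pr$delta, gamma = pr$gamma,
                                           stringsAsFactors = FALSE)
  s1 <- predict_pianos(flipped, ps$scores)$score
  # k = 1 members and continuous scores: each flip changes that vote
  expect_true(all(abs(s1 - s0) == 1))
})

test_that("cohort classification has no batch dependence", {
  fx <- small_cohort(seed = 25)
  sel <- apply_label_windows(fx$clinical)
  ps <- compute_pathway_scores(fx$expr, fx$sets)
  model <- train_pianos(ps, sel, B = 4, seed = 7,
                        ktsp_config = list(k_grid = c(1L, 3L)))
  all_pred <- classify_cohort(model, fx$expr, fx$sets)
  solo <- classify_cohort(model, fx$expr[, 5, drop = FALSE], fx$sets)
  expect_identical(solo$score, all_pred$score[5])

  shuf <- sample(ncol(fx$expr))
  resh <- classify_cohort(model, fx$expr[, shuf], fx$sets)
  expect_identical(resh$score, all_pred$score[shuf])

  mono <- classify_cohort(model, exp(fx$expr / 3), fx$sets)
  expect_identical(mono$group, all_pred$group)

  expect_error(classify_cohort(model, fx$expr,
                               gene_set_collection(list(zz = "g1"))),
               "lacks model pathway")
})
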