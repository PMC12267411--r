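# The ensemble trainer/predictor: prognosis-window label selection,
# B-fold resampling of k-TSP models on stratified 70/30 splits, retention of
# members whose held-out balanced accuracy exceeds the threshold, and
# vote-count risk scoring thresholded at tau into high/low risk groups.

#' Select poor/good prognosis training labels from survival windows
#'
#' A sample is labeled `poor` iff it recurred (event = 1) within
#' `poor_window` months, `good` iff it is event-free (event = 0) with
#' follow-up of at least `good_window` months, and `excluded` otherwise.
#' Defaults encode the 3-year / 5-year windows.
#'
#' @param clinical validated clinical table.
#' @param poor_window months (default 36).
#' @param good_window months (default 60).
#' @return object of class `training_selection`: data.frame-backed labels
#'   plus the windows and category counts.
#' @export
select_training_labels <- function(clinical, poor_window = 36,
                                   good_window = 60) {
  clinical <- as_clinical_table(clinical)
  check_number(poor_window, "poor_window", lower = 0)
  check_number(good_window, "good_window", lower = 0)
  label <- rep("excluded", nrow(clinical))
  label[clinical$event == 1L & clinical$time <= poor_window] <- "poor"
  label[clinical$event == 0L & clinical$time >= good_window] <- "good"
  counts <- c(poor = sum(label == "poor"), good = sum(label == "good"),
              excluded = sum(label == "excluded"))
  if (counts[["poor"]] == 0L) stop_named("no poor-prognosis samples selected")
  if (counts[["good"]] == 0L) stop_named("no good-prognosis samples selected")
  structure(list(labels = data.frame(sample_id = clinical$sample_id,
                                     label = label,
                                     stringsAsFactors = FALSE),
                 poor_window = poor_window, good_window = good_window,
                 counts = counts),
            class = "training_selection")
}

#' @export
print.training_selection <- function(x, ...) {
  cat(sprintf("training_selection: %d poor / %d good / %d excluded (windows %g/%g months)\n",
              x$counts[["poor"]], x$counts[["good"]], x$counts[["excluded"]],
              x$poor_window, x$good_window))
  invisible(x)
}

#' Balanced accuracy with poor as the positive class
#'
#' (sensitivity + specificity) / 2; the ensemble's member-retention
#' criterion.
#'
#' @param truth,predicted label vectors over the same samples, values
#'   `"poor"` / `"good"`.
#' @return a number in [0, 1].
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop_named("truth and predicted lengths differ")
  }
  if (!any(truth == "poor") || !any(truth == "good")) {
    stop_named("both classes must be present in truth")
  }
  sens <- mean(predicted[truth == "poor"] == "poor")
  spec <- mean(predicted[truth == "good"] == "good")
  (sens + spec) / 2
}

new_pianos_ensemble <- function(members, B, split_fraction, ba_threshold,
                                tau, seed, scoring = NULL, audit = NULL) {
  stopifnot(length(members) >= 1L, tau >= 0L, tau < length(members))
  structure(list(members = members, B = B, split_fraction = split_fraction,
                 ba_threshold = ba_threshold, tau = as.integer(tau),
                 seed = seed, scoring = scoring, audit = audit),
            class = "pianos_ensemble")
}

#' @export
print.pianos_ensemble <- function(x, ...) {
  cat(sprintf("pianos_ensemble: %d retained member(s) of B = %d (balanced accuracy > %.2f), tau = %d\n",
              length(x$members), x$B, x$ba_threshold, x$tau))
  invisible(x)
}

#' Pathways used by an ensemble's pair rules
#' @param model a `pianos_ensemble`.
#' @return character vector of pathway names.
#' @export
model_pathways <- function(model) {
  stopifnot(inherits(model, "pianos_ensemble"))
  unique(unlist(lapply(model$members,
                       function(m) c(m$pairs$greater, m$pairs$lesser))))
}

#' Train the resampling ensemble
#'
#' For each of `B` iterations (per-iteration RNG streams derived from the
#' master seed and the iteration index): stratified random `split_fraction` /
#' `1 - split_fraction` split by class, pathway screening and k-TSP training
#' on the training part, balanced accuracy on the held-out part; the member
#' is retained iff its held-out balanced accuracy strictly exceeds
#' `ba_threshold`. The vote threshold `tau` defaults to
#' `floor(#members / 2)` (a strict majority).
#'
#' @param scores a `pathway_scores` object or pathways x samples matrix for
#'   the training cohort.
#' @param selection a `training_selection`.
#' @param B resampling iterations (default 100).
#' @param split_fraction training share of each split (default 0.70).
#' @param ba_threshold retention cut, strict (default 0.6).
#' @param ktsp_config list with `k_grid`, `cv_folds`, `screen_m` (defaults
#'   `c(3,5,7,9)`, 5, 1000).
#' @param seed master RNG seed.
#' @param tau optional vote-threshold override.
#' @return a `pianos_ensemble` with a per-iteration audit table
#'   (iteration, seed, n_train, n_test, k, ba, retained).
#' @export
train_pianos <- function(scores, selection, B = 100L, split_fraction = 0.7,
                         ba_threshold = 0.6,
                         ktsp_config = list(), seed = 1L, tau = NULL) {
  if (inherits(scores, "pathway_scores")) {
    scoring <- list(alpha = scores$alpha, min_size = scores$min_size,
                    max_size = scores$max_size)
    scores <- scores$scores
  } else {
    scoring <- list(alpha = 0.25, min_size = 5L, max_size = 2000L)
  }
  stopifnot(inherits(selection, "training_selection"))
  B <- check_count(B, "B", lower = 1L)
  check_number(split_fraction, "split_fraction", lower = 0.1, upper = 0.95)
  check_number(ba_threshold, "ba_threshold", lower = 0, upper = 1)
  cfg <- utils::modifyList(list(k_grid = c(3L, 5L, 7L, 9L), cv_folds = 5L,
                                screen_m = 1000), ktsp_config)
  cfg$screen_m <- min(cfg$screen_m, nrow(scores))

  lab <- selection$labels
  lab <- lab[lab$label != "excluded", , drop = FALSE]
  lab <- lab[lab$sample_id %in% colnames(scores), , drop = FALSE]
  if (nrow(lab) == 0L) stop_named("no labeled samples found in the score matrix")
  X <- scores[, lab$sample_id, drop = FALSE]
  y <- lab$label
  need <- ceiling(1 / (1 - split_fraction))
  if (sum(y == "poor") < need || sum(y == "good") < need) {
    stop_named("each class needs at least %d samples for a %.0f/%.0f split",
               need, 100 * split_fraction, 100 * (1 - split_fraction))
  }

  members <- list()
  audit <- data.frame(iteration = seq_len(B), seed = NA_integer_,
                      n_train = NA_integer_, n_test = NA_integer_,
                      k = NA_integer_, ba = NA_real_, retained = FALSE)
  for (b in seq_len(B)) {
    iter_seed <- derive_seed(seed, b)
    set.seed(iter_seed)
    tr <- logical(length(y))
    for (cl in c("poor", "good")) {
      idx <- which(y == cl)
      n_tr <- min(max(round(split_fraction * length(idx)), 1L),
                  length(idx) - 1L)
      tr[sample(idx, n_tr)] <- TRUE
    }
    Xtr <- screen_features(X[, tr, drop = FALSE], y[tr], m = cfg$screen_m)
    fit <- tryCatch(
      train_ktsp(Xtr, y[tr], k_grid = cfg$k_grid, cv_folds = cfg$cv_folds,
                 seed = iter_seed),
      error = function(e) NULL)
    audit$seed[b] <- iter_seed
    audit$n_train[b] <- sum(tr)
    audit$n_test[b] <- sum(!tr)
    if (is.null(fit)) next
    pred <- predict_ktsp(fit, X[, !tr, drop = FALSE])
    ba <- balanced_accuracy(y[!tr], pred)
    audit$k[b] <- fit$k
    audit$ba[b] <- ba
    if (ba > ba_threshold) {
      fit$ba <- ba
      members[[length(members) + 1L]] <- fit
      audit$retained[b] <- TRUE
    }
  }
  if (length(members) == 0L) {
    stop_named("no model passed the retention filter (balanced accuracy > %.2f)",
               ba_threshold)
  }
  if (is.null(tau)) tau <- length(members) %/% 2L
  tau <- check_count(tau, "tau")
  new_pianos_ensemble(members, B = B, split_fraction = split_fraction,
                      ba_threshold = ba_threshold, tau = tau, seed = seed,
                      scoring = scoring, audit = audit)
}

#' Risk predictions from an ensemble
#'
#' The risk score `s` of a sample is the number of retained members voting
#' poor; the sample is `high` risk iff `s > tau` (strictly).
#'
#' @param model a `pianos_ensemble`.
#' @param scores named pathway-score vector or pathways x samples matrix.
#' @return data.frame: sample_id, score, group.
#' @export
predict_pianos <- function(model, scores) {
  stopifnot(inherits(model, "pianos_ensemble"))
  if (is.null(dim(scores))) {
    scores <- matrix(scores, ncol = 1L,
                     dimnames = list(names(scores), "sample"))
  }
  votes <- vapply(model$members,
                  function(m) predict_ktsp(m, scores) == "poor",
                  logical(ncol(scores)))
  if (ncol(scores) == 1L) votes <- matrix(votes, nrow = 1L)
  s <- as.integer(rowSums(votes))
  data.frame(sample_id = colnames(scores), score = s,
             group = ifelse(s > model$tau, "high", "low"),
             stringsAsFactors = FALSE)
}

#' End-to-end cohort classification from raw expression
#'
#' Computes enrichment scores for exactly the pathways the model uses
#' (against the full gene universe of `expr`), then applies
#' [predict_pianos()]. Each sample's prediction depends only on its own
#' column.
#'
#' @param model a `pianos_ensemble`.
#' @param expr expression matrix (genes x samples), any monotone scale.
#' @param sets `gene_set_collection` containing every model pathway.
#' @return data.frame: sample_id, score, group.
#' @export
classify_cohort <- function(model, expr, sets) {
  stopifnot(inherits(model, "pianos_ensemble"),
            inherits(sets, "gene_set_collection"))
  expr <- as_expression_matrix(expr)
  need <- model_pathways(model)
  miss <- setdiff(need, names(sets$sets))
  if (length(miss) > 0L) {
    stop_named("gene set collection lacks model pathway '%s'", miss[1L])
  }
  sub <- gene_set_collection(sets$sets[need], sets$descriptions[need])
  alpha <- model$scoring$alpha %||% 0.25
  # no size filter at prediction time: a pathway depleted by gene loss is
  # rescored on whatever genes remain; a pathway with no genes left gets an
  # undefined (NA) score, which every pair comparison treats as a tie and
  # therefore a conservative low-risk vote
  ps <- compute_pathway_scores(expr, sub, alpha = alpha,
                               min_size = 1L, max_size = Inf)
  gone <- setdiff(need, rownames(ps$scores))
  if (length(gone) == length(need)) {
    stop_named("every model pathway (e.g. '%s') has no genes left in the expression matrix",
               gone[1L])
  }
  scores <- ps$scores
  if (length(gone) > 0L) {
    warning(sprintf("%d model pathway(s) have no genes left and score NA: %s",
                    length(gone),
                    paste(utils::head(gone, 3L), collapse = ", ")),
            call. = FALSE)
    scores <- rbind(scores,
                    matrix(NA_real_, length(gone), ncol(scores),
                           dimnames = list(gone, colnames(scores))))
  }
  predict_pianos(model, scores)
}
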