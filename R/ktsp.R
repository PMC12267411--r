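# k-Top-Scoring-Pairs over pathway scores. A pair rule compares two pathway
# scores *within* a sample; the class whose typical ordering matches wins the
# pair's vote. All statistics are order-based, so the classifier inherits the
# monotone-invariance of the scoring step.

# C-locale string sort, locale-independent, used for deterministic tie-breaks
sort_c <- function(x) sort(x, method = "radix")

#' Primary pair statistic
#'
#' \eqn{\Delta_{ij} = | P(score_i < score_j \mid poor) - P(score_i < score_j
#' \mid good) |}, with equality counted as "not less than".
#'
#' @param scores_i,scores_j per-sample score vectors of the two pathways.
#' @param labels per-sample class labels, values `"poor"` / `"good"`.
#' @return Delta in [0, 1].
#' @export
pair_delta <- function(scores_i, scores_j, labels) {
  cls <- check_labels(labels, length(scores_i))
  lt <- scores_i < scores_j
  abs(mean(lt[cls == "poor"]) - mean(lt[cls == "good"]))
}

#' Secondary (tie-break) pair statistic
#'
#' \eqn{\gamma_{ij} = | mean(r_i - r_j \mid poor) - mean(r_i - r_j \mid good)
#' |} where \eqn{r} are within-sample ranks of the pathway score matrix
#' (rank inputs keep gamma scale-free).
#'
#' @param ranks_i,ranks_j per-sample within-sample score ranks of the two
#'   pathways.
#' @param labels per-sample class labels.
#' @return gamma >= 0.
#' @export
pair_gamma <- function(ranks_i, ranks_j, labels) {
  cls <- check_labels(labels, length(ranks_i))
  d <- ranks_i - ranks_j
  abs(mean(d[cls == "poor"]) - mean(d[cls == "good"]))
}

check_labels <- function(labels, n) {
  labels <- as.character(labels)
  if (length(labels) != n) stop_named("labels length does not match scores")
  if (!all(labels %in% c("poor", "good"))) {
    stop_named("labels must be 'poor' or 'good'")
  }
  if (!any(labels == "poor") || !any(labels == "good")) {
    stop_named("both classes must be nonempty")
  }
  labels
}

#' Screen pathways by between-class rank statistic
#'
#' Keeps the `m` pathways with the largest absolute standardized two-sample
#' (Wilcoxon) rank statistic between classes, a tractability device for the
#' quadratic pair search. Ties in the statistic break deterministically by
#' pathway name.
#'
#' @param scores pathways x samples score matrix.
#' @param labels per-sample class labels.
#' @param m number of pathways to keep (>= 2; `Inf` disables screening).
#' @return the reduced score matrix (row subset, original row order kept).
#' @export
screen_features <- function(scores, labels, m = 1000) {
  labels <- check_labels(labels, ncol(scores))
  if (is.finite(m)) m <- check_count(m, "m")
  if (m < 2) stop_named("m must be at least 2 (pairs need two features)")
  P <- nrow(scores)
  if (m >= P) {
    if (is.finite(m) && m > P) {
      warning(sprintf("m = %d exceeds %d pathways; keeping all", m, P),
              call. = FALSE)
    }
    return(scores)
  }
  poor <- labels == "poor"
  n1 <- sum(poor); n2 <- sum(!poor); n <- n1 + n2
  z <- apply(scores, 1L, function(v) {
    u <- sum(rank(v)[poor]) - n1 * (n1 + 1) / 2
    abs(u - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  })
  ord <- order(-z, match(rownames(scores), sort_c(rownames(scores))))
  keep <- sort(ord[seq_len(m)])
  scores[keep, , drop = FALSE]
}

# All pathway pairs with Delta > 0, ranked (Delta desc, gamma desc,
# lexicographic names). Orientation: `greater` > `lesser` votes poor, chosen
# so the ordering more frequent in the poor class casts the poor vote.
pair_candidates <- function(scores, labels) {
  labels <- check_labels(labels, ncol(scores))
  P <- nrow(scores)
  nms <- rownames(scores)
  if (is.null(nms)) stop_named("score matrix must have pathway rownames")
  poor <- labels == "poor"
  np <- sum(poor); ng <- sum(!poor)

  rk <- apply(scores, 2L, rank)          # within-sample score ranks
  ap <- rowMeans(rk[, poor, drop = FALSE])
  ag <- rowMeans(rk[, !poor, drop = FALSE])

  # P(score_i < score_j | class) for all pairs, strict (< counts, ties don't)
  cnt <- .pair_lt_counts(scores, poor)
  up <- upper.tri(cnt$poor)
  ii <- row(cnt$poor)[up]; jj <- col(cnt$poor)[up]
  lp <- cnt$poor[up] / np
  lg <- cnt$good[up] / ng
  delta <- abs(lp - lg)
  keep <- delta > 0
  if (!any(keep)) return(NULL)
  ii <- ii[keep]; jj <- jj[keep]
  lp <- lp[keep]; lg <- lg[keep]; delta <- delta[keep]
  gamma <- abs((ap[ii] - ap[jj]) - (ag[ii] - ag[jj]))
  # orientation: i<j more frequent in poor  =>  score_j > score_i votes poor
  greater <- ifelse(lp > lg, nms[jj], nms[ii])
  lesser  <- ifelse(lp > lg, nms[ii], nms[jj])
  key <- match(nms, sort_c(nms))
  ord <- order(-delta, -gamma, pmin(key[ii], key[jj]), pmax(key[ii], key[jj]))
  data.frame(greater = greater[ord], lesser = lesser[ord],
             delta = delta[ord], gamma = gamma[ord],
             stringsAsFactors = FALSE)
}

# Greedy pathway-disjoint selection from the ranked candidate list.
greedy_disjoint <- function(candidates, max_pairs) {
  used <- character(0)
  take <- integer(0)
  for (r in seq_len(nrow(candidates))) {
    a <- candidates$greater[r]; b <- candidates$lesser[r]
    if (a %in% used || b %in% used) next
    take <- c(take, r)
    used <- c(used, a, b)
    if (length(take) >= max_pairs) break
  }
  candidates[take, , drop = FALSE]
}

new_ktsp_model <- function(pairs, k, tie_policy = "good", ba = NA_real_) {
  stopifnot(k %% 2L == 1L, nrow(pairs) == k)
  structure(list(pairs = pairs, k = as.integer(k), tie_policy = tie_policy,
                 ba = ba),
            class = "ktsp_model")
}

#' @export
print.ktsp_model <- function(x, ...) {
  cat(sprintf("ktsp_model: k = %d pair(s)\n", x$k))
  for (i in seq_len(nrow(x$pairs))) {
    cat(sprintf("  %s > %s  -> poor  (delta %.3f, gamma %.3f)\n",
                x$pairs$greater[i], x$pairs$lesser[i],
                x$pairs$delta[i], x$pairs$gamma[i]))
  }
  invisible(x)
}

largest_odd_at_most <- function(x) {
  x <- as.integer(x)
  if (x < 1L) 0L else if (x %% 2L == 1L) x else x - 1L
}

#' Train a k-TSP classifier on labeled pathway scores
#'
#' Candidate pairs are ranked by (Delta descending, gamma descending,
#' lexicographic pathway names) and selected greedily under the
#' pathway-disjointness constraint. `k` is chosen from `k_grid` by seeded
#' stratified cross-validated balanced accuracy (ties favor the smaller k);
#' if fewer disjoint informative pairs exist than the chosen k, the largest
#' available odd number is used.
#'
#' @param scores pathways x samples score matrix (rownames = pathway names).
#' @param labels per-sample class labels (`"poor"` / `"good"`).
#' @param k_grid odd candidate values for k (default `c(3, 5, 7, 9)`).
#' @param cv_folds stratified CV folds for the k choice (default 5; reduced
#'   automatically if a class is smaller).
#' @param seed RNG seed for fold assignment.
#' @return a `ktsp_model`.
#' @export
train_ktsp <- function(scores, labels, k_grid = c(3L, 5L, 7L, 9L),
                       cv_folds = 5L, seed = 1L) {
  if (inherits(scores, "pathway_scores")) scores <- scores$scores
  labels <- check_labels(labels, ncol(scores))
  if (sum(labels == "poor") < 2L || sum(labels == "good") < 2L) {
    stop_named("need at least 2 samples per class")
  }
  if (any(k_grid %% 2 == 0) || any(k_grid < 1)) {
    stop_named("k_grid must contain odd positive integers")
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  cand <- pair_candidates(scores, labels)
  if (is.null(cand)) stop_named("no discriminating pairs (all Delta = 0)")

  chosen_k <- k_grid[1L]
  nmin <- min(table(labels))
  folds <- min(cv_folds, nmin)
  if (length(k_grid) > 1L && folds >= 2L) {
    set.seed(derive_seed(seed, 0L))
    fold_id <- integer(ncol(scores))
    for (cl in c("poor", "good")) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    ba_k <- matrix(NA_real_, nrow = folds, ncol = length(k_grid))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      cf <- pair_candidates(scores[, tr, drop = FALSE], labels[tr])
      if (is.null(cf)) next
      gl <- greedy_disjoint(cf, max(k_grid))
      for (ki in seq_along(k_grid)) {
        k_eff <- largest_odd_at_most(min(k_grid[ki], nrow(gl)))
        if (k_eff < 1L) next
        m <- new_ktsp_model(gl[seq_len(k_eff), , drop = FALSE], k_eff)
        pred <- predict_ktsp(m, scores[, !tr, drop = FALSE])
        ba_k[f, ki] <- balanced_accuracy(labels[!tr], pred)
      }
    }
    mean_ba <- colMeans(ba_k, na.rm = TRUE)
    if (any(is.finite(mean_ba))) {
      chosen_k <- k_grid[which.max(round(mean_ba, 12))]  # ties -> smaller k
    }
  }
  gl <- greedy_disjoint(cand, chosen_k)
  k_eff <- largest_odd_at_most(nrow(gl))
  new_ktsp_model(gl[seq_len(k_eff), , drop = FALSE], k_eff)
}

#' Predict with a k-TSP model
#'
#' Each pair votes poor iff `score[greater] > score[lesser]` strictly within
#' the sample; a tie votes good (the fixed, risk-conservative tie policy).
#' The majority of the k (odd) votes decides.
#'
#' @param model a `ktsp_model`.
#' @param sample_scores named pathway-score vector for one sample, or a
#'   pathways x samples matrix.
#' @return character vector of `"poor"` / `"good"` votes, one per sample.
#' @export
predict_ktsp <- function(model, sample_scores) {
  stopifnot(inherits(model, "ktsp_model"))
  if (is.null(dim(sample_scores))) {
    sample_scores <- matrix(sample_scores, ncol = 1L,
                            dimnames = list(names(sample_scores), "sample"))
  }
  need <- unique(c(model$pairs$greater, model$pairs$lesser))
  miss <- setdiff(need, rownames(sample_scores))
  if (length(miss) > 0L) {
    stop_named("pathway '%s' required by the model is missing from the scores",
               miss[1L])
  }
  cmp <- sample_scores[model$pairs$greater, , drop = FALSE] >
    sample_scores[model$pairs$lesser, , drop = FALSE]
  cmp[is.na(cmp)] <- FALSE     # undefined score: treated as a tie -> good
  poor_votes <- colSums(cmp)
  out <- ifelse(poor_votes > model$k / 2, "poor", "good")
  stats::setNames(as.character(out), colnames(sample_scores))
}
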