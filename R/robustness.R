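# Stress protocols that operationalize "platform independent, normalization
# free": random input-gene deletion curves, and per-sample strictly monotone
# transform checks that must leave every prediction unchanged.

# strictly increasing random map applied to one sample's values; ties map to
# ties, so ranks (average and first-occurrence positions) are preserved
random_monotone_map <- function(x, seed) {
  set.seed(seed)
  u <- sort(unique(x))
  v <- cumsum(stats::runif(length(u), min = 0.05, max = 1))
  v[match(x, u)]
}

transform_sample <- function(x, family, seed) {
  set.seed(seed)
  switch(family,
         affine = stats::runif(1, 0.5, 3) * x + stats::runif(1, -5, 5),
         exp = exp(x / stats::runif(1, 1, 3)),
         quantile = random_monotone_map(x, seed),
         stop_named("unknown or non-monotone transform family '%s'", family))
}

#' Monotone-transform invariance check
#'
#' Applies seeded per-sample strictly increasing transforms (affine with
#' positive slope, exponential, random rank-preserving quantile maps) to the
#' expression matrix and reports per-transform prediction agreement with the
#' untransformed baseline. Because the whole pipeline uses only within-sample
#' ranks, agreement is exactly 1 by construction; this harness verifies the
#' guarantee end to end.
#'
#' @param model a `pianos_ensemble`.
#' @param expr expression matrix.
#' @param sets `gene_set_collection`.
#' @param families transform families to cycle through
#'   (`"affine"`, `"exp"`, `"quantile"`).
#' @param n_transforms number of transforms (default 100).
#' @param seed RNG seed.
#' @return object of class `shift_report`: per-transform agreement table,
#'   per-sample agreement vector, overall mean agreement.
#' @export
monotone_shift_check <- function(model, expr, sets,
                                 families = c("affine", "exp", "quantile"),
                                 n_transforms = 100L, seed = 1L) {
  expr <- as_expression_matrix(expr)
  bad <- setdiff(families, c("affine", "exp", "quantile"))
  if (length(bad) > 0L) {
    stop_named("unknown or non-monotone transform family '%s'", bad[1L])
  }
  n_transforms <- check_count(n_transforms, "n_transforms", lower = 1L)
  baseline <- classify_cohort(model, expr, sets)
  per_sample <- stats::setNames(numeric(ncol(expr)), colnames(expr))
  rows <- data.frame(transform = seq_len(n_transforms),
                     family = rep_len(families, n_transforms),
                     agreement = NA_real_)
  for (t in seq_len(n_transforms)) {
    fam <- rows$family[t]
    ex <- expr
    for (j in seq_len(ncol(expr))) {
      ex[, j] <- transform_sample(expr[, j], fam, derive_seed(seed, t, j))
    }
    pred <- classify_cohort(model, ex, sets)
    same <- pred$group == baseline$group
    rows$agreement[t] <- mean(same)
    per_sample <- per_sample + same
  }
  structure(list(per_transform = rows,
                 per_sample = per_sample / n_transforms,
                 overall = mean(rows$agreement),
                 seed = seed),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("monotone-transform agreement: %.4f over %d transforms (min per-sample %.4f)\n",
              x$overall, nrow(x$per_transform), min(x$per_sample)))
  invisible(x)
}

#' Random gene-dropout robustness curves
#'
#' For each deletion fraction `f` and replicate, deletes `floor(f * G)` genes
#' uniformly at random (seeded by master seed, fraction index and replicate),
#' rescores the surviving genes, re-predicts, and records C-index, D-index
#' and prediction agreement with the full-input baseline. `f = 0` reproduces
#' the baseline exactly.
#'
#' @param model a `pianos_ensemble`.
#' @param expr expression matrix.
#' @param sets `gene_set_collection`.
#' @param clinical clinical table for the same samples.
#' @param fractions deletion fractions in [0, 1) (default 0, 0.1, ..., 0.9).
#' @param R replicates per fraction (default 10).
#' @param seed RNG seed.
#' @return object of class `dropout_curve`: tidy `results` data.frame
#'   (fraction, replicate, c_index, d_index, agreement) plus the baseline
#'   metrics and predictions.
#' @export
gene_dropout_eval <- function(model, expr, sets, clinical,
                              fractions = seq(0, 0.9, by = 0.1), R = 10L,
                              seed = 1L) {
  expr <- as_expression_matrix(expr)
  clinical <- as_clinical_table(clinical)
  R <- check_count(R, "R", lower = 1L)
  if (any(fractions < 0 | fractions >= 1)) {
    stop_named("deletion fractions must lie in [0, 1)")
  }
  G <- nrow(expr)
  eval_once <- function(ex) {
    # at high deletion fractions some model pathways may score NA (no genes
    # left); the per-pathway warnings would repeat for every replicate
    pred <- suppressWarnings(classify_cohort(model, ex, sets))
    risk <- stats::setNames(pred$score, pred$sample_id)
    ci <- c_index(risk, clinical, boot_B = 0L)$c_index
    di <- tryCatch(d_index(risk, clinical)$d_index, error = function(e) NA_real_)
    list(pred = pred, c_index = ci, d_index = di)
  }
  base <- eval_once(expr)
  rows <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n_del <- floor(f * G)
    for (r in seq_len(R)) {
      if (n_del == 0L) {
        res <- base
      } else {
        set.seed(derive_seed(seed, fi, r))
        drop_idx <- sample.int(G, n_del)
        res <- eval_once(expr[-drop_idx, , drop = FALSE])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, replicate = r,
        c_index = res$c_index, d_index = res$d_index,
        agreement = mean(res$pred$group == base$pred$group))
    }
  }
  structure(list(results = do.call(rbind, rows),
                 baseline = list(c_index = base$c_index,
                                 d_index = base$d_index,
                                 predictions = base$pred),
                 R = R, seed = seed),
            class = "dropout_curve")
}

#' Per-fraction summary of a dropout curve
#' @param object a `dropout_curve`.
#' @param ... unused.
#' @return data.frame of replicate means and sds per deletion fraction.
#' @export
summary.dropout_curve <- function(object, ...) {
  res <- object$results
  out <- do.call(rbind, lapply(split(res, res$fraction), function(d) {
    data.frame(fraction = d$fraction[1L],
               c_index = mean(d$c_index, na.rm = TRUE),
               c_index_sd = stats::sd(d$c_index),
               d_index = mean(d$d_index, na.rm = TRUE),
               agreement = mean(d$agreement),
               agreement_sd = stats::sd(d$agreement))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.dropout_curve <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("dropout_curve: %d fractions x %d replicates (baseline C-index %.4f)\n",
              nrow(s), x$R, x$baseline$c_index))
  print(s, digits = 4)
  invisible(x)
}
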