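# Evaluation battery for risk predictions against right-censored survival:
# Harrell concordance, the D-index (normal-scores proportional-hazards
# coefficient), Kaplan-Meier / log-rank, fixed-horizon recurrence AUC, and
# the generic weighted-sum scorer used for published comparator signatures.

align_clinical <- function(risk, clinical) {
  clinical <- as_clinical_table(clinical)
  if (!is.null(names(risk))) {
    miss <- setdiff(names(risk), clinical$sample_id)
    if (length(miss) > 0L) {
      stop_named("sample '%s' has a risk value but no clinical record", miss[1L])
    }
    clinical <- clinical[match(names(risk), clinical$sample_id), , drop = FALSE]
  } else if (length(risk) != nrow(clinical)) {
    stop_named("risk length (%d) does not match clinical rows (%d)",
               length(risk), nrow(clinical))
  }
  list(risk = as.numeric(risk), time = clinical$time, event = clinical$event)
}

cindex_core <- function(risk, time, event) {
  n <- length(risk)
  cmp <- outer(time, time, "<") & matrix(event == 1L, n, n)  # i fails first
  diag(cmp) <- FALSE
  gt <- outer(risk, risk, ">")
  eq <- outer(risk, risk, "==")
  n_comp <- sum(cmp)
  if (n_comp == 0L) return(c(cindex = NA_real_, n = 0))
  c(cindex = (sum(gt & cmp) + 0.5 * sum(eq & cmp)) / n_comp, n = n_comp)
}

#' Harrell's concordance index
#'
#' A pair (i, j) is comparable iff `t_i < t_j` and sample i had the event;
#' it is concordant iff `risk_i > risk_j`, and risk ties credit 0.5. The
#' confidence interval comes from a seeded percentile bootstrap over samples.
#'
#' @param risk numeric risk per sample (optionally named by sample id).
#' @param clinical clinical table (sample_id, time, event).
#' @param boot_B bootstrap replicates for the CI (default 1000; 0 skips it).
#' @param seed bootstrap RNG seed.
#' @return object of class `concordance_result`: c_index, n_comparable_pairs,
#'   ci_low/ci_high, boot_B, seed.
#' @export
c_index <- function(risk, clinical, boot_B = 1000L, seed = 1L) {
  d <- align_clinical(risk, clinical)
  if (sum(d$event) < 1L) stop_named("need at least one event")
  est <- cindex_core(d$risk, d$time, d$event)
  if (est[["n"]] == 0) stop_named("no comparable pairs")
  ci <- c(NA_real_, NA_real_)
  if (boot_B > 0L) {
    set.seed(derive_seed(seed, 1L))
    n <- length(d$risk)
    boots <- vapply(seq_len(boot_B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cindex_core(d$risk[idx], d$time[idx], d$event[idx])[["cindex"]]
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                                 type = 7))
  }
  structure(list(c_index = est[["cindex"]],
                 n_comparable_pairs = as.integer(est[["n"]]),
                 ci_low = ci[1L], ci_high = ci[2L],
                 boot_B = boot_B, seed = seed),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("C-index %.4f (%d comparable pairs", x$c_index,
              x$n_comparable_pairs))
  if (!is.na(x$ci_low)) cat(sprintf("; 95%% CI %.4f-%.4f", x$ci_low, x$ci_high))
  cat(")\n")
  invisible(x)
}

# Single-covariate Cox partial likelihood (Breslow ties), Newton-Raphson.
# Returns beta and its standard error; errors on non-convergence or a
# monotone likelihood (perfect separation).
cox_newton <- function(x, time, event, tol = 1e-8, max_iter = 100L) {
  ord <- order(time)
  x <- x[ord]; event <- event[ord]; time <- time[ord]
  n <- length(x)
  # first index of each tied-time block: risk set of i = indices first(i)..n
  first <- match(time, time)
  beta <- 0
  for (it in seq_len(max_iter)) {
    e <- exp(beta * x)
    s0 <- rev(cumsum(rev(e)))
    s1 <- rev(cumsum(rev(e * x)))
    s2 <- rev(cumsum(rev(e * x^2)))
    ev <- event == 1L
    f <- first[ev]
    U <- sum(x[ev] - s1[f] / s0[f])
    I <- sum(s2[f] / s0[f] - (s1[f] / s0[f])^2)
    if (!is.finite(U) || !is.finite(I) || I <= 0) {
      stop_named("monotone partial likelihood (perfect separation) at beta = %.3f",
                 beta)
    }
    step <- U / I
    beta <- beta + step
    if (abs(beta) > 30) {
      stop_named("monotone partial likelihood (perfect separation): |beta| diverges")
    }
    if (abs(step) < tol) {
      return(list(beta = beta, se = 1 / sqrt(I), iterations = it))
    }
  }
  stop_named("Cox partial-likelihood fit did not converge in %d iterations",
             max_iter)
}

#' D-index: prognostic separation as a robust hazard ratio
#'
#' Risk values are mapped to normal scores via mid-ranks,
#' \eqn{z_i = \Phi^{-1}((r_i - 3/8)/(n + 1/4))}, scaled by
#' \eqn{\kappa = \sqrt{8/\pi}}, and a proportional-hazards model is fit on
#' \eqn{z/\kappa} by Newton-Raphson on the Breslow partial likelihood. The
#' D-index is \eqn{exp(\hat\beta)}; 1 means no prognostic separation.
#'
#' @param risk numeric risk per sample (>= 2 distinct values).
#' @param clinical clinical table.
#' @return object of class `d_index_result`: d_index, beta, se_beta,
#'   ci_low/ci_high (Wald), kappa.
#' @export
d_index <- function(risk, clinical) {
  d <- align_clinical(risk, clinical)
  if (length(unique(d$risk)) < 2L) stop_named("need at least 2 distinct risk values")
  if (sum(d$event) < 1L) stop_named("need at least one event")
  n <- length(d$risk)
  r <- rank(d$risk, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  kappa <- sqrt(8 / pi)
  fit <- cox_newton(z / kappa, d$time, d$event)
  ci <- fit$beta + c(-1, 1) * stats::qnorm(0.975) * fit$se
  structure(list(d_index = exp(fit$beta), beta = fit$beta,
                 se_beta = fit$se,
                 ci_low = exp(ci[1L]), ci_high = exp(ci[2L]),
                 kappa = kappa),
            class = "d_index_result")
}

#' @export
print.d_index_result <- function(x, ...) {
  cat(sprintf("D-index %.3f (95%% CI %.3f-%.3f)\n",
              x$d_index, x$ci_low, x$ci_high))
  invisible(x)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survivor curves per risk group (via `survival::survfit`)
#' and the 1-df log-rank chi-square with its p-value (via
#' `survival::survdiff`).
#'
#' @param groups per-sample group labels, `"high"` / `"low"` (optionally
#'   named by sample id).
#' @param clinical clinical table.
#' @return object of class `km_result`: per-group step functions
#'   (data.frame: group, time, n_risk, n_event, surv), log-rank `chisq` and
#'   `p_value`.
#' @export
km_logrank <- function(groups, clinical) {
  clinical <- as_clinical_table(clinical)
  if (!is.null(names(groups))) {
    clinical <- clinical[match(names(groups), clinical$sample_id), , drop = FALSE]
  } else if (length(groups) != nrow(clinical)) {
    stop_named("groups length does not match clinical rows")
  }
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) {
    stop_named("need two nonempty groups for the log-rank test")
  }
  sv <- survival::Surv(clinical$time, clinical$event)
  fit <- survival::survfit(sv ~ groups)
  strata_names <- sub("^groups=", "", names(fit$strata))
  curve <- data.frame(group = rep(strata_names, fit$strata),
                      time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      stringsAsFactors = FALSE)
  sd <- survival::survdiff(sv ~ groups)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  structure(list(curves = curve, chisq = unname(sd$chisq), p_value = p),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("log-rank chi-square %.3f, p = %.3g\n", x$chisq, x$p_value))
  invisible(x)
}

#' Fixed-horizon recurrence AUC
#'
#' Positives are samples with an event at or before `horizon` months;
#' negatives are samples still at risk (event-free) at the horizon; samples
#' censored before the horizon without an event are excluded (and counted).
#' The AUC is the Mann-Whitney probability with ties credited 0.5.
#'
#' @param risk numeric risk per sample.
#' @param clinical clinical table.
#' @param horizon months (default 36 = 3 years).
#' @return object of class `roc_result`: auc, horizon, n_pos, n_neg,
#'   n_excluded.
#' @export
auc_horizon <- function(risk, clinical, horizon = 36) {
  d <- align_clinical(risk, clinical)
  check_number(horizon, "horizon", lower = 0)
  pos <- d$event == 1L & d$time <= horizon
  neg <- !pos & d$time >= horizon
  excl <- !pos & !neg
  if (!any(pos)) stop_named("no positive samples (event within horizon)")
  if (!any(neg)) stop_named("no negative samples (event-free at horizon)")
  rp <- d$risk[pos]; rn <- d$risk[neg]
  gt <- outer(rp, rn, ">"); eq <- outer(rp, rn, "==")
  auc <- (sum(gt) + 0.5 * sum(eq)) / (length(rp) * length(rn))
  structure(list(auc = auc, horizon = horizon,
                 n_pos = sum(pos), n_neg = sum(neg),
                 n_excluded = sum(excl)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f at %g months (%d pos / %d neg, %d excluded)\n",
              x$auc, x$horizon, x$n_pos, x$n_neg, x$n_excluded))
  invisible(x)
}

#' Weighted-sum signature scoring
#'
#' The generic scorer used by published comparator signatures: each sample's
#' score is the dot product of the signature's gene weights with that
#' sample's expression over the genes present; absent genes are skipped and
#' reported in the `coverage` attribute.
#'
#' @param weights named numeric vector of gene weights.
#' @param expr expression matrix (genes x samples).
#' @return named numeric score per sample, with attribute `coverage`
#'   (list: n_used, n_missing, missing gene ids).
#' @export
score_weighted_signature <- function(weights, expr) {
  expr <- as_expression_matrix(expr)
  if (is.null(names(weights))) stop_named("weights must be named by gene id")
  present <- intersect(names(weights), rownames(expr))
  if (length(present) == 0L) {
    stop_named("no signature gene present in the expression matrix")
  }
  out <- colSums(expr[present, , drop = FALSE] * weights[present])
  attr(out, "coverage") <- list(n_used = length(present),
                                n_missing = length(weights) - length(present),
                                missing = setdiff(names(weights), present))
  out
}
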