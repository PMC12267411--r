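# Independent oracle implementations, deliberately written as plain
# enumerations so they share no code path with the package internals.

# Explicit running-sum enrichment score: walk the descending-expression list
# and accumulate the weighted in-set ECDF minus the uniform out-of-set ECDF.
brute_ssgsea <- function(x, genes, alpha = 0.25) {
  N <- length(x)
  ord <- order(-x)                      # stable: ties keep original order
  avg <- rank(-x, ties.method = "average")
  in_set <- names(x)[ord] %in% genes
  w <- (N - avg[ord] + 1)^alpha
  p_in <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
  p_out <- cumsum(!in_set) / (N - sum(in_set))
  sum(p_in - p_out)
}

# Naive per-pair enumeration of the TSP statistics, sorted and greedily
# filtered exactly as the contract states.
brute_pair_list <- function(X, labels) {
  nms <- rownames(X)
  P <- nrow(X)
  rk <- apply(X, 2, rank)
  rows <- list()
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      lp <- mean(X[i, labels == "poor"] < X[j, labels == "poor"])
      lg <- mean(X[i, labels == "good"] < X[j, labels == "good"])
      delta <- abs(lp - lg)
      if (delta <= 0) next
      gamma <- abs(mean(rk[i, labels == "poor"] - rk[j, labels == "poor"]) -
                     mean(rk[i, labels == "good"] - rk[j, labels == "good"]))
      rows[[length(rows) + 1]] <- data.frame(
        greater = if (lp > lg) nms[j] else nms[i],
        lesser = if (lp > lg) nms[i] else nms[j],
        delta = delta, gamma = gamma, i = i, j = j,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  cand <- do.call(rbind, rows)
  key <- match(nms, sort(nms, method = "radix"))
  cand[order(-cand$delta, -cand$gamma,
             pmin(key[cand$i], key[cand$j]),
             pmax(key[cand$i], key[cand$j])), ]
}

brute_greedy <- function(cand, max_pairs) {
  used <- character(0)
  out <- NULL
  for (r in seq_len(nrow(cand))) {
    if (cand$greater[r] %in% used || cand$lesser[r] %in% used) next
    out <- rbind(out, cand[r, c("greater", "lesser", "delta", "gamma")])
    used <- c(used, cand$greater[r], cand$lesser[r])
    if (nrow(out) >= max_pairs) break
  }
  out
}

# Hand log-rank enumeration: loop over distinct event times, accumulate
# observed minus expected events in group 1 and the hypergeometric variance.
brute_logrank_chisq <- function(group, time, event) {
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == group[order(group)][1])
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == group[order(group)][1])
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Small labeled score matrix with a controllable planted pair, for k-TSP
# unit tests.
random_scores <- function(P, n_poor, n_good, seed) {
  set.seed(seed)
  X <- matrix(rnorm(P * (n_poor + n_good)), nrow = P,
              dimnames = list(sprintf("P%03d", seq_len(P)),
                              sprintf("S%03d", seq_len(n_poor + n_good))))
  list(X = X, labels = rep(c("poor", "good"), c(n_poor, n_good)))
}

# Small end-to-end cohort for fast ensemble/robustness unit tests: a
# low-noise regime (low baseline hazard, large hazard ratio) so prognosis
# labels track the latent class closely even at small n.
small_cohort <- function(seed = 1, n = 160, G = 300, P = 30, D = 4) {
  simulate_cohort(simulation_config(G = G, P = P, D = D, n = n,
                                    size_range = c(8L, 20L),
                                    lambda0 = 0.004, hr = 8, seed = seed))
}

# The reference study conditions (2000 genes, 200 pathways, 10 prognostic,
# delta = 1, HR 3, 300 + 300 samples, B = 100), trained once per test
# session and cached.
.fixture_env <- new.env(parent = emptyenv())
default_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  co <- simulate_cohort(simulation_config(n = 600L, seed = 1L))
  sp <- split_cohort(co, 300L)
  sel <- apply_label_windows(sp$train$clinical)
  ps <- compute_pathway_scores(sp$train$expr, sp$train$sets)
  model <- train_pianos(ps, sel, B = 100L, seed = 1L)
  pred <- classify_cohort(model, sp$test$expr, sp$test$sets)
  .fixture_env$fx <- list(split = sp, selection = sel, model = model,
                          pred = pred)
  .fixture_env$fx
}
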