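# Synthetic cohort generator: expression with pathway-structured class
# effects and class-dependent censored survival, so that training,
# evaluation and robustness protocols are exercisable without any external
# cohort.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 2000 genes, 200
#' pathways of 15-50 genes, 10 prognostic pathways shifted by delta = 1
#' log-expression SD in the poor class, equal class prevalence, exponential
#' survival with class hazard ratio 3, and uniform censoring over 180 months
#' (about 30% of observations censored at these rates).
#'
#' @param G number of genes.
#' @param P number of pathways.
#' @param size_range pathway size range (genes per set, inclusive).
#' @param D number of prognostic pathways (class-shifted).
#' @param delta mean expression shift, in baseline SD units, applied to
#'   prognostic-pathway genes of poor-class samples.
#' @param prevalence poor-class prevalence, in (0, 1).
#' @param n number of samples.
#' @param lambda0 baseline exponential hazard per month (good class).
#' @param hr hazard ratio of the poor class relative to the good class.
#' @param c_max censoring horizon: censoring times ~ Uniform(0, c_max).
#' @param platform_distortion apply a random per-sample strictly monotone
#'   distortion emulating platform differences (default FALSE).
#' @param seed RNG seed.
#' @return validated config list of class `simulation_config`.
#' @export
simulation_config <- function(G = 2000L, P = 200L, size_range = c(15L, 50L),
                              D = 10L, delta = 1.0, prevalence = 0.5,
                              n = 300L, lambda0 = 0.01, hr = 3,
                              c_max = 180, platform_distortion = FALSE,
                              seed = 1L) {
  G <- check_count(G, "G", lower = 2L)
  P <- check_count(P, "P", lower = 1L)
  D <- check_count(D, "D", lower = 0L)
  n <- check_count(n, "n", lower = 1L)
  check_number(delta, "delta", lower = 0)
  check_number(prevalence, "prevalence")
  if (prevalence <= 0 || prevalence >= 1) {
    stop_named("prevalence must be strictly between 0 and 1")
  }
  check_number(lambda0, "lambda0")
  if (lambda0 <= 0) stop_named("lambda0 must be positive")
  check_number(hr, "hr")
  if (hr <= 0) stop_named("hr must be positive")
  check_number(c_max, "c_max")
  if (c_max <= 0) stop_named("c_max must be positive")
  if (length(size_range) != 2L || size_range[1L] > size_range[2L]) {
    stop_named("size_range must be c(min, max) with min <= max")
  }
  if (size_range[2L] > G) stop_named("pathway size range exceeds gene count G")
  if (D > P) stop_named("D prognostic pathways cannot exceed P pathways")
  check_flag(platform_distortion, "platform_distortion")
  structure(list(G = G, P = P, size_range = as.integer(size_range), D = D,
                 delta = delta, prevalence = prevalence, n = n,
                 lambda0 = lambda0, hr = hr, c_max = c_max,
                 platform_distortion = platform_distortion,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a cohort with pathway-structured prognosis
#'
#' Gene baselines are Normal(mu_g, 1) on the log scale with mu_g ~
#' Normal(6, 1.5). Pathways sample their member genes independently, so sets
#' overlap (as curated collections do). Each sample draws a latent class
#' (poor with probability `prevalence`); poor-class samples have `delta`
#' added to every gene in a prognostic pathway. Survival times are
#' exponential with hazard `lambda0 * hr^class`, censoring is
#' Uniform(0, c_max), observed time is the minimum, and the event indicator
#' marks an uncensored failure. Everything is determined by the seed.
#'
#' @param config a `simulation_config`.
#' @return list of class `synthetic_cohort`: `expr` (genes x samples),
#'   `sets` (`gene_set_collection`), `clinical` (sample_id, time, event) and
#'   `truth` (latent class, prognostic pathway names, config).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  gene_ids <- sprintf("G%05d", seq_len(config$G))
  sample_ids <- sprintf("S%04d", seq_len(config$n))
  path_ids <- sprintf("P%04d", seq_len(config$P))

  mu <- stats::rnorm(config$G, mean = 6, sd = 1.5)
  sizes <- sample(seq(config$size_range[1L], config$size_range[2L]),
                  config$P, replace = TRUE)
  member_idx <- lapply(sizes, function(sz) sort(sample.int(config$G, sz)))
  prognostic <- sort(sample.int(config$P, config$D))

  cls <- stats::rbinom(config$n, 1L, config$prevalence)
  expr <- matrix(stats::rnorm(config$G * config$n, mean = mu, sd = 1),
                 nrow = config$G, ncol = config$n,
                 dimnames = list(gene_ids, sample_ids))
  if (config$D > 0L && any(cls == 1L)) {
    prog_genes <- unique(unlist(member_idx[prognostic]))
    expr[prog_genes, cls == 1L] <- expr[prog_genes, cls == 1L] + config$delta
  }

  t_lat <- stats::rexp(config$n, rate = config$lambda0 * config$hr^cls)
  cens <- stats::runif(config$n, 0, config$c_max)
  clinical <- data.frame(sample_id = sample_ids,
                         time = pmin(t_lat, cens),
                         event = as.integer(t_lat <= cens),
                         stringsAsFactors = FALSE)

  if (config$platform_distortion) {
    for (j in seq_len(config$n)) {
      expr[, j] <- random_monotone_map(expr[, j],
                                       derive_seed(config$seed, 7L, j))
    }
  }

  desc <- ifelse(seq_len(config$P) %in% prognostic, "prognostic", "background")
  sets <- gene_set_collection(
    stats::setNames(lapply(member_idx, function(ix) gene_ids[ix]), path_ids),
    desc)
  structure(list(expr = as_expression_matrix(expr),
                 sets = sets,
                 clinical = as_clinical_table(clinical),
                 truth = list(class = stats::setNames(cls, sample_ids),
                              prognostic = path_ids[prognostic],
                              config = config)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("synthetic_cohort: %d genes x %d samples, %d pathways (%d prognostic), %.0f%% events\n",
              cfg$G, cfg$n, cfg$P, cfg$D, 100 * mean(x$clinical$event)))
  invisible(x)
}

#' Apply the prognosis label windows to a simulated cohort's clinical table
#'
#' Convenience wrapper around [select_training_labels()] with the standard
#' 3-year / 5-year windows.
#'
#' @param clinical clinical table (typically from [simulate_cohort()]).
#' @param poor_window,good_window months (defaults 36 and 60).
#' @return a `training_selection`.
#' @export
apply_label_windows <- function(clinical, poor_window = 36, good_window = 60) {
  select_training_labels(clinical, poor_window, good_window)
}

#' Split a simulated cohort into training and test cohorts
#'
#' Samples are iid given the population (gene baselines, pathways,
#' prognostic effects), so a split by sample yields two cohorts from the
#' same population -- the setting required to evaluate a trained model on
#' held-out patients.
#'
#' @param cohort a `synthetic_cohort`.
#' @param n_train number of samples for the training cohort (the first
#'   `n_train` columns; draws are exchangeable).
#' @return list with `train` and `test` `synthetic_cohort` objects sharing
#'   `sets` and prognostic truth.
#' @export
split_cohort <- function(cohort, n_train) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- ncol(cohort$expr)
  n_train <- check_count(n_train, "n_train", lower = 1L)
  if (n_train >= n) stop_named("n_train must leave at least one test sample")
  take <- function(idx) {
    structure(list(expr = cohort$expr[, idx, drop = FALSE],
                   sets = cohort$sets,
                   clinical = cohort$clinical[idx, , drop = FALSE],
                   truth = list(class = cohort$truth$class[idx],
                                prognostic = cohort$truth$prognostic,
                                config = cohort$truth$config)),
              class = "synthetic_cohort")
  }
  list(train = take(seq_len(n_train)), test = take((n_train + 1L):n))
}
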