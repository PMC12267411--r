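# Readers and writers for the external artifacts: expression matrices,
# GMT gene-set collections, clinical survival tables, and trained-model JSON.
# Every reader validates fully; malformed input is a named error, never a
# silently coerced value.

#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants every downstream function relies on: unique gene and
#' sample identifiers, no missing values, at least 2 genes and 1 sample.
#' Values may be on any monotone expression scale (counts, TPM,
#' log-intensity): only within-sample ranks are ever used, so no
#' transformation or normalization is applied.
#'
#' @param values numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).
#' @return the validated matrix, invisibly unchanged.
#' @export
as_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_named("expression must be a numeric matrix (genes x samples)")
  }
  g <- rownames(values)
  s <- colnames(values)
  if (is.null(g) || is.null(s)) {
    stop_named("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(g)) {
    stop_named("duplicate gene ids: %s",
               paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  if (anyDuplicated(s)) {
    stop_named("duplicate sample ids: %s",
               paste(unique(s[duplicated(s)]), collapse = ", "))
  }
  bad <- rowSums(is.na(values)) > 0
  if (any(bad)) {
    stop_named("missing values in gene row(s): %s",
               paste(g[bad], collapse = ", "))
  }
  if (nrow(values) < 2L) stop_named("expression matrix needs at least 2 genes")
  if (ncol(values) < 1L) stop_named("expression matrix needs at least 1 sample")
  values
}

#' Read an expression matrix from TSV or CSV
#'
#' First column holds gene ids, header row holds sample ids. Duplicate gene
#' rows are collapsed by arithmetic mean with a warning (the common microarray
#' probe-collapse convention); duplicate sample ids and non-numeric cells are
#' errors naming the offending row/column.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return validated numeric matrix (genes x samples).
#' @export
read_expression <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop_named("expression file '%s' has no sample columns", path)
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop_named("duplicate sample ids in header: %s",
               paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_named("non-numeric value '%s' for gene '%s', sample '%s'",
               vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
               samples[bad[1L, 2L]])
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("collapsing %d duplicated gene row(s) by mean: %s",
                    length(dup), paste(utils::head(dup, 5L), collapse = ", ")),
            call. = FALSE)
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  dimnames(num) <- list(genes, samples)
  as_expression_matrix(num)
}

#' Write an expression matrix as TSV
#'
#' Numbers are formatted with \code{\%.17g} so that write-read-write is
#' byte-stable.
#'
#' @param expr validated expression matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1L, function(v) paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member genes); names are the
#'   set names and must be unique and nonempty.
#' @param descriptions optional character vector, one per set.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop_named("gene sets must be a named list")
  }
  if (anyDuplicated(names(sets))) {
    stop_named("duplicate gene-set names: %s",
               paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  for (nm in names(sets)) {
    if (length(sets[[nm]]) < 1L) stop_named("gene set '%s' is empty", nm)
    if (anyDuplicated(sets[[nm]])) {
      stop_named("gene set '%s' contains duplicate genes", nm)
    }
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets,
                 descriptions = stats::setNames(descriptions, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)\n",
              length(x$sets), min(sizes), max(sizes)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard MSigDB layout: one set per line, tab-separated fields
#' name, description, gene, gene, ... Duplicate genes within a line are
#' deduplicated with a warning; duplicate set names or a line with no genes
#' are errors.
#'
#' @param path file path.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_named("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", "")
  if (anyDuplicated(nm)) {
    stop_named("duplicate gene-set names in GMT: %s",
               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    genes <- f[-(1:2)][nzchar(f[-(1:2)])]
    if (length(f) < 3L || length(genes) < 1L) {
      stop_named("GMT line %d ('%s') has no genes", i, nm[i])
    }
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set '%s': removed %d duplicate gene(s)",
                      nm[i], sum(duplicated(genes))), call. = FALSE)
      genes <- unique(genes)
    }
    sets[[i]] <- genes
  }
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Validate a clinical survival table
#'
#' Requires columns `sample_id`, `time` (months, >= 0) and `event`
#' (0 = censored, 1 = recurrence/death). Extra covariate columns are carried
#' along but ignored by the classifier.
#'
#' @param df data.frame.
#' @return the validated data.frame.
#' @export
as_clinical_table <- function(df) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) {
    stop_named("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop_named("duplicate sample ids in clinical table: %s",
               paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  tnum <- suppressWarnings(as.numeric(df$time))
  badt <- which(is.na(tnum) | tnum < 0)
  if (length(badt) > 0L) {
    stop_named("invalid time '%s' for sample '%s' (must be a number >= 0)",
               df$time[badt[1L]], df$sample_id[badt[1L]])
  }
  enum <- suppressWarnings(as.numeric(df$event))
  bade <- which(is.na(enum) | !(enum %in% c(0, 1)))
  if (length(bade) > 0L) {
    stop_named("invalid event '%s' for sample '%s' (must be 0 or 1)",
               df$event[bade[1L]], df$sample_id[bade[1L]])
  }
  df$time <- tnum
  df$event <- as.integer(enum)
  df
}

#' Read a clinical survival table from TSV
#' @param path file path (tab-separated, columns sample_id, time, event).
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  as_clinical_table(df)
}

#' Write a clinical table as TSV
#' @param clinical validated clinical table.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  clinical <- as_clinical_table(clinical)
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Report clinical/expression sample mismatches
#'
#' Samples present in one input but not the other are reported (returned and
#' messaged), never silently dropped.
#'
#' @param clinical clinical table.
#' @param expr expression matrix.
#' @return list with `shared`, `clinical_only`, `expression_only` id vectors.
#' @export
match_samples <- function(clinical, expr) {
  cs <- clinical$sample_id
  es <- colnames(expr)
  out <- list(shared = intersect(cs, es),
              clinical_only = setdiff(cs, es),
              expression_only = setdiff(es, cs))
  if (length(out$clinical_only) || length(out$expression_only)) {
    message(sprintf("sample mismatch: %d clinical-only, %d expression-only",
                    length(out$clinical_only), length(out$expression_only)))
  }
  out
}

MODEL_SCHEMA_VERSION <- 1L
PAIR_ORIENTATION <- "greater_votes_poor"

#' Write a trained ensemble model to JSON
#'
#' The file carries a `schema_version`, a provenance block (package version,
#' master seed, training parameters) and every retained member with its pairs,
#' chosen k and held-out balanced accuracy. `read_model(write_model(m))`
#' predicts identically to `m` on any input.
#'
#' @param model a `pianos_ensemble`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pianos_ensemble"))
  members <- lapply(model$members, function(m) {
    list(k = m$k,
         tie_policy = m$tie_policy,
         ba = m$ba,
         pairs = unname(lapply(seq_len(nrow(m$pairs)), function(i) {
           list(greater = m$pairs$greater[i],
                lesser = m$pairs$lesser[i],
                orientation = PAIR_ORIENTATION,
                delta = m$pairs$delta[i],
                gamma = m$pairs$gamma[i])
         })))
  })
  obj <- list(schema_version = MODEL_SCHEMA_VERSION,
              provenance = list(
                software = "pianos",
                version = as.character(utils::packageVersion("pianos")),
                seed = model$seed,
                B = model$B,
                split_fraction = model$split_fraction,
                ba_threshold = model$ba_threshold,
                scoring = model$scoring),
              tau = model$tau,
              members = members)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trained ensemble model from JSON
#'
#' Validates the schema version, rejects unknown fields by name, and
#' re-checks the retention invariant: every member's stored held-out balanced
#' accuracy must exceed the stored threshold.
#'
#' @param path model JSON path.
#' @return a `pianos_ensemble`.
#' @export
read_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_named("cannot parse model file '%s': %s", path,
                               conditionMessage(e))
                  })
  known <- c("schema_version", "provenance", "tau", "members")
  extra <- setdiff(names(obj), known)
  if (length(extra) > 0L) {
    stop_named("unknown field(s) in model file: %s", paste(extra, collapse = ", "))
  }
  miss <- setdiff(known, names(obj))
  if (length(miss) > 0L) {
    stop_named("model file missing field(s): %s", paste(miss, collapse = ", "))
  }
  if (!identical(as.integer(obj$schema_version), MODEL_SCHEMA_VERSION)) {
    stop_named("model schema_version %s not supported (expected %d)",
               obj$schema_version, MODEL_SCHEMA_VERSION)
  }
  prov <- obj$provenance
  ba_threshold <- prov$ba_threshold
  members <- lapply(obj$members, function(m) {
    pk <- setdiff(names(m), c("k", "tie_policy", "ba", "pairs"))
    if (length(pk) > 0L) {
      stop_named("unknown member field(s): %s", paste(pk, collapse = ", "))
    }
    pairs <- do.call(rbind, lapply(m$pairs, function(p) {
      if (!identical(p$orientation, PAIR_ORIENTATION)) {
        stop_named("unknown pair orientation '%s'", p$orientation)
      }
      data.frame(greater = p$greater, lesser = p$lesser,
                 delta = p$delta, gamma = p$gamma,
                 stringsAsFactors = FALSE)
    }))
    new_ktsp_model(pairs, k = as.integer(m$k), tie_policy = m$tie_policy,
                   ba = m$ba)
  })
  for (i in seq_along(members)) {
    if (!is.null(ba_threshold) && !(members[[i]]$ba > ba_threshold)) {
      stop_named("member %d has held-out balanced accuracy %.4f <= threshold %.2f: retention invariant violated",
                 i, members[[i]]$ba, ba_threshold)
    }
  }
  new_pianos_ensemble(members = members,
                      B = prov$B,
                      split_fraction = prov$split_fraction,
                      ba_threshold = ba_threshold,
                      tau = as.integer(obj$tau),
                      seed = prov$seed,
                      scoring = prov$scoring)
}
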