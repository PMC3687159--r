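# Evaluation protocol: repeated random 50/25/25 splits of the experimental
# conditions into train/validation/test, Pearson correlation between
# predicted and observed target expression on the held-out test set, success
# called at mean CC > 0.7 over the repetitions, and an output-shuffle null
# for significance.

#' Evaluation protocol parameters
#'
#' @param n_reps Number of random-split repetitions (default 100).
#' @param train_frac,val_frac,test_frac Split fractions (defaults 0.50,
#'   0.25, 0.25; must be positive and sum to 1).
#' @param success_threshold A model is called successful when its mean test
#'   CC strictly exceeds this (default 0.70).
#' @param n_starts Random restarts per repetition: the network is trained
#'   from `n_starts` seeded uniform initializations and the one with the
#'   best validation MSE is kept (default 3). Training-set sizes here are
#'   small, and a single Levenberg-Marquardt run occasionally lands in a
#'   catastrophic local minimum; restarts chosen on validation data remove
#'   that failure mode without touching the test partition.
#' @param seed Integer seed; every repetition's split and initialization
#'   stream is derived from it.
#' @return A list of class `eval_params`.
#' @export
eval_params <- function(n_reps = 100, train_frac = 0.50, val_frac = 0.25,
                        test_frac = 0.25, success_threshold = 0.70,
                        n_starts = 3, seed = 1) {
  abort_if(train_frac <= 0 || val_frac <= 0 || test_frac <= 0,
           "split fractions must be positive")
  abort_if(abs(train_frac + val_frac + test_frac - 1) > 1e-8,
           "split fractions must sum to 1")
  abort_if(n_starts < 1, "n_starts must be >= 1")
  structure(list(n_reps = as.integer(n_reps), train_frac = train_frac,
                 val_frac = val_frac, test_frac = test_frac,
                 success_threshold = success_threshold,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "eval_params")
}

#' Random train/validation/test split for one repetition
#'
#' A uniformly random permutation of `1:n`, seeded deterministically by
#' `(seed, rep_index)`, cut at `floor(n * train_frac)` and
#' `floor(n * (train_frac + val_frac))`. Partitions are disjoint and
#' exhaustive.
#'
#' @param n Number of samples; must be >= 8 so every partition is non-empty
#'   under the default fractions.
#' @param params An [eval_params()] object.
#' @param rep_index Repetition index (1-based).
#' @return List with integer vectors `train`, `val`, `test`.
#' @export
split_samples <- function(n, params = eval_params(), rep_index = 1) {
  abort_if(n < 8,
           "need >= 8 samples to split into train/validation/test (got %d); provide more data",
           n)
  perm <- with_seed(derive_seed(params$seed, "split", rep_index),
                    sample.int(n))
  c1 <- floor(n * params$train_frac)
  c2 <- floor(n * (params$train_frac + params$val_frac))
  list(train = perm[seq_len(c1)],
       val = perm[(c1 + 1):c2],
       test = perm[(c2 + 1):n])
}

#' Pearson product-moment correlation with degenerate-case handling
#'
#' When either vector has zero variance (a degenerate trained network can
#' predict a constant) the correlation is undefined; it is recorded as 0
#' with attribute `degenerate = TRUE` and a warning, so aggregation over
#' repetitions never aborts.
#'
#' @param pred,actual Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\]; attribute `degenerate` flags the
#'   zero-variance case.
#' @export
pearson_cc <- function(pred, actual) {
  abort_if(length(pred) != length(actual), "length mismatch")
  abort_if(length(pred) < 3, "need >= 3 points for a correlation")
  if (stats::sd(pred) == 0 || stats::sd(actual) == 0) {
    warning("zero variance in correlation input; recording CC = 0",
            call. = FALSE)
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(pred, actual), degenerate = FALSE)
}

# Drop samples with a missing value in any input or the target (listwise
# deletion; the conservative choice for the masked-network fit).
drop_incomplete <- function(X, y) {
  ok <- stats::complete.cases(X) & !is.na(y)
  list(X = X[ok, , drop = FALSE], y = y[ok])
}

#' Evaluate a cascade network on an explicit design
#'
#' Runs the repeated-split protocol on a ready-made design matrix: per
#' repetition, split, initialize a fresh masked network with a
#' repetition-specific seed, train by Levenberg-Marquardt with early
#' stopping, and score the Pearson CC on the test partition.
#'
#' @param cascade A [cascade()] object.
#' @param X Numeric design matrix (samples x upper TFs, in `upper_tfs`
#'   column order); rows with missing values are dropped listwise with `y`.
#' @param y Numeric target vector.
#' @param ep An [eval_params()] object.
#' @param tp A [train_params()] object.
#' @return An `eval_result`: list with `target_gene`, `category`, `n_reps`,
#'   `per_rep_test_cc`, `mean_cc`, `sd_cc`, `success`, `n_samples`, `seed`,
#'   `n_degenerate`.
#' @export
evaluate_design <- function(cascade, X, y, ep = eval_params(),
                            tp = train_params()) {
  clean <- drop_incomplete(as.matrix(X), y)
  n <- nrow(clean$X)
  abort_if(n < 8, "only %d complete samples; need >= 8", n)
  ccs <- numeric(ep$n_reps)
  degen <- 0L
  n_starts <- if (is.null(ep$n_starts)) 1L else ep$n_starts
  for (rep in seq_len(ep$n_reps)) {
    ix <- split_samples(n, ep, rep)
    Xv <- clean$X[ix$val, , drop = FALSE]
    best_val <- Inf
    fit <- NULL
    for (start in seq_len(n_starts)) {
      ann <- init_ann(cascade,
                      seed = derive_seed(ep$seed, "init", rep, start))
      cand <- train_lm(ann, clean$X[ix$train, , drop = FALSE],
                       clean$y[ix$train], Xv, clean$y[ix$val], params = tp)
      vm <- mean((ann_forward(cand$ann, Xv) - clean$y[ix$val])^2)
      if (vm < best_val) {
        best_val <- vm
        fit <- cand
      }
    }
    pred <- ann_forward(fit$ann, clean$X[ix$test, , drop = FALSE])
    cc <- suppressWarnings(pearson_cc(pred, clean$y[ix$test]))
    if (isTRUE(attr(cc, "degenerate"))) degen <- degen + 1L
    ccs[rep] <- as.numeric(cc)
  }
  structure(list(target_gene = cascade$target_gene,
                 category = cascade$category,
                 source_module = cascade$source_module,
                 n_reps = ep$n_reps, per_rep_test_cc = ccs,
                 mean_cc = mean(ccs), sd_cc = stats::sd(ccs),
                 success = mean(ccs) > ep$success_threshold,
                 n_samples = n, seed = ep$seed, n_degenerate = degen),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "eval_result %s [%s]: mean CC %.3f +/- %.3f over %d reps (n = %d)%s\n",
    x$target_gene, x$category, x$mean_cc, x$sd_cc, x$n_reps, x$n_samples,
    if (x$success) " SUCCESS" else ""))
  invisible(x)
}

# Build the synchronous (unshifted) design for a cascade: inputs are the
# upper-layer TF expression profiles, the output is the target gene's, over
# the cascade's category (or all experiments when the category is unset).
cascade_design <- function(cascade, expr) {
  e <- expr
  if (!is.na(cascade$category) && cascade$category %in% expr$meta$category)
    e <- subset_category(expr, cascade$category)
  need <- c(cascade$upper_tfs, cascade$target_gene)
  missing_ids <- setdiff(need, rownames(e$values))
  abort_if(length(missing_ids) > 0,
           "IDs absent from expression data: %s",
           paste(missing_ids, collapse = ", "))
  list(X = t(e$values[cascade$upper_tfs, , drop = FALSE]),
       y = e$values[cascade$target_gene, ])
}

#' Evaluate a cascade against expression data (synchronous)
#'
#' Builds the unshifted design (inputs = upper-layer TF profiles, output =
#' target gene profile over the cascade's category) and runs
#' [evaluate_design()].
#'
#' @param cascade A [cascade()] object.
#' @param expr An [expression_matrix()] containing rows for all upper TFs
#'   and the target gene.
#' @param ep An [eval_params()] object.
#' @param tp A [train_params()] object.
#' @return An `eval_result`.
#' @export
evaluate_cascade <- function(cascade, expr, ep = eval_params(),
                             tp = train_params()) {
  d <- cascade_design(cascade, expr)
  evaluate_design(cascade, d$X, d$y, ep, tp)
}

#' Output-shuffle significance test
#'
#' Repeats the full evaluation with the target gene's expression values
#' randomly permuted (a fresh uniform permutation per shuffle trial,
#' preserving the multiset of values). The verdict is `TRUE` iff the
#' unshuffled mean CC exceeds the maximum mean CC attained by any shuffled
#' run.
#'
#' @param cascade A [cascade()] object.
#' @param expr An [expression_matrix()].
#' @param ep An [eval_params()] object.
#' @param tp A [train_params()] object.
#' @param n_shuffles Number of shuffle trials (default 100).
#' @param observed Optionally, a precomputed `eval_result` for the
#'   unshuffled data (with the same `ep`/`tp`), to avoid re-fitting.
#' @param design Optionally, a precomputed `list(X, y)` design to use
#'   instead of the synchronous design from `expr` (used by the time-shift
#'   search).
#' @return List of class `shuffle_null`: `observed` (`eval_result`),
#'   `null_mean_cc` (vector), `max_null_cc`, `verdict`.
#' @export
shuffle_null <- function(cascade, expr, ep = eval_params(),
                         tp = train_params(), n_shuffles = 100,
                         observed = NULL, design = NULL) {
  d <- if (is.null(design)) cascade_design(cascade, expr) else design
  if (is.null(observed)) observed <- evaluate_design(cascade, d$X, d$y, ep, tp)
  nulls <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    y_perm <- with_seed(derive_seed(ep$seed, "shuffle", s),
                        sample(d$y))
    ep_s <- ep
    ep_s$seed <- derive_seed(ep$seed, "shuffle-eval", s)
    nulls[s] <- evaluate_design(cascade, d$X, y_perm, ep_s, tp)$mean_cc
  }
  structure(list(observed = observed, null_mean_cc = nulls,
                 max_null_cc = max(nulls),
                 verdict = observed$mean_cc > max(nulls)),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf(
    "shuffle_null: observed mean CC %.3f vs max of %d nulls %.3f -> %s\n",
    x$observed$mean_cc, length(x$null_mean_cc), x$max_null_cc,
    if (x$verdict) "significant" else "not significant"))
  invisible(x)
}

#' Write evaluation results as TSV
#'
#' One row per result: target gene, category, source module, sample count,
#' mean/SD test CC, success call and, when available, the shuffle-null
#' maximum and verdict.
#'
#' @param results List of `eval_result` (or `shuffle_null`) objects.
#' @param path Output path.
#' @return Invisibly, the data frame written.
#' @export
write_eval_results <- function(results, path) {
  rows <- lapply(results, function(r) {
    if (inherits(r, "shuffle_null")) {
      obs <- r$observed
      data.frame(target_gene = obs$target_gene, category = obs$category,
                 source_module = obs$source_module, n_samples = obs$n_samples,
                 mean_cc = obs$mean_cc, sd_cc = obs$sd_cc,
                 success = obs$success, null_max_cc = r$max_null_cc,
                 verdict = r$verdict, stringsAsFactors = FALSE)
    } else {
      data.frame(target_gene = r$target_gene, category = r$category,
                 source_module = r$source_module, n_samples = r$n_samples,
                 mean_cc = r$mean_cc, sd_cc = r$sd_cc, success = r$success,
                 null_max_cc = NA_real_, verdict = NA,
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
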