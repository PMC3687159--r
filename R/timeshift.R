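# Asynchronous regulation: each upper-layer TF's activity profile may be
# shifted k time steps backwards relative to the target gene, independently
# per TF, within each condition's own time grid. The search enumerates every
# shift assignment up to the category's bound, rebuilds the design for each,
# and evaluates it with the standard protocol. A TF can never be shifted so
# that it appears active after its target is expressed: only backward shifts
# exist, and samples whose shifted index would fall before the first time
# point are excluded structurally.

#' Maximum backward shift available in a category
#'
#' `n - 1`, where `n` is the smallest number of time points among the
#' category's multi-time-point conditions. Single-time-point conditions are
#' excluded from the count (they carry no temporal information).
#'
#' @param expr An [expression_matrix()].
#' @param category Category label.
#' @return Integer maximum shift.
#' @export
max_shift <- function(expr, category) {
  meta <- expr$meta[expr$meta$category == category, ]
  abort_if(nrow(meta) == 0, "no experiments in category '%s'", category)
  counts <- table(meta$condition[!is.na(meta$time_point)])
  counts <- counts[counts >= 2]
  abort_if(length(counts) == 0,
           "category '%s' has no condition with >= 2 time points", category)
  as.integer(min(counts) - 1)
}

#' Enumerate per-TF shift assignments
#'
#' The full cross product `{0..max_shift}^N` in lexicographic order (first
#' TF varies slowest). The count `(max_shift + 1)^N` grows quickly; a cap
#' aborts with guidance when exceeded.
#'
#' @param upper_tfs Ordered character vector of upper-layer TF IDs.
#' @param max_shift Maximum backward shift (>= 0).
#' @param cap Maximum number of assignments to enumerate (default 1e5).
#' @return Integer matrix, one row per assignment, one named column per TF.
#' @export
enumerate_assignments <- function(upper_tfs, max_shift, cap = 1e5) {
  abort_if(max_shift < 0, "max_shift must be >= 0")
  n_assign <- (max_shift + 1)^length(upper_tfs)
  abort_if(n_assign > cap,
           "%g shift assignments exceed the cap (%g); reduce max_shift or restrict per-TF shifts",
           n_assign, cap)
  grid <- expand.grid(rev(replicate(length(upper_tfs),
                                    0:max_shift, simplify = FALSE)),
                      KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid[, rev(seq_len(ncol(grid))), drop = FALSE])
  dimnames(m) <- list(NULL, upper_tfs)
  storage.mode(m) <- "integer"
  m
}

#' Build the time-shifted design matrix for a shift assignment
#'
#' Within each multi-time-point condition (time points ordered 1..m), every
#' target index `j` yields one sample pairing the target's value at `t_j`
#' with TF `i`'s value at `t_(j - k_i)`; the sample is included only when
#' `j - k_i >= 1` for every TF. Single-time-point conditions contribute
#' samples only under the all-zero assignment. The all-zero assignment
#' therefore reproduces the synchronous design exactly.
#'
#' @param cascade A [cascade()] object.
#' @param expr An [expression_matrix()].
#' @param assignment Named integer vector (or 1-row matrix) of backward
#'   shifts covering every upper TF of the cascade.
#' @return List with `X` (samples x upper TFs), `y`, and `sample_info`
#'   (data frame: condition, target time index).
#' @export
build_shifted_design <- function(cascade, expr, assignment) {
  shifts <- assignment[cascade$upper_tfs]
  abort_if(any(is.na(shifts)),
           "assignment must cover every upper TF of the cascade")
  e <- expr
  if (!is.na(cascade$category) && cascade$category %in% expr$meta$category)
    e <- subset_category(expr, cascade$category)
  need <- c(cascade$upper_tfs, cascade$target_gene)
  missing_ids <- setdiff(need, rownames(e$values))
  abort_if(length(missing_ids) > 0, "IDs absent from expression data: %s",
           paste(missing_ids, collapse = ", "))

  rows_X <- list()
  ys <- numeric(0)
  info <- list()
  for (cond in unique(e$meta$condition)) {
    ix <- which(e$meta$condition == cond)
    tps <- e$meta$time_point[ix]
    if (all(is.na(tps)) || length(ix) == 1) {
      # single-sample condition: usable only when nothing is shifted
      if (all(shifts == 0)) {
        for (col in ix) {
          rows_X[[length(rows_X) + 1]] <-
            e$values[cascade$upper_tfs, col]
          ys <- c(ys, e$values[cascade$target_gene, col])
          info[[length(info) + 1]] <- data.frame(condition = cond,
                                                 time_index = 1L)
        }
      }
      next
    }
    ord <- ix[order(tps)]
    m <- length(ord)
    for (j in seq_len(m)) {
      if (j - max(shifts) < 1) next
      x <- vapply(seq_along(cascade$upper_tfs), function(i)
        e$values[cascade$upper_tfs[i], ord[j - shifts[i]]], numeric(1))
      rows_X[[length(rows_X) + 1]] <- x
      ys <- c(ys, e$values[cascade$target_gene, ord[j]])
      info[[length(info) + 1]] <- data.frame(condition = cond,
                                             time_index = j)
    }
  }
  X <- if (length(rows_X) > 0) do.call(rbind, rows_X)
       else matrix(numeric(0), 0, length(cascade$upper_tfs))
  colnames(X) <- cascade$upper_tfs
  list(X = X, y = ys,
       sample_info = if (length(info) > 0) do.call(rbind, info)
                     else data.frame(condition = character(0),
                                     time_index = integer(0)))
}

#' Search over shift assignments for a cascade
#'
#' Evaluates every enumerated assignment with the repeated-split protocol on
#' its shifted design. The best assignment maximizes the mean test CC (ties
#' broken by smaller total shift, then enumeration order); every assignment
#' beating the success threshold is reported, since more than one
#' combination of delays typically yields an accurate model. Assignments
#' whose design retains fewer than 8 complete samples are recorded with
#' `NA` and never best. For the best assignment an output-shuffle null can
#' be run; its verdict asks whether the best mean CC exceeds the maximum
#' shuffled mean CC.
#'
#' @param cascade A [cascade()] object.
#' @param expr An [expression_matrix()] with time-series metadata.
#' @param ep An [eval_params()] object.
#' @param tp A [train_params()] object.
#' @param cap Assignment-enumeration cap (see [enumerate_assignments()]).
#' @param run_null Run the shuffle null on the best assignment?
#' @param n_shuffles Shuffle trials for the null (default 100).
#' @return An object of class `shift_search`: list with `cascade`,
#'   `max_shift`, `assignments` (matrix), `results` (list of `eval_result`
#'   or `NULL`), `table` (data frame: one row per assignment with mean/sd CC
#'   and success), `best` (named shift vector), `best_result`, `successes`
#'   (row indices with mean CC above threshold), and `null` (a
#'   `shuffle_null` or `NULL`).
#' @export
search_shifts <- function(cascade, expr, ep = eval_params(),
                          tp = train_params(), cap = 1e5, run_null = FALSE,
                          n_shuffles = 100) {
  ms <- max_shift(expr, cascade$category)
  assigns <- enumerate_assignments(cascade$upper_tfs, ms, cap = cap)
  n_a <- nrow(assigns)
  results <- vector("list", n_a)
  mean_cc <- rep(NA_real_, n_a)
  sd_cc <- rep(NA_real_, n_a)
  n_samp <- integer(n_a)
  for (a in seq_len(n_a)) {
    d <- build_shifted_design(cascade, expr, assigns[a, ])
    clean <- drop_incomplete(d$X, d$y)
    n_samp[a] <- nrow(clean$X)
    if (n_samp[a] < 8) next  # too few samples at this shift depth
    # common random numbers: every assignment shares the split and
    # initialization streams, so assignments with equal sample counts are
    # compared on identical partitions (and the all-zero assignment
    # reproduces the synchronous evaluation exactly)
    res <- evaluate_design(cascade, clean$X, clean$y, ep, tp)
    results[[a]] <- res
    mean_cc[a] <- res$mean_cc
    sd_cc[a] <- res$sd_cc
  }
  abort_if(all(is.na(mean_cc)),
           "no shift assignment left enough samples to evaluate")
  total <- rowSums(assigns)
  ord <- order(-mean_cc, total, seq_len(n_a), na.last = TRUE)
  best_ix <- ord[1]
  successes <- which(!is.na(mean_cc) & mean_cc > ep$success_threshold)
  tab <- data.frame(
    shifts = apply(assigns, 1, paste, collapse = ","),
    n_samples = n_samp, mean_cc = mean_cc, sd_cc = sd_cc,
    success = !is.na(mean_cc) & mean_cc > ep$success_threshold,
    max_shift = ms, stringsAsFactors = FALSE)
  null <- NULL
  if (run_null) {
    d_best <- build_shifted_design(cascade, expr, assigns[best_ix, ])
    null <- shuffle_null(cascade, expr, ep, tp, n_shuffles = n_shuffles,
                         observed = results[[best_ix]], design = d_best)
  }
  structure(list(cascade = cascade, max_shift = ms, assignments = assigns,
                 results = results, table = tab,
                 best = assigns[best_ix, ], best_index = best_ix,
                 best_result = results[[best_ix]],
                 successes = successes, null = null),
            class = "shift_search")
}

#' @export
print.shift_search <- function(x, ...) {
  cat(sprintf(
    "shift_search %s [%s]: %d assignments (max shift %d), best (%s) mean CC %.3f, %d successes\n",
    x$cascade$target_gene, x$cascade$category, nrow(x$assignments),
    x$max_shift, paste(x$best, collapse = ","),
    x$best_result$mean_cc, length(x$successes)))
  invisible(x)
}

#' Write a shift-search report as TSV
#'
#' One row per assignment: comma-joined per-TF delays, sample count, mean
#' and SD test CC, success flag and the category's maximum shift.
#'
#' @param search A `shift_search` object.
#' @param path Output path.
#' @return Invisibly, the data frame written.
#' @export
write_shift_report <- function(search, path) {
  utils::write.table(search$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(search$table)
}
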