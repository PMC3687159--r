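# Small in-code fixtures shared across the suite. Everything is generated
# programmatically; no binary data.

# A tiny expression matrix: `genes` x `n` experiments in one category/one
# condition time series unless a custom meta is supplied.
toy_expr <- function(values, category = "A", condition = "A_c1",
                     time_point = seq_len(ncol(values)),
                     replicate_group = NULL) {
  ids <- colnames(values)
  if (is.null(ids)) {
    ids <- sprintf("e%d", seq_len(ncol(values)))
    colnames(values) <- ids
  }
  if (is.null(replicate_group)) replicate_group <- ids
  meta <- data.frame(experiment_id = ids,
                     category = rep_len(category, ncol(values)),
                     condition = rep_len(condition, ncol(values)),
                     time_point = as.integer(rep_len(time_point,
                                                     ncol(values))),
                     time_value = NA_real_,
                     replicate_group = rep_len(replicate_group,
                                               ncol(values)),
                     stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}

named_matrix <- function(data, genes, exps) {
  matrix(data, nrow = length(genes), ncol = length(exps),
         dimnames = list(genes, exps))
}

# A small complete-bipartite cascade for network-level tests.
toy_cascade <- function(n_upper = 4, n_middle = 2, target = "G") {
  upper <- sprintf("U%d", seq_len(n_upper))
  middle <- sprintf("M%d", seq_len(n_middle))
  cascade(target, middle, upper,
          expand.grid(upper = upper, middle = middle,
                      stringsAsFactors = FALSE),
          category = "A", source_module = 1L)
}

# Deterministic random design for a cascade.
toy_design <- function(cascade, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * length(cascade$upper_tfs)), n,
         length(cascade$upper_tfs),
         dimnames = list(NULL, cascade$upper_tfs))
}

# Central finite-difference Jacobian of the forward pass w.r.t. the free
# parameters -- the independent oracle for the analytic Jacobian.
fd_jacobian <- function(ann, X, eps = 1e-6) {
  theta <- cascann:::get_free_params(ann)
  J <- matrix(0, nrow(X), length(theta))
  for (k in seq_along(theta)) {
    up <- theta; up[k] <- up[k] + eps
    dn <- theta; dn[k] <- dn[k] - eps
    J[, k] <- (ann_forward(cascann:::set_free_params(ann, up), X) -
                 ann_forward(cascann:::set_free_params(ann, dn), X)) /
      (2 * eps)
  }
  J
}
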