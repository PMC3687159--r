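# Synthetic input bundles generated from a planted ground-truth cascade.
# The generator emulates the five external inputs (expression matrix with
# metadata, binding p-value matrix, regulator edge list, binding-site table,
# interaction pairs) so every pipeline stage is testable without external
# databases. Upper-layer TF profiles are smooth random walks per condition
# (shifts would be unidentifiable from white noise); middle-layer activities
# are the logistic readout of the planted, possibly time-shifted weights;
# module genes share the planted target function plus independent Gaussian
# noise on the log2 scale.

#' Specification of a synthetic bundle
#'
#' @param n_categories Number of stress categories (labels A, B, ...).
#' @param conditions_per_category Conditions per category.
#' @param timepoints_per_condition Time points per condition.
#' @param n_upper,n_middle Number of upper- and middle-layer TFs.
#' @param n_module_genes Genes in the planted module (share the target's
#'   generating function plus independent noise).
#' @param n_background Background genes (independent random walks).
#' @param true_W_in Optional planted input-weight matrix (upper x middle);
#'   drawn uniform on \[-2, 2\] when `NULL`.
#' @param true_b_mid,true_w_out,true_b_out Optional planted biases/readout;
#'   drawn when `NULL` (readout weights uniform on \[0.5, 1.5\] with random
#'   sign).
#' @param planted_shifts Integer vector of per-upper-TF backward time
#'   shifts (default all zero); bounded by `timepoints_per_condition - 1`.
#' @param dimer Optional list `(partner_upstream =, strength =)`: adds a
#'   constitutively expressed partner TF, driven by its own
#'   `partner_upstream` regulators, whose activity multiplies the (single)
#'   middle TF's activity with coefficient `strength` in the target.
#'   Requires `n_middle = 1`.
#' @param n_extra_constitutive Additional constitutive TFs (near-zero
#'   profiles clipped within twofold).
#' @param n_pool Decoy TFs, each regulated by `partner_upstream` (or 3)
#'   private upstream TFs - the replacement pool for degree-matched dimer
#'   controls, and stringently unbound rows of the binding matrix.
#' @param noise_sd Gaussian noise SD on module-gene log2 values
#'   (default 0.05).
#' @param target_mode `"coupled"` (module genes follow the planted cascade)
#'   or `"noise"` (module genes are independent standard normal noise - the
#'   null world).
#' @param seed Integer seed; identical specs with identical seeds generate
#'   identical bundles.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_categories = 1, conditions_per_category = 6,
                           timepoints_per_condition = 4, n_upper = 3,
                           n_middle = 2, n_module_genes = 5,
                           n_background = 20, true_W_in = NULL,
                           true_b_mid = NULL, true_w_out = NULL,
                           true_b_out = NULL, planted_shifts = NULL,
                           dimer = NULL, n_extra_constitutive = 0,
                           n_pool = 0, noise_sd = 0.05,
                           target_mode = c("coupled", "noise"), seed = 1) {
  target_mode <- match.arg(target_mode)
  if (is.null(planted_shifts)) planted_shifts <- rep(0L, n_upper)
  abort_if(length(planted_shifts) != n_upper,
           "planted_shifts must have one entry per upper TF")
  abort_if(any(planted_shifts < 0) ||
             any(planted_shifts > timepoints_per_condition - 1),
           "planted_shifts must lie in [0, timepoints_per_condition - 1]")
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  if (!is.null(dimer)) {
    abort_if(n_middle != 1,
             "a dimer spec requires a single middle-layer TF (the anchor)")
    if (is.null(dimer$partner_upstream)) dimer$partner_upstream <- 3
    if (is.null(dimer$strength)) dimer$strength <- 3
  }
  structure(list(n_categories = n_categories,
                 conditions_per_category = conditions_per_category,
                 timepoints_per_condition = timepoints_per_condition,
                 n_upper = n_upper, n_middle = n_middle,
                 n_module_genes = n_module_genes,
                 n_background = n_background, true_W_in = true_W_in,
                 true_b_mid = true_b_mid, true_w_out = true_w_out,
                 true_b_out = true_b_out,
                 planted_shifts = as.integer(planted_shifts), dimer = dimer,
                 n_extra_constitutive = n_extra_constitutive,
                 n_pool = n_pool, noise_sd = noise_sd,
                 target_mode = target_mode, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Smooth per-condition random walk: start N(0, 0.5), steps N(0, 0.5).
random_walk <- function(n, step_sd = 0.5) cumsum(stats::rnorm(n, 0, step_sd))

#' Generate a complete synthetic input bundle
#'
#' Produces the five pipeline inputs plus a ground-truth record from a
#' [synthetic_spec()]. True middle-TF/module-gene binding p-values are 1e-4,
#' everything else Uniform(0.3, 1); true regulator edges carry a binding
#' site at 500 bp upstream, decoy edges (present in the edge list but
#' without a promoter-proximal site) carry one at 1500 bp. Interaction
#' pairs cover the planted dimer (plus screening decoys). The ground-truth
#' record includes the planted cascade (per the first module gene), all
#' planted parameters, the per-category affine rescale of the target
#' activity, and the names of every synthetic entity.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `expr` ([expression_matrix()]), `binding`,
#'   `edges`, `sites`, `ppi`, `truth`.
#' @export
generate_bundle <- function(spec) {
  with_seed(spec$seed, generate_bundle_impl(spec))
}

generate_bundle_impl <- function(spec) {
  Tn <- spec$timepoints_per_condition
  upper <- sprintf("UT%02d", seq_len(spec$n_upper))
  middle <- sprintf("MT%d", seq_len(spec$n_middle))
  modgenes <- sprintf("G%02d", seq_len(spec$n_module_genes))
  background <- sprintf("B%02d", seq_len(spec$n_background))
  pool <- if (spec$n_pool > 0) sprintf("DP%d", seq_len(spec$n_pool))
          else character(0)
  extra_const <- if (spec$n_extra_constitutive > 0)
    sprintf("CT%d", seq_len(spec$n_extra_constitutive)) else character(0)
  has_dimer <- !is.null(spec$dimer)
  partner <- if (has_dimer) "PTN1" else character(0)
  pu <- if (has_dimer) sprintf("PU%d", seq_len(spec$dimer$partner_upstream))
        else character(0)
  pool_deg <- if (has_dimer) spec$dimer$partner_upstream else 3
  pool_ups <- lapply(seq_len(spec$n_pool), function(p)
    sprintf("Q%d_%d", p, seq_len(pool_deg)))
  decoy_reg <- "DX1"  # regulator whose only binding site is beyond 1000 bp

  # planted parameters
  W <- spec$true_W_in
  if (is.null(W)) W <- matrix(stats::runif(spec$n_upper * spec$n_middle,
                                           -2, 2),
                              spec$n_upper, spec$n_middle)
  dimnames(W) <- list(upper, middle)
  b_mid <- spec$true_b_mid
  if (is.null(b_mid)) b_mid <- stats::runif(spec$n_middle, -0.5, 0.5)
  w_out <- spec$true_w_out
  if (is.null(w_out))
    w_out <- stats::runif(spec$n_middle, 0.5, 1.5) *
      sample(c(-1, 1), spec$n_middle, replace = TRUE)
  b_out <- spec$true_b_out
  if (is.null(b_out)) b_out <- stats::rnorm(1, 0, 0.2)
  Wp <- if (has_dimer) stats::runif(length(pu), 1, 2) *
          sample(c(-1, 1), length(pu), replace = TRUE) else numeric(0)

  cats <- LETTERS[seq_len(spec$n_categories)]
  input_tfs <- c(upper, pu, unlist(pool_ups), decoy_reg)
  all_rows <- c(upper, middle, partner, pu, unlist(pool_ups), pool,
                extra_const, decoy_reg, modgenes, background)

  meta_list <- list()
  val_cols <- list()
  scales <- list()
  for (cat in cats) {
    for (ci in seq_len(spec$conditions_per_category)) {
      cond <- sprintf("%s_c%d", cat, ci)
      ids <- sprintf("%s_t%d", cond, seq_len(Tn))
      meta_list[[length(meta_list) + 1]] <- data.frame(
        experiment_id = ids, category = cat, condition = cond,
        time_point = seq_len(Tn), time_value = 5 * 2^(seq_len(Tn) - 1),
        replicate_group = ids, stringsAsFactors = FALSE)

      # per-condition profiles of every input TF, with a burn-in of
      # max(shift) steps before the first observed time point so the
      # planted lag structure holds exactly at every observed sample
      # (clamping lags at the boundary would leak synchronous signal)
      ext <- max(spec$planted_shifts)
      Uext <- vapply(input_tfs, function(tf) random_walk(Tn + ext),
                     numeric(Tn + ext))  # (Tn + ext) x inputs
      U <- Uext[ext + seq_len(Tn), , drop = FALSE]
      Hm <- matrix(0, Tn, spec$n_middle)
      for (j in seq_len(spec$n_middle)) {
        z <- vapply(seq_len(Tn), function(t) {
          tt <- ext + t - spec$planted_shifts
          sum(W[, j] * Uext[cbind(tt, seq_len(spec$n_upper))]) + b_mid[j]
        }, numeric(1))
        Hm[, j] <- logsig(z)
      }
      act <- drop(Hm %*% w_out) + b_out
      if (has_dimer) {
        hp <- logsig(drop(U[, pu, drop = FALSE] %*% Wp))
        act <- act + spec$dimer$strength * Hm[, 1] * hp
      }
      block <- matrix(NA_real_, length(all_rows), Tn,
                      dimnames = list(all_rows, ids))
      block[input_tfs, ] <- t(U)
      block[middle, ] <- t((Hm - 0.5) * 4)  # rescale to ~[-2, 2] log2 units
      if (has_dimer)
        block[partner, ] <- pmin(1, pmax(-1, stats::rnorm(Tn, 0, 0.1)))
      for (ct in extra_const)
        block[ct, ] <- pmin(1, pmax(-1, stats::rnorm(Tn, 0, 0.1)))
      for (p in pool) block[p, ] <- random_walk(Tn)
      for (b in background) block[b, ] <- random_walk(Tn)
      attr(block, "act") <- act
      val_cols[[length(val_cols) + 1]] <- block
    }
  }
  values <- do.call(cbind, val_cols)
  meta <- do.call(rbind, meta_list)

  # rescale target activity per category to a realistic log2 range and add
  # per-gene noise
  acts <- unlist(lapply(val_cols, attr, "act"))
  for (cat in cats) {
    ix <- which(meta$category == cat)
    a <- acts[ix]
    mu <- mean(a)
    s <- stats::sd(a)
    if (!is.finite(s) || s == 0) s <- 1
    scales[[cat]] <- c(center = mu, scale = 1.5 / s)
    acts[ix] <- (a - mu) * (1.5 / s)
  }
  for (g in modgenes) {
    values[g, ] <- if (spec$target_mode == "noise")
      stats::rnorm(ncol(values), 0, 1)
    else acts + stats::rnorm(ncol(values), 0, spec$noise_sd)
  }

  expr <- expression_matrix(values, meta)

  # binding p-values: regulator rows x candidate-gene columns
  bind_rows <- c(middle, partner, pool)
  bind_cols <- c(modgenes, background)
  binding <- matrix(stats::runif(length(bind_rows) * length(bind_cols),
                                 0.3, 1),
                    length(bind_rows), length(bind_cols),
                    dimnames = list(bind_rows, bind_cols))
  binding[middle, modgenes] <- 1e-4

  # regulator edges and binding sites; decoy edges get only a distal site
  true_edges <- rbind(
    expand.grid(regulator = upper, target = middle,
                stringsAsFactors = FALSE),
    if (has_dimer) data.frame(regulator = pu, target = partner,
                              stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_len(spec$n_pool), function(p)
      data.frame(regulator = pool_ups[[p]], target = pool[p],
                 stringsAsFactors = FALSE))))
  decoy_edges <- data.frame(regulator = decoy_reg, target = middle[1],
                            stringsAsFactors = FALSE)
  edges <- rbind(true_edges, decoy_edges)
  edges <- data.frame(regulator = as.character(edges$regulator),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  sites <- rbind(
    data.frame(tf = true_edges$regulator, target = true_edges$target,
               upstream_offset = 500L, stringsAsFactors = FALSE),
    data.frame(tf = decoy_edges$regulator, target = decoy_edges$target,
               upstream_offset = 1500L, stringsAsFactors = FALSE))

  ppi <- if (has_dimer) {
    ppi_pairs(c(middle[1], middle[1], if (spec$n_pool >= 2) pool[1]),
              c(partner, upper[1], if (spec$n_pool >= 2) pool[2]))
  } else if (spec$n_pool >= 2) {
    ppi_pairs(pool[1], pool[2])
  } else {
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  }

  planted_cascade <- cascade(
    target_gene = modgenes[1], middle_tfs = middle, upper_tfs = upper,
    input_edges = expand.grid(upper = upper, middle = middle,
                              stringsAsFactors = FALSE),
    category = cats[1], source_module = 1L)

  truth <- list(spec = spec, W_in = W, b_mid = b_mid, w_out = w_out,
                b_out = b_out, partner_weights = Wp,
                planted_shifts = stats::setNames(spec$planted_shifts, upper),
                scales = scales, cascade = planted_cascade,
                upper = upper, middle = middle, module_genes = modgenes,
                background = background, partner = partner,
                partner_upstream = pu, pool = pool, pool_upstream = pool_ups,
                decoy_regulator = decoy_reg,
                constitutive = c(partner, extra_const))
  list(expr = expr, binding = binding, edges = edges, sites = sites,
       ppi = ppi, truth = truth)
}

#' Canonical named fixtures used throughout the test suite
#'
#' * `planted_module`: one well-separated 6-gene module bound by two TFs
#'   (p = 1e-4) among 24 background genes and a third, stringently unbound
#'   TF; 6 conditions x 4 time points, noise SD 0.1.
#' * `planted_delays`: 3 upper TFs with planted backward shifts (2, 0, 1),
#'   2 middle TFs, 6 conditions x 4 time points, noise SD 0.05.
#' * `planted_dimer`: single anchor TF whose activity is multiplied by a
#'   constitutively expressed partner (interaction strength 3), 8 decoy TFs
#'   for degree-matched controls; 12 conditions x 4 time points (about the
#'   per-category experiment count of a real stress compendium), noise
#'   SD 0.05.
#' * `pure_noise`: module genes independent of every TF (standard normal),
#'   15 conditions x 8 time points - the null world.
#'
#' @param name One of `"planted_module"`, `"planted_delays"`,
#'   `"planted_dimer"`, `"pure_noise"`.
#' @return A [synthetic_spec()] with a fixed seed.
#' @export
make_fixture <- function(name) {
  switch(name,
    planted_module = synthetic_spec(
      n_categories = 1, conditions_per_category = 6,
      timepoints_per_condition = 4, n_upper = 2, n_middle = 2,
      n_module_genes = 6, n_background = 24, n_pool = 1,
      noise_sd = 0.1, seed = 42),
    planted_delays = synthetic_spec(
      n_categories = 1, conditions_per_category = 6,
      timepoints_per_condition = 4, n_upper = 3, n_middle = 1,
      n_module_genes = 3, n_background = 6,
      # explicit planted weights: every upper TF must exert substantive
      # influence, otherwise its delay is unidentifiable in principle
      # (cf. the white-noise caveat); one hidden node keeps the free
      # parameters well below the shifted designs' sample counts
      true_W_in = matrix(c(1.5, 1.2, -1.3), 3, 1),
      true_b_mid = 0, true_w_out = 1.2, true_b_out = 0,
      planted_shifts = c(2L, 0L, 1L), noise_sd = 0.05, seed = 7),
    planted_dimer = synthetic_spec(
      n_categories = 1, conditions_per_category = 12,
      timepoints_per_condition = 4, n_upper = 3, n_middle = 1,
      n_module_genes = 5, n_background = 10,
      dimer = list(partner_upstream = 3, strength = 3),
      true_w_out = 0.5, n_pool = 8, noise_sd = 0.05, seed = 11),
    pure_noise = synthetic_spec(
      n_categories = 1, conditions_per_category = 15,
      timepoints_per_condition = 8, n_upper = 3, n_middle = 2,
      n_module_genes = 3, n_background = 6, target_mode = "noise",
      noise_sd = 0.05, seed = 23),
    stop(sprintf("unknown fixture '%s'", name), call. = FALSE))
}

#' Write a synthetic bundle to a directory of TSV files
#'
#' Files: `expression.tsv`, `metadata.tsv`, `binding.tsv`, `edges.tsv`,
#' `sites.tsv`, `ppi.tsv` - the standard formats read back by the data-IO
#' functions.
#'
#' @param bundle A bundle from [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(bundle$expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "metadata.tsv"))
  write_binding(bundle$binding, file.path(dir, "binding.tsv"))
  write_edges(bundle$edges, file.path(dir, "edges.tsv"))
  write_sites(bundle$sites, file.path(dir, "sites.tsv"))
  write_ppi(bundle$ppi, file.path(dir, "ppi.tsv"))
  invisible(dir)
}
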