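# Heterodimer augmentation. A TF that is constitutively expressed is
# invisible to expression-based module finding, yet can act
# condition-specifically as the partner in a heterodimer. For modules with a
# single identified regulator, protein-interaction partners of that
# regulator are screened for constitutive expression and available binding
# data; a qualifying partner is added as a second middle-layer node, with
# its own upstream regulators merged into the upper layer. A degree-matched
# random-replacement control guards against the improvement being a mere
# free-parameter effect.

#' Parameters for the constitutive-expression test
#'
#' @param fold_threshold Fold-change bound (default 2; on log2 data a value
#'   is within bound when `|value| <= log2(fold_threshold)`, the boundary
#'   inclusive).
#' @param fraction Minimum fraction of data points that must lie within the
#'   bound (default 0.95, inclusive).
#' @return A list of class `constitutive_params`.
#' @export
constitutive_params <- function(fold_threshold = 2, fraction = 0.95) {
  abort_if(fold_threshold <= 1, "fold_threshold must be > 1")
  abort_if(!(fraction > 0 && fraction <= 1), "fraction must be in (0, 1]")
  structure(list(fold_threshold = fold_threshold, fraction = fraction),
            class = "constitutive_params")
}

#' Is an expression profile constitutive?
#'
#' `TRUE` iff at least `fraction` of the non-missing log2 values lie within
#' the fold-change bound: `|value| <= log2(fold_threshold)`. A value exactly
#' at twofold (`|log2| = 1`) counts as within. Invariant under permutation
#' of the profile and under a global sign flip.
#'
#' @param profile Numeric vector of log2 ratios (restricted to one
#'   category's experiments); must contain at least one non-missing value.
#' @param params A [constitutive_params()] object.
#' @return Logical scalar.
#' @export
is_constitutive <- function(profile, params = constitutive_params()) {
  v <- profile[!is.na(profile)]
  abort_if(length(v) == 0, "profile is entirely missing")
  mean(abs(v) <= log2(params$fold_threshold)) >= params$fraction
}

#' Propose heterodimer partners for a single regulator
#'
#' Candidates are the protein-interaction neighbors of the anchor TF. A
#' candidate is usable iff binding data are available for it (it appears as
#' a row of the binding p-value matrix) and its expression in the given
#' category is constitutive. An anchor absent from the interaction data
#' yields an empty table.
#'
#' @param anchor_tf The module's sole identified regulator.
#' @param ppi Interaction pair table ([read_ppi()] / [ppi_pairs()]).
#' @param binding Binding p-value matrix (TFs x genes).
#' @param expr An [expression_matrix()].
#' @param category Category label for the constitutive test.
#' @param params A [constitutive_params()] object.
#' @return Data frame with columns `anchor_tf`, `partner_tf`, `category`,
#'   `constitutive`, `has_binding_data`, `usable`, one row per neighbor.
#' @export
propose_partners <- function(anchor_tf, ppi, binding, expr, category,
                             params = constitutive_params()) {
  partners <- ppi_neighbors(anchor_tf, ppi)
  if (length(partners) == 0)
    return(data.frame(anchor_tf = character(0), partner_tf = character(0),
                      category = character(0), constitutive = logical(0),
                      has_binding_data = logical(0), usable = logical(0),
                      stringsAsFactors = FALSE))
  e <- subset_category(expr, category)
  const <- vapply(partners, function(p) {
    if (!(p %in% rownames(e$values))) return(FALSE)
    prof <- e$values[p, ]
    if (all(is.na(prof))) return(FALSE)
    is_constitutive(prof, params)
  }, logical(1))
  has_bind <- partners %in% rownames(binding)
  data.frame(anchor_tf = anchor_tf, partner_tf = partners,
             category = category, constitutive = const,
             has_binding_data = has_bind, usable = const & has_bind,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Augment a single-regulator cascade with a dimer partner
#'
#' Adds the partner as a second middle-layer node; the partner's upstream
#' regulators (after promoter filtering) are merged into the upper layer and
#' the input edges. The partner's expression still reaches the model only
#' through its upstream regulators - the input layer remains the upper layer
#' only. The augmented cascade is re-checked against the upper-layer size
#' bound and the layer-disjointness rule; violations exclude it (returned as
#' `NULL` with a message).
#'
#' @param cascade A [cascade()] with exactly one middle-layer TF.
#' @param partner Partner TF ID, not already in either layer.
#' @param filtered_edges Edge table from [filter_edges_by_promoter()].
#' @param max_upper Maximum upper-layer size (default 15).
#' @return The augmented `cascade`, or `NULL` when excluded.
#' @export
augment_cascade <- function(cascade, partner, filtered_edges,
                            max_upper = 15) {
  abort_if(length(cascade$middle_tfs) != 1,
           "dimer augmentation applies to single-regulator cascades")
  abort_if(partner %in% c(cascade$middle_tfs, cascade$upper_tfs),
           "partner '%s' already appears in the cascade", partner)
  ups <- upstream_regulators(partner, filtered_edges)
  abort_if(length(ups) == 0,
           "partner '%s' has no upstream regulators after promoter filtering; no input path to the new node",
           partner)
  middle <- c(cascade$middle_tfs, partner)
  upper <- sort(unique(c(cascade$upper_tfs, ups)))
  if (length(upper) > max_upper) {
    message(sprintf("augmented upper layer has %d TFs (> %d); excluded",
                    length(upper), max_upper))
    return(NULL)
  }
  if (length(intersect(upper, middle)) > 0) {
    message(sprintf("TF in both layers after augmentation (%s); excluded",
                    paste(intersect(upper, middle), collapse = ", ")))
    return(NULL)
  }
  edges <- rbind(cascade$input_edges,
                 data.frame(upper = ups, middle = partner,
                            stringsAsFactors = FALSE))
  cascade(target_gene = cascade$target_gene, middle_tfs = middle,
          upper_tfs = upper, input_edges = edges,
          category = cascade$category,
          source_module = cascade$source_module)
}

#' Degree-matched random-replacement control
#'
#' Replaces the true partner with randomly selected TFs regulated by the
#' same number of upper-layer TFs (after promoter filtering), so each
#' control network has exactly the true dimer network's number of free
#' parameters. Improvements specific to the true partner then cannot be
#' explained by added flexibility alone.
#'
#' @param cascade The single-regulator `cascade` (before augmentation).
#' @param true_partner The partner being controlled for.
#' @param tf_pool Character vector of candidate replacement TFs; the anchor
#'   and the true partner are excluded automatically.
#' @param filtered_edges Edge table from [filter_edges_by_promoter()].
#' @param n_controls Number of random replacements (default 5).
#' @param seed Integer seed.
#' @param max_upper Maximum upper-layer size (default 15).
#' @return List of augmented control `cascade`s, each carrying attribute
#'   `partner`; errors when fewer than `n_controls` degree-matched TFs
#'   qualify, reporting how many were found.
#' @export
random_partner_control <- function(cascade, true_partner, tf_pool,
                                   filtered_edges, n_controls = 5, seed = 1,
                                   max_upper = 15) {
  pool <- setdiff(tf_pool, c(cascade$middle_tfs, true_partner))
  target_degree <- length(upstream_regulators(true_partner, filtered_edges))
  abort_if(target_degree == 0, "true partner has no upstream regulators")
  degrees <- vapply(pool, function(tf)
    length(upstream_regulators(tf, filtered_edges)), integer(1))
  qualified <- pool[degrees == target_degree &
                      !(pool %in% cascade$upper_tfs)]
  abort_if(length(qualified) < n_controls,
           "only %d degree-matched replacement TFs available (need %d)",
           length(qualified), n_controls)
  chosen <- with_seed(derive_seed(seed, "partner-control"),
                      sample(qualified, n_controls))
  out <- lapply(chosen, function(tf) {
    cs <- augment_cascade(cascade, tf, filtered_edges, max_upper = max_upper)
    if (!is.null(cs)) attr(cs, "partner") <- tf
    cs
  })
  Filter(Negate(is.null), out)
}

#' Compare a single-regulator model, its dimer model and random controls
#'
#' Evaluates the original cascade, the partner-augmented cascade and each
#' degree-matched control with the same protocol, and tabulates the mean
#' test CCs. The qualitative expectation for a true dimer is that the
#' augmented model beats both the single-TF model and the mean of the
#' controls.
#'
#' @param cascade The single-regulator `cascade`.
#' @param partner The proposed dimer partner.
#' @param tf_pool Candidate replacement TFs for the control.
#' @param filtered_edges Edge table from [filter_edges_by_promoter()].
#' @param expr An [expression_matrix()].
#' @param ep An [eval_params()] object.
#' @param tp A [train_params()] object.
#' @param n_controls Number of random replacements (default 5).
#' @return List of class `dimer_comparison`: `single`, `dimer` (both
#'   `eval_result`), `controls` (list of `eval_result`), `table`
#'   (data frame: model, partner, mean_cc, sd_cc, success).
#' @export
compare_dimer <- function(cascade, partner, tf_pool, filtered_edges, expr,
                          ep = eval_params(), tp = train_params(),
                          n_controls = 5) {
  single <- evaluate_cascade(cascade, expr, ep, tp)
  aug <- augment_cascade(cascade, partner, filtered_edges)
  abort_if(is.null(aug), "dimer augmentation was excluded")
  ep_d <- ep
  ep_d$seed <- derive_seed(ep$seed, "dimer", partner)
  dimer <- evaluate_cascade(aug, expr, ep_d, tp)
  controls <- random_partner_control(cascade, partner, tf_pool,
                                     filtered_edges, n_controls = n_controls,
                                     seed = ep$seed)
  control_res <- lapply(controls, function(cs) {
    ep_c <- ep
    ep_c$seed <- derive_seed(ep$seed, "dimer", attr(cs, "partner"))
    evaluate_cascade(cs, expr, ep_c, tp)
  })
  tab <- data.frame(
    model = c("single", "dimer",
              rep("control", length(control_res))),
    partner = c(NA_character_, partner,
                vapply(controls, attr, character(1), "partner")),
    mean_cc = c(single$mean_cc, dimer$mean_cc,
                vapply(control_res, function(r) r$mean_cc, numeric(1))),
    sd_cc = c(single$sd_cc, dimer$sd_cc,
              vapply(control_res, function(r) r$sd_cc, numeric(1))),
    success = c(single$success, dimer$success,
                vapply(control_res, function(r) r$success, logical(1))),
    stringsAsFactors = FALSE)
  structure(list(single = single, dimer = dimer, controls = control_res,
                 table = tab),
            class = "dimer_comparison")
}

#' @export
print.dimer_comparison <- function(x, ...) {
  cat(sprintf(
    "dimer_comparison %s: single %.3f, dimer %.3f, controls mean %.3f (n = %d)\n",
    x$single$target_gene, x$single$mean_cc, x$dimer$mean_cc,
    mean(vapply(x$controls, function(r) r$mean_cc, numeric(1))),
    length(x$controls)))
  invisible(x)
}
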