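# GRAM-style discovery of gene modules: sets of genes bound by a common set
# of regulators under a stringent binding p-value cutoff, refined for
# expression coherence and extended under a relaxed, combined-p criterion.
# Works on one stress category's (replicate-averaged) expression matrix.

#' Parameters for module discovery
#'
#' @param stringent_p Binding p-value cutoff used to form core sets
#'   (default 0.001).
#' @param relaxed_p Per-regulator relaxed binding cutoff used during the
#'   extension step (default 0.01); a candidate's combined p-value (product
#'   over the module's regulators) must not exceed `relaxed_p^|regulators|`.
#' @param missing_frac_max A gene is rejected when more than this fraction of
#'   its expression or binding measurements is missing (default 0.20; the
#'   boundary is strict, exactly 20\% missing is kept).
#' @param min_core_size Minimum number of genes in an initial core set
#'   (default 3).
#' @param coherence_radius Euclidean distance threshold between a gene's
#'   row-normalized (z-scored) profile and a module's mean profile. The
#'   default `NULL` resolves at use to `0.8 * sqrt(m)` for `m` experiments.
#' @return A list of class `gram_params`.
#' @export
gram_params <- function(stringent_p = 0.001, relaxed_p = 0.01,
                        missing_frac_max = 0.20, min_core_size = 3,
                        coherence_radius = NULL) {
  abort_if(!(stringent_p > 0 && stringent_p <= relaxed_p && relaxed_p <= 1),
           "require 0 < stringent_p <= relaxed_p <= 1")
  abort_if(!(missing_frac_max >= 0 && missing_frac_max < 1),
           "require 0 <= missing_frac_max < 1")
  abort_if(min_core_size < 1, "min_core_size must be >= 1")
  structure(list(stringent_p = stringent_p, relaxed_p = relaxed_p,
                 missing_frac_max = missing_frac_max,
                 min_core_size = min_core_size,
                 coherence_radius = coherence_radius),
            class = "gram_params")
}

#' Filter genes by missingness of expression and binding data
#'
#' A gene is admissible iff at most `missing_frac_max` of its expression
#' values and at most `missing_frac_max` of its binding p-values are missing
#' (the rule rejects "more than" the fraction, so the boundary is kept).
#' Genes absent from the binding matrix are rejected.
#'
#' @param expr An [expression_matrix()] (one category, replicates averaged).
#' @param binding Binding p-value matrix (TFs x genes).
#' @param params A [gram_params()] object.
#' @return Character vector of admissible gene IDs, in expression row order.
#' @export
filter_missingness <- function(expr, binding, params = gram_params()) {
  genes <- rownames(expr$values)
  expr_frac <- rowMeans(is.na(expr$values))
  in_binding <- genes %in% colnames(binding)
  bind_frac <- rep(1, length(genes))
  if (nrow(binding) > 0)
    bind_frac[in_binding] <-
      colMeans(is.na(binding[, genes[in_binding], drop = FALSE]))
  keep <- in_binding & expr_frac <= params$missing_frac_max &
    bind_frac <= params$missing_frac_max
  genes[keep]
}

# Row-wise normalization: z-score each gene over the category's experiments
# (pairwise over non-missing entries); zero-variance rows center to 0.
zscore_rows <- function(values) {
  mu <- rowMeans(values, na.rm = TRUE)
  sd <- apply(values, 1, stats::sd, na.rm = TRUE)
  sd[is.na(sd) | sd == 0] <- 1
  (values - mu) / sd
}

# Euclidean distance between a profile and a mean profile with pairwise
# deletion of missing entries, rescaled to the full profile length m so the
# radius is comparable across genes with different missingness.
profile_distance <- function(x, mu) {
  ok <- !is.na(x) & !is.na(mu)
  if (!any(ok)) return(Inf)
  sqrt(mean((x[ok] - mu[ok])^2) * length(mu))
}

#' Find candidate core sets of co-bound genes
#'
#' Per admissible gene, the stringent regulator set is the set of TFs binding
#' it with p-value at most `stringent_p` (missing p-values fail every
#' cutoff). Each distinct non-empty stringent set is a candidate regulator
#' set R; its core is every admissible gene bound by all TFs in R at the
#' stringent level. Cores smaller than `min_core_size` are dropped.
#'
#' @param binding Binding p-value matrix (TFs x genes).
#' @param admissible Character vector of admissible gene IDs.
#' @param params A [gram_params()] object.
#' @return List of `list(regulators =, genes =)` candidates, ordered by
#'   decreasing core size then regulator labels.
#' @export
find_core_sets <- function(binding, admissible, params = gram_params()) {
  admissible <- intersect(admissible, colnames(binding))
  if (length(admissible) == 0) return(list())
  sub <- binding[, admissible, drop = FALSE]
  hit <- !is.na(sub) & sub <= params$stringent_p
  per_gene <- lapply(seq_along(admissible),
                     function(j) rownames(sub)[hit[, j]])
  keys <- vapply(per_gene, paste, character(1), collapse = ",")
  cand <- unique(keys[lengths(per_gene) > 0])
  out <- list()
  for (key in cand) {
    regs <- strsplit(key, ",", fixed = TRUE)[[1]]
    covered <- colSums(!hit[regs, , drop = FALSE]) == 0
    genes <- admissible[covered]
    if (length(genes) >= params$min_core_size)
      out[[length(out) + 1]] <- list(regulators = sort(regs), genes = genes)
  }
  # deduplicate regulator sets that may collide after sorting
  key2 <- vapply(out, function(cs) paste(cs$regulators, collapse = ","),
                 character(1))
  out <- out[!duplicated(key2)]
  ord <- order(-vapply(out, function(cs) length(cs$genes), integer(1)),
               vapply(out, function(cs) paste(cs$regulators, collapse = ","),
                      character(1)))
  out[ord]
}

#' Refine a core set for expression coherence and extend it
#'
#' Refinement keeps core genes whose z-scored profile lies within
#' `coherence_radius` of the core's mean profile and recomputes the mean; if
#' fewer than `min_core_size` genes survive, nothing is returned. Extension
#' then scans every other admissible gene: one within the radius of the
#' refined mean is added iff its combined binding p-value (product over the
#' module's regulators; a missing p-value fails) is strictly below
#' `relaxed_p^|regulators|`.
#'
#' @param core A `list(regulators =, genes =)` candidate from
#'   [find_core_sets()].
#' @param expr An [expression_matrix()] for the module's category.
#' @param binding Binding p-value matrix.
#' @param admissible Character vector of admissible gene IDs.
#' @param params A [gram_params()] object.
#' @return A `gene_module` list (`module_id` unset) or `NULL` when the
#'   refined core is too small. The module's `mean_profile` is the mean
#'   z-scored profile of its final gene set.
#' @export
refine_and_extend <- function(core, expr, binding, admissible,
                              params = gram_params()) {
  z <- zscore_rows(expr$values)
  m <- ncol(z)
  radius <- params$coherence_radius
  if (is.null(radius)) radius <- 0.8 * sqrt(m)

  core_profiles <- z[core$genes, , drop = FALSE]
  mu <- colMeans(core_profiles, na.rm = TRUE)
  d <- apply(core_profiles, 1, profile_distance, mu = mu)
  kept <- core$genes[d <= radius]
  if (length(kept) < params$min_core_size) return(NULL)
  mu <- colMeans(z[kept, , drop = FALSE], na.rm = TRUE)

  candidates <- setdiff(intersect(admissible, colnames(binding)), kept)
  added <- character(0)
  if (length(candidates) > 0) {
    dd <- apply(z[candidates, , drop = FALSE], 1, profile_distance, mu = mu)
    close <- candidates[dd <= radius]
    if (length(close) > 0) {
      pv <- binding[core$regulators, close, drop = FALSE]
      pv[is.na(pv)] <- 1  # missing binding fails any cutoff
      combined <- apply(pv, 2, prod)
      # strictly "less than" the relaxed cutoff
      added <- close[combined < params$relaxed_p^length(core$regulators)]
    }
  }
  genes <- c(kept, added)
  structure(list(module_id = NA_integer_, regulators = core$regulators,
                 genes = genes,
                 category = unique(expr$meta$category)[1],
                 mean_profile = colMeans(z[genes, , drop = FALSE],
                                         na.rm = TRUE)),
            class = "gene_module")
}

#' Discover gene modules from expression and binding data
#'
#' Composes [filter_missingness()], [find_core_sets()] and
#' [refine_and_extend()] on one category's expression matrix. Modules are
#' sorted by decreasing gene count (ties by regulator labels) and numbered
#' in that order; a gene may belong to several modules.
#'
#' @param expr An [expression_matrix()] (one category, replicates averaged).
#' @param binding Binding p-value matrix (TFs x genes).
#' @param params A [gram_params()] object.
#' @return List of `gene_module` objects (possibly empty).
#' @export
find_modules <- function(expr, binding, params = gram_params()) {
  admissible <- filter_missingness(expr, binding, params)
  if (length(admissible) < params$min_core_size) {
    warning("fewer admissible genes than min_core_size; no modules",
            call. = FALSE)
    return(list())
  }
  cores <- find_core_sets(binding, admissible, params)
  mods <- Filter(Negate(is.null),
                 lapply(cores, refine_and_extend, expr = expr,
                        binding = binding, admissible = admissible,
                        params = params))
  if (length(mods) == 0) return(list())
  key <- vapply(mods, function(m)
    paste(paste(m$regulators, collapse = ","),
          paste(sort(m$genes), collapse = ","), sep = "|"), character(1))
  mods <- mods[!duplicated(key)]
  ord <- order(-vapply(mods, function(m) length(m$genes), integer(1)),
               vapply(mods, function(m) paste(m$regulators, collapse = ","),
                      character(1)))
  mods <- mods[ord]
  for (i in seq_along(mods)) mods[[i]]$module_id <- i
  mods
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("gene_module %s [%s]: %d genes, regulators: %s\n",
              x$module_id, x$category, length(x$genes),
              paste(x$regulators, collapse = ", ")))
  invisible(x)
}

#' Write gene modules to TSV
#'
#' One row per module: `module_id`, `category`, comma-joined `regulators`,
#' comma-joined `genes`. The same schema is accepted back by
#' [read_modules()], so externally produced module tables can be substituted.
#'
#' @param modules List of `gene_module` objects.
#' @param path Output path.
#' @return Invisibly, `modules`.
#' @export
write_modules <- function(modules, path) {
  df <- data.frame(
    module_id = vapply(modules, function(m) m$module_id, integer(1)),
    category = vapply(modules, function(m) m$category, character(1)),
    regulators = vapply(modules, function(m)
      paste(m$regulators, collapse = ","), character(1)),
    genes = vapply(modules, function(m)
      paste(m$genes, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(modules)
}

#' Read gene modules from TSV
#'
#' @param path Path to a module table written by [write_modules()] (or an
#'   external tool using the same schema). `mean_profile` is not serialized
#'   and comes back `NULL`.
#' @return List of `gene_module` objects.
#' @export
read_modules <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  abort_if(!all(c("module_id", "category", "regulators", "genes") %in%
                  names(df)),
           "%s: expected columns module_id, category, regulators, genes", path)
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(module_id = as.integer(df$module_id[i]),
                   regulators = strsplit(df$regulators[i], ",")[[1]],
                   genes = strsplit(df$genes[i], ",")[[1]],
                   category = df$category[i],
                   mean_profile = NULL),
              class = "gene_module")
  })
}
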