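# Assembly of three-layer cascades: a gene module's regulators form the
# middle layer; their own upstream regulators (documented edges confirmed by
# a promoter-proximal binding site) form the upper layer; each module gene in
# turn is the output of its own cascade.

#' Construct and validate a three-layer cascade
#'
#' A cascade is a directed three-layer graph: upper-layer TFs feed
#' middle-layer TFs (the module's direct regulators) through `input_edges`,
#' and the middle layer feeds a single target gene. Within one cascade the
#' upper and middle layers are disjoint, every upper TF drives at least one
#' edge and every middle TF receives at least one.
#'
#' @param target_gene Target gene ID.
#' @param middle_tfs Character vector of middle-layer TF IDs.
#' @param upper_tfs Character vector of upper-layer TF IDs.
#' @param input_edges Data frame with columns `upper`, `middle`.
#' @param category Stress-category label.
#' @param source_module Integer ID of the originating module (or `NA`).
#' @return An object of class `cascade`.
#' @export
cascade <- function(target_gene, middle_tfs, upper_tfs, input_edges,
                    category = NA_character_, source_module = NA_integer_) {
  abort_if(length(middle_tfs) < 1, "cascade needs >= 1 middle-layer TF")
  abort_if(length(upper_tfs) < 1, "cascade needs >= 1 upper-layer TF")
  abort_if(length(intersect(upper_tfs, middle_tfs)) > 0,
           "upper and middle layers must be disjoint (%s)",
           paste(intersect(upper_tfs, middle_tfs), collapse = ", "))
  input_edges <- unique(as.data.frame(input_edges)[, c("upper", "middle")])
  rownames(input_edges) <- NULL
  abort_if(!all(input_edges$upper %in% upper_tfs) ||
             !all(input_edges$middle %in% middle_tfs),
           "input_edges reference TFs outside the declared layers")
  abort_if(!all(upper_tfs %in% input_edges$upper),
           "every upper TF must participate in >= 1 input edge")
  abort_if(!all(middle_tfs %in% input_edges$middle),
           "every middle TF must have >= 1 incoming input edge")
  structure(list(target_gene = target_gene,
                 middle_tfs = as.character(middle_tfs),
                 upper_tfs = as.character(upper_tfs),
                 input_edges = input_edges,
                 category = category,
                 source_module = as.integer(source_module)),
            class = "cascade")
}

#' @export
print.cascade <- function(x, ...) {
  cat(sprintf("cascade -> %s [%s]: upper {%s} -> middle {%s} (%d edges)\n",
              x$target_gene, x$category,
              paste(x$upper_tfs, collapse = ","),
              paste(x$middle_tfs, collapse = ","),
              nrow(x$input_edges)))
  invisible(x)
}

#' Keep regulator edges with a promoter-proximal binding site
#'
#' An edge (TF, gene) survives iff the binding-site table records at least
#' one site for that pair within the upstream window: offsets 1..`window_bp`
#' base pairs upstream of the target's transcription start (inclusive
#' window, 1-based offsets). The filter is idempotent and monotone in
#' `window_bp`.
#'
#' @param edges Edge data frame (`regulator`, `target`), e.g. from
#'   [read_edges()].
#' @param sites Binding-site data frame (`tf`, `target`, `upstream_offset`).
#' @param window_bp Window size in base pairs (default 1000).
#' @return The filtered edge data frame.
#' @export
filter_edges_by_promoter <- function(edges, sites, window_bp = 1000) {
  ok_sites <- sites[sites$upstream_offset >= 1 &
                      sites$upstream_offset <= window_bp, , drop = FALSE]
  site_key <- unique(paste(ok_sites$tf, ok_sites$target, sep = "\r"))
  keep <- paste(edges$regulator, edges$target, sep = "\r") %in% site_key
  edges[keep, , drop = FALSE]
}

#' Upstream regulators of a middle-layer TF
#'
#' Regulators documented to target the gene encoding `middle_tf` in the
#' (promoter-filtered) edge set. TFs and the genes encoding them share one ID
#' namespace. Self-regulation is dropped: a TF is never its own upstream
#' regulator in a cascade.
#'
#' @param middle_tf TF ID.
#' @param filtered_edges Edge data frame from [filter_edges_by_promoter()].
#' @return Sorted character vector of upstream TF IDs (possibly empty).
#' @export
upstream_regulators <- function(middle_tf, filtered_edges) {
  regs <- filtered_edges$regulator[filtered_edges$target == middle_tf]
  sort(unique(setdiff(regs, middle_tf)))
}

#' Build three-layer cascades from gene modules
#'
#' For every module with at least `min_module_regulators` regulators, the
#' upper layer is the union of the upstream regulators of its middle-layer
#' TFs. A module is excluded when that union is empty (upstream regulators
#' unknown or lacking a promoter binding site), larger than `max_upper`
#' ("plentiful" regulators), when some middle TF receives no upstream edge,
#' or when a TF would appear in both layers (which would make the mask
#' cyclic). Each surviving module emits one cascade per member gene: the
#' graph is shared, only `target_gene` differs.
#'
#' @param modules List of `gene_module` objects.
#' @param filtered_edges Edge data frame from [filter_edges_by_promoter()].
#' @param max_upper Maximum size of the upper layer (default 15).
#' @param min_module_regulators Minimum regulator count for a module to be
#'   cascaded directly (default 2; single-regulator modules are candidates
#'   for heterodimer augmentation instead).
#' @param complete_wiring If `TRUE`, wire the layers as a complete bipartite
#'   graph instead of the per-edge upstream wiring.
#' @return List of `cascade` objects. Exclusions are reported via messages.
#' @export
build_cascades <- function(modules, filtered_edges, max_upper = 15,
                           min_module_regulators = 2,
                           complete_wiring = FALSE) {
  out <- list()
  for (mod in modules) {
    if (length(mod$regulators) < min_module_regulators) next
    ups <- lapply(mod$regulators, upstream_regulators,
                  filtered_edges = filtered_edges)
    upper <- sort(unique(unlist(ups)))
    if (length(upper) == 0) {
      message(sprintf("module %s: no known upstream regulators; excluded",
                      mod$module_id))
      next
    }
    if (length(upper) > max_upper) {
      message(sprintf("module %s: %d upstream regulators (> %d); excluded",
                      mod$module_id, length(upper), max_upper))
      next
    }
    if (any(lengths(ups) == 0)) {
      message(sprintf(
        "module %s: middle TF without upstream input (%s); excluded",
        mod$module_id,
        paste(mod$regulators[lengths(ups) == 0], collapse = ", ")))
      next
    }
    if (length(intersect(upper, mod$regulators)) > 0) {
      message(sprintf(
        "module %s: TF in both layers (%s); excluded to keep the mask acyclic",
        mod$module_id,
        paste(intersect(upper, mod$regulators), collapse = ", ")))
      next
    }
    if (complete_wiring) {
      edges <- expand.grid(upper = upper, middle = mod$regulators,
                           stringsAsFactors = FALSE)
    } else {
      edges <- do.call(rbind, lapply(seq_along(mod$regulators), function(i)
        data.frame(upper = ups[[i]], middle = mod$regulators[i],
                   stringsAsFactors = FALSE)))
    }
    for (g in mod$genes) {
      out[[length(out) + 1]] <- cascade(
        target_gene = g, middle_tfs = mod$regulators, upper_tfs = upper,
        input_edges = edges, category = mod$category,
        source_module = mod$module_id)
    }
  }
  out
}

#' Serialize cascades to a JSON-lines file
#'
#' One JSON record per line so long runs are resumable and diffable.
#'
#' @param cascades List of `cascade` objects.
#' @param path Output path.
#' @return Invisibly, `cascades`.
#' @export
write_cascades <- function(cascades, path) {
  lines <- vapply(cascades, function(cs) {
    jsonlite::toJSON(list(
      target_gene = cs$target_gene, middle_tfs = cs$middle_tfs,
      upper_tfs = cs$upper_tfs,
      edge_upper = cs$input_edges$upper, edge_middle = cs$input_edges$middle,
      category = cs$category, source_module = cs$source_module),
      auto_unbox = FALSE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(cascades)
}

#' Read cascades from a JSON-lines file
#' @param path Path written by [write_cascades()].
#' @return List of `cascade` objects.
#' @export
read_cascades <- function(path) {
  lapply(readLines(path), function(line) {
    rec <- jsonlite::fromJSON(line)
    cascade(target_gene = rec$target_gene, middle_tfs = rec$middle_tfs,
            upper_tfs = rec$upper_tfs,
            input_edges = data.frame(upper = rec$edge_upper,
                                     middle = rec$edge_middle,
                                     stringsAsFactors = FALSE),
            category = if (is.null(rec$category)) NA_character_
                       else rec$category,
            source_module = if (is.null(rec$source_module)) NA_integer_
                            else rec$source_module)
  })
}

#' Dump cascade edges in GraphViz dot format
#' @param cascades List of `cascade` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cascades_dot <- function(cascades, path) {
  lines <- c("digraph cascades {")
  for (cs in cascades) {
    lines <- c(lines,
               sprintf("  \"%s\" -> \"%s\";", cs$input_edges$upper,
                       cs$input_edges$middle),
               sprintf("  \"%s\" -> \"%s\";", cs$middle_tfs, cs$target_gene))
  }
  writeLines(c(unique(lines), "}"), path)
  invisible(path)
}
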