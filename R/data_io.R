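# Tabular input/output: expression matrices with experiment metadata, binding
# p-value matrices, regulator edge lists, binding-site tables and
# protein-protein interaction pairs. All files are headered, UTF-8 TSV;
# missing values are written as "NA" and read from "" or "NA" (never a
# sentinel number, because the module finder's missingness filter must see
# them as missing).

META_COLS <- c("experiment_id", "category", "condition", "time_point",
               "time_value", "replicate_group")

#' Construct an expression matrix with experiment metadata
#'
#' An expression matrix holds normalized log2 ratios for genes (rows) across
#' experiments (columns), together with per-experiment metadata: stress
#' category, condition, ordinal time point within the condition (`NA` for
#' single-sample conditions), optional time value in minutes, and a replicate
#' group label (experiments sharing a label are replicates of one
#' measurement). Values are taken as-is; no re-normalization is performed.
#'
#' @param values Numeric matrix, rows = genes (rownames required), columns =
#'   experiments (colnames required). `NA` marks missing measurements.
#' @param meta Data frame with columns `experiment_id`, `category`,
#'   `condition`, `time_point`, `time_value`, `replicate_group`, one row per
#'   column of `values`, in column order.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `meta`.
#' @export
expression_matrix <- function(values, meta) {
  abort_if(!is.matrix(values) || !is.numeric(values),
           "`values` must be a numeric matrix")
  abort_if(is.null(rownames(values)) || is.null(colnames(values)),
           "`values` must have gene rownames and experiment colnames")
  abort_if(!is.data.frame(meta) || !all(META_COLS %in% names(meta)),
           "`meta` must contain columns: %s", paste(META_COLS, collapse = ", "))
  meta <- as.data.frame(meta)[, META_COLS]
  meta$experiment_id <- as.character(meta$experiment_id)
  meta$category <- as.character(meta$category)
  meta$condition <- as.character(meta$condition)
  meta$time_point <- as.integer(meta$time_point)
  meta$time_value <- as.numeric(meta$time_value)
  meta$replicate_group <- as.character(meta$replicate_group)
  abort_if(nrow(meta) != ncol(values),
           "metadata has %d rows but matrix has %d columns",
           nrow(meta), ncol(values))
  abort_if(!identical(meta$experiment_id, colnames(values)),
           "metadata experiment_id order must match matrix column order")
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d experiments (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cat(sprintf("categories: %s\n",
              paste(sort(unique(x$meta$category)), collapse = ", ")))
  invisible(x)
}

# Parse a TSV of numbers with row/column-addressed errors on malformed cells.
parse_numeric_tsv <- function(path, key_col) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0))
  abort_if(ncol(raw) < 2, "%s: expected a key column plus data columns", path)
  abort_if(names(raw)[1] != key_col,
           "%s: first column must be named '%s', found '%s'",
           path, key_col, names(raw)[1])
  ids <- raw[[1]]
  abort_if(anyDuplicated(ids) > 0, "%s: duplicated ids in column '%s'",
           path, key_col)
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  vals[cells == "" | cells == "NA"] <- NA_real_
  bad <- which(is.na(vals) & !(cells == "" | cells == "NA"), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("%s: malformed numeric cell '%s' at row '%s', column '%s'",
                 path, cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]), call. = FALSE)
  }
  dimnames(vals) <- list(ids, colnames(cells))
  vals
}

#' Read an expression matrix and its experiment metadata
#'
#' The matrix file is TSV with a first column named `gene` and one column per
#' experiment; the metadata file is TSV with columns `experiment_id`,
#' `category`, `condition`, `time_point`, `time_value`, `replicate_group`.
#' Empty cells and `NA` are read as missing. Every experiment must appear in
#' both files.
#'
#' @param matrix_path Path to the expression TSV.
#' @param meta_path Path to the metadata TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, meta_path) {
  vals <- parse_numeric_tsv(matrix_path, "gene")
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE,
                            na.strings = c("", "NA"))
  abort_if(!all(META_COLS %in% names(meta)),
           "%s: missing metadata columns: %s", meta_path,
           paste(setdiff(META_COLS, names(meta)), collapse = ", "))
  missing_meta <- setdiff(colnames(vals), meta$experiment_id)
  abort_if(length(missing_meta) > 0,
           "experiments in matrix absent from metadata: %s",
           paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(meta$experiment_id, colnames(vals))
  abort_if(length(extra_meta) > 0,
           "experiments in metadata absent from matrix: %s",
           paste(extra_meta, collapse = ", "))
  meta <- meta[match(colnames(vals), meta$experiment_id), ]
  expression_matrix(vals, meta)
}

#' Write an expression matrix and its metadata to TSV
#'
#' Inverse of [read_expression()]: round-trips values, gene order, experiment
#' order and the missingness pattern exactly.
#'
#' @param expr An [expression_matrix()].
#' @param matrix_path,meta_path Output paths.
#' @return Invisibly, `expr`.
#' @export
write_expression <- function(expr, matrix_path, meta_path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(expr$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(expr)
}

#' Read a TF-binding p-value matrix
#'
#' TSV with first column `tf` and one column per gene; values are binding
#' confidence p-values in \[0, 1\], missing entries permitted.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, rows = TFs, columns = genes.
#' @export
read_binding <- function(path) {
  m <- parse_numeric_tsv(path, "tf")
  bad <- which(!is.na(m) & (m < 0 | m > 1))
  abort_if(length(bad) > 0, "%s: binding p-values outside [0, 1]", path)
  m
}

#' Write a TF-binding p-value matrix
#' @param binding Numeric matrix, rows = TFs, columns = genes.
#' @param path Output path.
#' @return Invisibly, `binding`.
#' @export
write_binding <- function(binding, path) {
  df <- data.frame(tf = rownames(binding), binding,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(binding)
}

#' Read a directed regulator-to-gene edge list
#'
#' TSV with columns `regulator` and `target`. Duplicate pairs are collapsed;
#' self-edges are kept as recorded (they are dropped later, when cascades are
#' assembled).
#'
#' @param path Path to the TSV file.
#' @return Data frame with character columns `regulator` and `target`.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  abort_if(!all(c("regulator", "target") %in% names(df)),
           "%s: expected columns 'regulator' and 'target'", path)
  unique(df[, c("regulator", "target")])
}

#' Write a regulator edge list
#' @param edges Data frame with columns `regulator`, `target`.
#' @param path Output path.
#' @return Invisibly, `edges`.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges[, c("regulator", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(edges)
}

#' Read a binding-site table
#'
#' TSV with columns `tf`, `target`, `upstream_offset`; the offset is the
#' 1-based distance in base pairs upstream of the target's transcription
#' start and must be >= 1.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `tf`, `target` (character) and
#'   `upstream_offset` (integer).
#' @export
read_sites <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          colClasses = c(tf = "character",
                                         target = "character",
                                         upstream_offset = "integer"))
  abort_if(!all(c("tf", "target", "upstream_offset") %in% names(df)),
           "%s: expected columns 'tf', 'target', 'upstream_offset'", path)
  abort_if(any(df$upstream_offset < 1),
           "%s: upstream_offset must be >= 1", path)
  df[, c("tf", "target", "upstream_offset")]
}

#' Write a binding-site table
#' @param sites Data frame with columns `tf`, `target`, `upstream_offset`.
#' @param path Output path.
#' @return Invisibly, `sites`.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites[, c("tf", "target", "upstream_offset")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sites)
}

#' Read an undirected protein-protein interaction pair list
#'
#' TSV with columns `a` and `b`. Pairs are undirected: the returned table is
#' stored with each pair once, ordered lexicographically, duplicates (in
#' either orientation) collapsed.
#'
#' @param path Path to the TSV file.
#' @return Data frame with character columns `a`, `b` (a <= b per row).
#' @export
read_ppi <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  abort_if(!all(c("a", "b") %in% names(df)), "%s: expected columns 'a','b'",
           path)
  ppi_pairs(df$a, df$b)
}

#' Canonicalize protein interaction pairs
#' @param a,b Character vectors of interacting protein IDs.
#' @return Data frame with columns `a`, `b`, one row per unordered pair.
#' @export
ppi_pairs <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Write a protein-protein interaction pair list
#' @param ppi Data frame with columns `a`, `b`.
#' @param path Output path.
#' @return Invisibly, `ppi`.
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(ppi[, c("a", "b")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ppi)
}

#' Interaction partners of a protein
#' @param id Protein ID.
#' @param ppi Pair table from [read_ppi()] or [ppi_pairs()].
#' @return Character vector of partners (possibly empty).
#' @export
ppi_neighbors <- function(id, ppi) {
  sort(unique(c(ppi$b[ppi$a == id], ppi$a[ppi$b == id])))
}

#' Average replicate experiments
#'
#' Experiments sharing a `replicate_group` label are collapsed to a single
#' column holding the arithmetic mean of the non-missing replicate values
#' (all-missing stays missing). Averaging precedes any modeling so that
#' replicates of one condition can never straddle a train/test split.
#' Metadata of the group's first member is kept. Replicates disagreeing on
#' category, condition or time point are an error.
#'
#' @param expr An [expression_matrix()].
#' @return An [expression_matrix()] with one column per replicate group, in
#'   order of first appearance.
#' @export
average_replicates <- function(expr) {
  meta <- expr$meta
  abort_if(any(is.na(meta$replicate_group) | meta$replicate_group == ""),
           "replicate_group must be set on all experiments")
  groups <- unique(meta$replicate_group)
  cols <- lapply(groups, function(g) which(meta$replicate_group == g))
  for (i in seq_along(groups)) {
    sub <- meta[cols[[i]], c("category", "condition", "time_point")]
    abort_if(nrow(unique(sub)) != 1,
             "replicate group '%s' disagrees on category/condition/time_point",
             groups[i])
  }
  vals <- vapply(cols, function(ix) {
    v <- rowMeans(expr$values[, ix, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }, numeric(nrow(expr$values)))
  dim(vals) <- c(nrow(expr$values), length(groups))
  new_meta <- meta[vapply(cols, `[`, integer(1), 1), ]
  dimnames(vals) <- list(rownames(expr$values), new_meta$experiment_id)
  expression_matrix(vals, new_meta)
}

#' Partition experiments into stress categories
#'
#' Drops experiments whose condition is excluded (e.g. over-expression and
#' knockout series), then splits the remaining columns by category label.
#' Gene rows are unchanged. A category left empty after filtering is omitted
#' with a warning.
#'
#' @param expr An [expression_matrix()].
#' @param exclude_conditions Character vector of condition labels to drop.
#' @return Named list of [expression_matrix()] objects, one per category.
#' @export
partition_by_category <- function(expr, exclude_conditions = character(0)) {
  keep <- !(expr$meta$condition %in% exclude_conditions)
  cats <- sort(unique(expr$meta$category))
  dropped <- setdiff(cats, unique(expr$meta$category[keep]))
  if (length(dropped) > 0)
    warning(sprintf("categories empty after condition filtering: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  out <- list()
  for (cat in setdiff(cats, dropped)) {
    ix <- which(keep & expr$meta$category == cat)
    out[[cat]] <- expression_matrix(expr$values[, ix, drop = FALSE],
                                    expr$meta[ix, ])
  }
  out
}

#' Restrict an expression matrix to one category's experiments
#' @param expr An [expression_matrix()].
#' @param category Category label.
#' @return An [expression_matrix()] with only that category's columns.
#' @export
subset_category <- function(expr, category) {
  ix <- which(expr$meta$category == category)
  abort_if(length(ix) == 0, "no experiments in category '%s'", category)
  expression_matrix(expr$values[, ix, drop = FALSE], expr$meta[ix, ])
}
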