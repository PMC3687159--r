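# Module discovery: missingness filter, core sets, refine/extend, and exact
# recovery of planted modules.

test_that("missingness filter rejects strictly more than the threshold", {
  genes <- sprintf("g%d", 1:4)
  vals <- named_matrix(rnorm(40), genes, sprintf("e%d", 1:10))
  vals["g2", 1:3] <- NA            # 30% missing expression -> rejected
  vals["g3", 1:2] <- NA            # exactly 20% -> kept (rule is "more than")
  expr <- toy_expr(vals, time_point = 1:10)
  binding <- named_matrix(runif(3 * 4, 0.3, 1), c("T1", "T2", "T3"),
                          genes)
  keep <- filter_missingness(expr, binding, gram_params())
  expect_setequal(keep, c("g1", "g3", "g4"))

  # binding-side missingness and absence from the binding matrix
  binding2 <- binding
  binding2["T1", "g4"] <- NA       # 1/3 missing binding -> rejected
  expect_setequal(filter_missingness(expr, binding2, gram_params()),
                  c("g1", "g3"))
  expect_setequal(
    filter_missingness(expr, binding[, c("g1", "g2", "g3")],
                       gram_params()),
    c("g1", "g3"))                 # g4 absent from binding -> rejected
})

test_that("find_core_sets matches exhaustive enumeration on a toy", {
  genes <- sprintf("g%d", 1:6)
  binding <- named_matrix(0.5, c("T1", "T2", "T3"), genes)
  binding[c("T1", "T2"), c("g1", "g2", "g3", "g4")] <- 1e-4
  cores <- find_core_sets(binding, genes, gram_params())
  expect_length(cores, 1)
  expect_identical(cores[[1]]$regulators, c("T1", "T2"))
  expect_setequal(cores[[1]]$genes, c("g1", "g2", "g3", "g4"))

  # independent oracle: enumerate every regulator subset; a subset is a core
  # iff it is some gene's exact stringent set and covers >= 3 genes
  tfs <- rownames(binding)
  stringent <- lapply(genes, function(g)
    tfs[binding[, g] <= 0.001])
  oracle <- list()
  for (mask in 1:(2^length(tfs) - 1)) {
    R <- tfs[as.logical(bitwAnd(mask, 2^(seq_along(tfs) - 1)))]
    is_cand <- any(vapply(stringent, function(s) setequal(s, R),
                          logical(1)))
    covered <- genes[vapply(genes, function(g)
      all(binding[R, g] <= 0.001), logical(1))]
    if (is_cand && length(covered) >= 3)
      oracle[[length(oracle) + 1]] <- list(regulators = sort(R),
                                           genes = covered)
  }
  expect_length(cores, length(oracle))
  expect_setequal(cores[[1]]$genes, oracle[[1]]$genes)

  # all p-values 1 -> nothing
  expect_length(find_core_sets(named_matrix(1, "T1", genes), genes,
                               gram_params()), 0)
  # 2 genes bound with min_core_size 3 -> dropped
  b2 <- named_matrix(0.5, "T1", genes)
  b2["T1", c("g1", "g2")] <- 1e-4
  expect_length(find_core_sets(b2, genes, gram_params()), 0)
})

test_that("extension adds coherent, relaxed-bound genes and only those", {
  set.seed(1)
  genes <- sprintf("g%d", 1:8)
  sig <- rnorm(12)
  vals <- named_matrix(NA_real_, genes, sprintf("e%d", 1:12))
  for (g in genes[1:5]) vals[g, ] <- sig + rnorm(12, 0, 0.05)
  vals["g6", ] <- sig + rnorm(12, 0, 0.05)   # coherent, relaxed binding
  vals["g7", ] <- sig + rnorm(12, 0, 0.05)   # coherent, one p-value = 1
  vals["g8", ] <- rnorm(12)                  # incoherent
  expr <- toy_expr(vals, time_point = 1:12)
  binding <- named_matrix(0.5, c("T1", "T2"), genes)
  binding[, genes[1:5]] <- 1e-4
  binding[, "g6"] <- 0.005                   # product 2.5e-5 < 0.01^2
  binding["T1", "g7"] <- 1e-4
  binding["T2", "g7"] <- 1                   # product dominated by 1
  binding[, "g8"] <- 1e-4
  core <- list(regulators = c("T1", "T2"), genes = genes[1:5])
  mod <- refine_and_extend(core, expr, binding, genes, gram_params())
  expect_setequal(mod$genes, c(genes[1:5], "g6"))
  expect_length(mod$mean_profile, 12)

  # refinement below min_core_size returns nothing
  scattered <- toy_expr(named_matrix(rnorm(8 * 12, sd = 5), genes,
                                     sprintf("e%d", 1:12)),
                        time_point = 1:12)
  tight <- gram_params(coherence_radius = 1e-6)
  expect_null(refine_and_extend(core, scattered, binding, genes, tight))
})

test_that("planted module is recovered exactly", {
  b <- generate_bundle(make_fixture("planted_module"))
  mods <- find_modules(b$expr, b$binding)
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$genes, b$truth$module_genes)
  expect_setequal(mods[[1]]$regulators, b$truth$middle)
  expect_identical(mods[[1]]$module_id, 1L)
  expect_identical(mods[[1]]$category, "A")

  # exhaustive oracle over regulator subsets: no background gene passes both
  # the stringent-binding and the (trivially satisfied) coherence criteria
  for (g in b$truth$background) {
    expect_true(all(b$binding[, g] > 0.001))
    expect_true(prod(b$binding[b$truth$middle, g]) > 0.01^2)
  }
})

test_that("two disjoint planted modules are both recovered", {
  s1 <- make_fixture("planted_module")
  b1 <- generate_bundle(s1)
  # second module: different TFs/genes, same experiment grid
  vals <- b1$expr$values
  set.seed(99)
  sig <- rnorm(ncol(vals), sd = 1.5)
  extra <- t(vapply(1:4, function(i) sig + rnorm(ncol(vals), 0, 0.1),
                    numeric(ncol(vals))))
  rownames(extra) <- sprintf("H%02d", 1:4)
  expr <- expression_matrix(rbind(vals, extra), b1$expr$meta)
  binding <- rbind(b1$binding,
                   named_matrix(runif(2 * ncol(b1$binding), 0.3, 1),
                                c("XT1", "XT2"), colnames(b1$binding)))
  extra_cols <- named_matrix(runif(nrow(binding) * 4, 0.3, 1),
                             rownames(binding), rownames(extra))
  extra_cols[c("XT1", "XT2"), ] <- 1e-4
  binding <- cbind(binding, extra_cols)
  mods <- find_modules(expr, binding)
  expect_length(mods, 2)
  key <- vapply(mods, function(m) paste(m$regulators, collapse = ","),
                character(1))
  expect_setequal(key, c("MT1,MT2", "XT1,XT2"))
  expect_setequal(mods[[which(key == "XT1,XT2")]]$genes, rownames(extra))
  expect_setequal(mods[[which(key == "MT1,MT2")]]$genes,
                  b1$truth$module_genes)
})

test_that("module invariants and parameter monotonicity hold", {
  b <- generate_bundle(make_fixture("planted_module"))
  params <- gram_params()
  admissible <- filter_missingness(b$expr, b$binding, params)
  mods <- find_modules(b$expr, b$binding, params)
  for (m in mods) {
    expect_true(all(m$genes %in% admissible))
    expect_gte(length(m$genes), params$min_core_size)
    expect_gte(length(m$regulators), 1)
  }
  # tightening stringent_p never adds a core set (well-separated p-values)
  loose <- find_core_sets(b$binding, admissible,
                          gram_params(stringent_p = 0.01))
  tight <- find_core_sets(b$binding, admissible,
                          gram_params(stringent_p = 1e-5))
  key <- function(cs) paste(cs$regulators, collapse = ",")
  expect_true(all(vapply(tight, key, character(1)) %in%
                    vapply(loose, key, character(1))))
  # enlarging the coherence radius never removes an extension gene
  small <- refine_and_extend(list(regulators = b$truth$middle,
                                  genes = b$truth$module_genes[1:3]),
                             b$expr, b$binding, admissible,
                             gram_params(coherence_radius = 2))
  large <- refine_and_extend(list(regulators = b$truth$middle,
                                  genes = b$truth$module_genes[1:3]),
                             b$expr, b$binding, admissible,
                             gram_params(coherence_radius = 6))
  expect_true(all(small$genes %in% large$genes))
})

test_that("modules round-trip through TSV", {
  b <- generate_bundle(make_fixture("planted_module"))
  mods <- find_modules(b$expr, b$binding)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_modules(mods, p)
  back <- read_modules(p)
  expect_length(back, length(mods))
  expect_identical(back[[1]]$regulators, mods[[1]]$regulators)
  expect_identical(back[[1]]$genes, mods[[1]]$genes)
  expect_identical(back[[1]]$category, mods[[1]]$category)
})

test_that("degenerate inputs give empty module lists", {
  genes <- sprintf("g%d", 1:5)
  expr <- toy_expr(named_matrix(rnorm(5 * 6), genes, sprintf("e%d", 1:6)),
                   time_point = 1:6)
  empty_binding <- named_matrix(numeric(0), character(0), genes)
  expect_warning(out <- find_modules(expr, empty_binding), "admissible")
  expect_length(out, 0)
})
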