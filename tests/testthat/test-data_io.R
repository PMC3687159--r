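# Reading, writing, replicate averaging and category partitioning.

test_that("expression round-trip preserves values, order and missingness", {
  vals <- named_matrix(c(1.5, -0.25, 0, 2, NA, -1, 0.125, 3, -2, 1, 0.5, NA),
                       c("g1", "g2", "g3"), c("e1", "e2", "e3", "e4"))
  expr <- toy_expr(vals, time_point = 1:4)
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, mp, dp)
  back <- read_expression(mp, dp)
  expect_identical(back$values, expr$values)
  expect_identical(back$meta, expr$meta)
  expect_identical(sum(is.na(back$values)), 2L)
})

test_that("reader flags malformed cells and metadata inconsistencies", {
  vals <- named_matrix(rnorm(12), c("g1", "g2", "g3"),
                       c("e1", "e2", "e3", "e4"))
  expr <- toy_expr(vals)
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, mp, dp)

  # metadata listing 3 of 4 experiments -> consistency error
  meta3 <- utils::read.delim(dp, colClasses = "character")
  utils::write.table(meta3[1:3, ], dp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_expression(mp, dp), "absent from metadata")

  # malformed numeric cell is named by row and column
  utils::write.table(meta3, dp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- readLines(mp)
  lines[3] <- sub("\t[^\t]*$", "\tnot_a_number", lines[3])
  writeLines(lines, mp)
  expect_error(read_expression(mp, dp), "g2")
})

test_that("empty cells read back as flagged missing values", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\te1\te2\te3\te4",
               "g1\t0.5\t\t1.0\t-1.0",
               "g2\t1\t2\t3\t4",
               "g3\t0\t0\t0\t0"), mp)
  writeLines(c(paste(c("experiment_id", "category", "condition",
                       "time_point", "time_value", "replicate_group"),
                     collapse = "\t"),
               sprintf("e%d\tA\tc1\t%d\tNA\te%d", 1:4, 1:4, 1:4)), dp)
  expr <- read_expression(mp, dp)
  expect_identical(sum(is.na(expr$values)), 1L)
  expect_true(is.na(expr$values["g1", "e2"]))
  expect_identical(expr$values["g3", "e1"], 0)  # zero is not missing
})

test_that("average_replicates takes the mean of non-missing replicates", {
  vals <- named_matrix(c(1, 2, -1,   3, NA, 0,   5, 2, 1),
                       c("g1", "g2", "g3"), c("r1a", "r1b", "r1c"))
  expr <- toy_expr(vals, time_point = c(1, 1, 1),
                   replicate_group = c("m1", "m1", "m1"))
  avg <- average_replicates(expr)
  expect_identical(ncol(avg$values), 1L)
  expect_equal(unname(avg$values[, 1]), c(3, 2, 0))  # (1+3+5)/3, (2+2)/2, ...
  expect_identical(avg$meta$experiment_id, "r1a")

  # all-missing group stays missing
  vals2 <- named_matrix(c(NA, 1, NA, 3), c("g1", "g2"), c("a", "b"))
  expr2 <- toy_expr(vals2, time_point = c(1, 1),
                    replicate_group = c("m", "m"))
  expect_true(is.na(average_replicates(expr2)$values["g1", 1]))
  expect_equal(unname(average_replicates(expr2)$values["g2", 1]), 2)
})

test_that("average_replicates rejects groups straddling conditions", {
  vals <- named_matrix(rnorm(4), c("g1", "g2"), c("a", "b"))
  meta <- data.frame(experiment_id = c("a", "b"), category = "A",
                     condition = c("c1", "c2"), time_point = 1L,
                     time_value = NA_real_, replicate_group = "m",
                     stringsAsFactors = FALSE)
  expect_error(average_replicates(expression_matrix(vals, meta)),
               "disagrees")
})

test_that("average_replicates conserves genes and never adds columns", {
  set.seed(4)
  for (trial in 1:5) {
    n <- sample(4:10, 1)
    vals <- named_matrix(rnorm(3 * n), c("g1", "g2", "g3"),
                         sprintf("e%d", 1:n))
    groups <- sprintf("m%d", sample(ceiling(n / 2), n, replace = TRUE))
    expr <- toy_expr(vals, time_point = rep(1L, n),
                     condition = groups,  # one condition per group
                     replicate_group = groups)
    avg <- average_replicates(expr)
    expect_identical(rownames(avg$values), rownames(vals))
    expect_lte(ncol(avg$values), n)
    expect_identical(ncol(avg$values), length(unique(groups)))
  }
})

test_that("partition_by_category drops excluded conditions and conserves columns", {
  vals <- named_matrix(rnorm(12), c("g1", "g2"), sprintf("e%d", 1:6))
  meta <- data.frame(experiment_id = sprintf("e%d", 1:6),
                     category = c("A", "A", "B", "B", "C", "C"),
                     condition = c("hs1", "hs2", "aa", "nd", "h2o2", "h2o2"),
                     time_point = 1L, time_value = NA_real_,
                     replicate_group = sprintf("e%d", 1:6),
                     stringsAsFactors = FALSE)
  expr <- expression_matrix(vals, meta)

  parts <- partition_by_category(expr)
  expect_named(parts, c("A", "B", "C"))
  expect_true(all(vapply(parts, function(p) ncol(p$values), integer(1)) == 2L))
  # conservation: every column in exactly one part
  expect_setequal(unlist(lapply(parts, function(p) colnames(p$values))),
                  colnames(vals))

  # excluding category C's only condition omits the category with a warning
  expect_warning(parts2 <- partition_by_category(expr, "h2o2"), "empty")
  expect_named(parts2, c("A", "B"))
})

test_that("ppi pairs are symmetric and deduplicated", {
  ppi <- ppi_pairs(c("BAS1", "PHO2", "HIR1"), c("PHO2", "BAS1", "HIR2"))
  expect_identical(nrow(ppi), 2L)
  expect_setequal(ppi_neighbors("BAS1", ppi), "PHO2")
  expect_setequal(ppi_neighbors("PHO2", ppi), "BAS1")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ppi(ppi, p)
  expect_identical(read_ppi(p), ppi)
})
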