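# Shift bounds, assignment enumeration, shifted designs, shift search.

# expression matrix with heterogeneous conditions for bound tests
multi_cond_expr <- function() {
  conds <- list(c1 = 3, c2 = 5, c3 = 9, s1 = 1, s2 = 1)
  ids <- unlist(lapply(names(conds), function(cn)
    sprintf("%s_t%d", cn, seq_len(conds[[cn]]))))
  meta <- data.frame(
    experiment_id = ids,
    category = "A",
    condition = rep(names(conds), unlist(conds)),
    time_point = unlist(lapply(conds, function(m)
      if (m == 1) NA_integer_ else seq_len(m))),
    time_value = NA_real_, replicate_group = ids,
    stringsAsFactors = FALSE)
  set.seed(1)
  vals <- named_matrix(rnorm(3 * length(ids)), c("U1", "U2", "G"), ids)
  expression_matrix(vals, meta)
}

test_that("max_shift is the smallest multi-time-point condition minus one", {
  e <- multi_cond_expr()
  expect_identical(max_shift(e, "A"), 2L)  # min(3,5,9) - 1; singles excluded

  two <- toy_expr(named_matrix(rnorm(4), c("U1", "G"), c("a", "b")),
                  time_point = 1:2)
  expect_identical(max_shift(two, "A"), 1L)

  singles <- toy_expr(named_matrix(rnorm(4), c("U1", "G"), c("a", "b")),
                      condition = c("s1", "s2"),
                      time_point = c(NA, NA))
  expect_error(max_shift(singles, "A"), "time points")
  expect_error(max_shift(e, "Z"), "no experiments")
})

test_that("enumerate_assignments equals brute-force counts for N <= 4, n <= 4", {
  for (N in 1:4) {
    for (ms in 0:3) {
      tfs <- sprintf("U%d", seq_len(N))
      a <- enumerate_assignments(tfs, ms)
      expect_identical(nrow(a), as.integer((ms + 1)^N))
      expect_identical(colnames(a), tfs)
      expect_false(any(duplicated(a)))
      expect_true(all(a >= 0 & a <= ms))
    }
  }
  # N=1, max 0: exactly the zero assignment
  a0 <- enumerate_assignments("U1", 0)
  expect_identical(nrow(a0), 1L)
  expect_identical(unname(a0[1, ]), 0L)
  # representative pairs all present for N=2, max 3
  a2 <- enumerate_assignments(c("U1", "U2"), 3)
  for (want in list(c(0, 0), c(1, 0), c(2, 3)))
    expect_true(any(a2[, 1] == want[1] & a2[, 2] == want[2]))
  # lexicographic order: first TF varies slowest
  expect_identical(unname(a2[1:4, 2]), 0:3)
  expect_identical(unname(a2[1:4, 1]), rep(0L, 4))
  expect_error(enumerate_assignments(sprintf("U%d", 1:10), 3, cap = 100),
               "cap")
})

test_that("build_shifted_design enumerates lagged samples correctly", {
  vals <- t(matrix(c(1:4, 10 * (1:4), 100 * (1:4)), 4, 3))
  dimnames(vals) <- list(c("U1", "U2", "G"), sprintf("e%d", 1:4))
  e <- toy_expr(vals, time_point = 1:4)
  cs <- cascade("G", "M1", c("U1", "U2"),
                data.frame(upper = c("U1", "U2"), middle = "M1"),
                category = "A")

  # all-zero assignment reproduces the synchronous design
  d0 <- build_shifted_design(cs, e, c(U1 = 0L, U2 = 0L))
  expect_identical(unname(d0$X), unname(cbind(1:4, 10 * (1:4))) * 1.0)
  expect_identical(d0$y, 100 * (1:4) * 1.0)

  # shifts (1,0) on 4 time points -> 3 samples with U1 lagged by one
  d10 <- build_shifted_design(cs, e, c(U1 = 1L, U2 = 0L))
  expect_identical(nrow(d10$X), 3L)
  expect_identical(unname(d10$X[, "U1"]), c(1, 2, 3))
  expect_identical(unname(d10$X[, "U2"]), c(20, 30, 40))
  expect_identical(d10$y, c(200, 300, 400))

  # shifts too deep for the condition -> empty design
  d33 <- build_shifted_design(cs, e, c(U1 = 3L, U2 = 3L))
  expect_identical(nrow(d33$X), 1L)  # only j = 4 survives for m = 4
  d_too <- build_shifted_design(
    cascade("G", "M1", c("U1", "U2"),
            data.frame(upper = c("U1", "U2"), middle = "M1"),
            category = "A"),
    toy_expr(vals[, 1:3], time_point = 1:3), c(U1 = 3L, U2 = 3L))
  expect_identical(nrow(d_too$X), 0L)

  expect_error(build_shifted_design(cs, e, c(U1 = 1L)), "cover")
})

test_that("sample counts equal sum over conditions of max(0, m - max k)", {
  set.seed(31)
  conds <- c(c1 = 4, c2 = 3, c3 = 6)
  ids <- unlist(lapply(names(conds), function(cn)
    sprintf("%s_t%d", cn, seq_len(conds[[cn]]))))
  meta <- data.frame(experiment_id = ids, category = "A",
                     condition = rep(names(conds), conds),
                     time_point = unlist(lapply(conds, seq_len)),
                     time_value = NA_real_, replicate_group = ids,
                     stringsAsFactors = FALSE)
  vals <- named_matrix(rnorm(3 * length(ids)), c("U1", "U2", "G"), ids)
  e <- expression_matrix(vals, meta)
  cs <- cascade("G", "M1", c("U1", "U2"),
                data.frame(upper = c("U1", "U2"), middle = "M1"),
                category = "A")
  for (a in seq_len(nrow(enumerate_assignments(cs$upper_tfs, 3)))) {
    k <- enumerate_assignments(cs$upper_tfs, 3)[a, ]
    d <- build_shifted_design(cs, e, k)
    expect_identical(nrow(d$X),
                     as.integer(sum(pmax(0, conds - max(k)))))
  }
})

test_that("single-time-point conditions contribute only when unshifted", {
  ids <- c("c1_t1", "c1_t2", "c1_t3", "s1_t1")
  meta <- data.frame(experiment_id = ids, category = "A",
                     condition = c("c1", "c1", "c1", "s1"),
                     time_point = c(1L, 2L, 3L, NA),
                     time_value = NA_real_, replicate_group = ids,
                     stringsAsFactors = FALSE)
  vals <- named_matrix(rnorm(8), c("U1", "G"), ids)
  e <- expression_matrix(vals, meta)
  cs <- cascade("G", "M1", "U1",
                data.frame(upper = "U1", middle = "M1"), category = "A")
  expect_identical(nrow(build_shifted_design(cs, e, c(U1 = 0L))$X), 4L)
  expect_identical(nrow(build_shifted_design(cs, e, c(U1 = 1L))$X), 2L)
})

test_that("search_shifts recovers planted delays and beats synchronous", {
  b <- generate_bundle(make_fixture("planted_delays"))
  sr <- search_shifts(b$truth$cascade, b$expr,
                      eval_params(n_reps = 20, seed = 1), train_params())
  expect_identical(unname(sr$best), c(2L, 0L, 1L))
  sync_cc <- sr$table$mean_cc[sr$table$shifts == "0,0,0"]
  expect_gt(sr$best_result$mean_cc, sync_cc)
  expect_true(all(sr$table$max_shift == 3L))
  # assignments at the full depth leave 6 samples and are recorded NA
  expect_true(all(is.na(sr$table$mean_cc[sr$table$n_samples < 8])))
  expect_true(length(sr$successes) >= 1)
  expect_true(sr$best_index %in% sr$successes)
  # all-zero row evaluates identically to the synchronous protocol
  sync <- evaluate_cascade(b$truth$cascade, b$expr,
                           eval_params(n_reps = 20, seed = 1),
                           train_params())
  expect_equal(sync_cc, sync$mean_cc)
})

test_that("shift report serializes one row per assignment", {
  b <- generate_bundle(make_fixture("planted_delays"))
  sr <- search_shifts(b$truth$cascade, b$expr,
                      eval_params(n_reps = 4, seed = 2), train_params())
  p <- withr::local_tempfile(fileext = ".tsv")
  write_shift_report(sr, p)
  back <- utils::read.delim(p, colClasses = c(shifts = "character"))
  expect_identical(nrow(back), 64L)
  expect_true("2,0,1" %in% back$shifts)
})
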