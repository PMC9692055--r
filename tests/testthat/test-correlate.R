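test_that("spearman matches hand-computed rank correlations", {
  expect_equal(spearman(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman(1:3, c(3, 2, 1)), -1)
  # ties get average ranks: ranks of (1,1,2,3) are (1.5,1.5,3,4);
  # Pearson of (1.5,1.5,3,4) with (2,1,4,3) is 3.5/sqrt(4.5*5)
  expect_equal(spearman(c(1, 1, 2, 3), c(2, 1, 4, 3)), 3.5 / sqrt(4.5 * 5))
})

test_that("spearman agrees with the stats implementation on random data", {
  set.seed(123)
  for (i in 1:20) {
    x <- sample(1:6, 15, replace = TRUE)   # heavy ties, like length vectors
    y <- rnorm(15)
    expect_equal(spearman(x, y), stats::cor(x, y, method = "spearman"))
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(99)
  x <- sample(1:5, 30, replace = TRUE)
  y <- runif(30, 1, 10)
  r <- spearman(x, y)
  expect_equal(spearman(exp(x), y), r)
  expect_equal(spearman(x, log(y)), r)
  expect_equal(spearman(2 * x + 3, y^3), r)
  expect_equal(spearman(x, x), 1)
})

test_that("spearman rejects degenerate input", {
  expect_error(spearman(1:3, 1:4), "same length")
  expect_error(spearman(1:2, 1:2), "at least 3")
  expect_error(spearman(c(1, NA, 3), 1:3), "missing")
  expect_error(spearman(rep(1, 5), 1:5), "zero rank variance")
})

test_that("rho tables join profiles and efforts, sorted by descending rho", {
  p_nand <- minimal_profile("nand", 2)
  p_eng <- minimal_profile(c("not", "and", "or", "nor"), 2)
  # efforts equal to one profile give that LOT rho = 1
  eff <- data.frame(category = names(p_nand$lengths),
                    mean_effort = as.numeric(p_nand$lengths))
  rt <- lot_rho_table(list(p_nand, p_eng), eff)
  expect_s3_class(rt, "rho_table")
  expect_identical(rt$lot_id[1], "nand")
  expect_equal(rt$rho[1], 1)
  expect_true(all(diff(rt$rho) <= 0))
  expect_identical(rt$n_categories, rep(16L, 2))
  expect_identical(rt$has_parity, c(FALSE, FALSE))

  single <- lot_rho_table(list(p_eng), eff)
  expect_identical(nrow(single), 1L)
})

test_that("missing categories produce a join error unless subsetting is allowed", {
  p <- minimal_profile("nand", 2)
  eff <- data.frame(category = names(p$lengths)[1:12],
                    mean_effort = as.numeric(p$lengths[1:12]))
  expect_error(lot_rho_table(list(p), eff), "lacks 4")
  expect_warning(rt <- lot_rho_table(list(p), eff, allow_subset = TRUE),
                 "12 of 16")
  expect_identical(rt$n_categories, 12L)
})

test_that("cumulative operator curves are monotone and conserve totals", {
  p1 <- minimal_profile("nand", 2)
  p2 <- minimal_profile(c("not", "and", "or", "nor"), 2)
  p3 <- minimal_profile(c("not", "or", "nbicond"), 2)
  eff <- surrogate_efforts(p2, surrogate_config(noise_sd = 0.5, seed = 4))
  rt <- lot_rho_table(list(p1, p2, p3), eff)
  cc <- cumulative_operator_counts(rt)
  expect_identical(dim(cc), c(3L, 9L))
  expect_true(all(apply(cc, 2, function(col) all(diff(col) >= 0))))
  totals <- colSums(sapply(candidate_operators()$name, function(op) {
    vapply(strsplit(rt$operators, "+", fixed = TRUE),
           function(o) op %in% o, logical(1))
  }))
  expect_identical(unname(cc[3, ]), unname(as.integer(totals)))

  rt1 <- lot_rho_table(list(p1), eff)
  cc1 <- cumulative_operator_counts(rt1)
  expect_identical(unname(cc1[1, "nand"]), 1L)
  expect_identical(sum(cc1[1, ]), 1L)

  bad <- rt[order(rt$rho), ]
  expect_error(cumulative_operator_counts(bad), "sorted")
})

test_that("parity split reports group statistics and flags empty groups", {
  rec <- data.frame(lot_id = c("a", "b", "c", "d"),
                    operators = c("nand", "nor", "bicond+nand", "nbicond+nor"),
                    n_operators = c(1L, 1L, 2L, 2L),
                    has_parity = c(FALSE, FALSE, TRUE, TRUE),
                    n_categories = 16L,
                    rho = c(0.8, 0.6, 0.3, 0.1))
  class(rec) <- c("rho_table", "data.frame")
  ps <- parity_split(rec)
  expect_equal(ps$mean_rho, c(0.7, 0.2))
  expect_equal(ps$min_rho, c(0.6, 0.1))
  expect_equal(ps$max_rho, c(0.8, 0.3))

  ps2 <- parity_split(rec[!rec$has_parity, ])
  expect_identical(ps2$n_lots, c(2L, 0L))
  expect_true(is.na(ps2$mean_rho[2]))
})

test_that("operator-count curve tracks group maxima", {
  rec <- data.frame(lot_id = letters[1:3],
                    operators = c("and+not", "nand", "bicond+nand+not"),
                    n_operators = c(2L, 1L, 3L),
                    has_parity = c(FALSE, FALSE, TRUE),
                    n_categories = 16L,
                    rho = c(0.9, 0.5, 0.2))
  class(rec) <- c("rho_table", "data.frame")
  oc <- operators_per_lot_curve(rec)
  expect_identical(oc$n_operators, c(2L, 1L, 3L))
  expect_identical(oc$max_without_parity, 2L)
  expect_identical(oc$max_with_parity, 3L)

  oc1 <- operators_per_lot_curve(rec[2, ])
  expect_length(oc1$n_operators, 1L)
  expect_true(is.na(oc1$max_with_parity))
})
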