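with_missing <- function() {
  codes <- matrix(sample.int(3, 60, TRUE), 20, 3)
  codes[1, ] <- NA          # fully missing row
  codes[5, 2] <- NA
  codes[9, 3] <- NA
  lcca_data_from_codes(codes, n_categories = rep(3, 3))
}

test_that("missingness summaries count cells exactly", {
  set.seed(1)
  d <- with_missing()
  rep_ <- missingness_summary(d)
  expect_equal(rep_$n_missing_cells, 5L)
  expect_equal(rep_$overall_fraction, 5 / 60)
  expect_equal(rep_$all_missing_rows, 1L)
  expect_equal(sum(rep_$per_item_fraction * d$n), 5)
  expect_equal(sum(rep_$per_row_fraction * d$J), 5)

  complete <- random_dataset(10, 2, 2, seed = 2)
  rc <- missingness_summary(complete)
  expect_equal(rc$overall_fraction, 0)
  expect_length(rc$all_missing_rows, 0)

  d22 <- lcca_data_from_codes(matrix(c(1L, 2L, NA, 1L), 2, 2),
                              n_categories = c(2, 2))
  expect_equal(missingness_summary(d22)$overall_fraction, 0.25)
})

test_that("dropping all-missing rows is exact, order-preserving, idempotent", {
  set.seed(1)
  d <- with_missing()
  out <- drop_empty_rows(d)
  expect_equal(out$dropped, 1L)
  expect_equal(out$dropped_rows, 1L)
  expect_equal(out$data$n, 19)
  expect_identical(out$data$codes, d$codes[-1, ])
  again <- drop_empty_rows(out$data)
  expect_equal(again$dropped, 0L)
  expect_identical(again$data$codes, out$data$codes)
})

test_that("ICC matches hand-worked ANOVA cases", {
  expect_equal(icc_per_variable(c(0, 0, 1, 1), c("a", "a", "b", "b")), 1)
  expect_equal(icc_per_variable(c(0, 1, 0, 1), c("a", "a", "b", "b")), 0)
  expect_equal(icc_per_variable(c(1, 2, 3, 4), c("a", "a", "b", "b")),
               3.5 / 4.5, tolerance = 1e-9)
  expect_error(icc_per_variable(c(1, 2), c("a", "a")), "2 groups")
})

test_that("ICC recovers a known variance ratio on simulated grouped data", {
  # 100 groups x 20 members: the one-way ICC estimator has sampling sd
  # ~0.03 at rho = 0.3, so the per-seed cap is set above that spread while
  # the average error must stay within 0.05
  rho <- 0.3
  errs <- vapply(1:10, function(s) {
    set.seed(1200 + s)
    g <- rep(1:100, each = 20)
    y <- rnorm(100, sd = sqrt(rho))[g] + rnorm(2000, sd = sqrt(1 - rho))
    abs(icc_per_variable(y, g) - rho)
  }, 0)
  expect_lt(mean(errs), 0.05)
  expect_true(all(errs < 0.1))
})

test_that("the ICC screen names items above the advisory ceiling", {
  set.seed(7)
  g <- rep(1:30, each = 10)
  codes <- cbind(
    pmin(4, pmax(1, round(2.5 + rnorm(30, sd = 1.5)[g] + rnorm(300, sd = 0.5)))),
    sample.int(4, 300, TRUE))
  d <- lcca_data_from_codes(codes, n_categories = c(4, 4),
                            item_names = c("grouped", "noise"))
  expect_warning(iccs <- icc_screen(d, g), "grouped")
  expect_gt(iccs[["grouped"]], iccs[["noise"]])
})

test_that("imputation completes the data without touching observed cells", {
  set.seed(11)
  sim <- simulate_from_model(separated_model_4(), n = 150, seed = 12)
  d <- sim$data
  miss_mask <- matrix(FALSE, d$n, d$J)
  miss_mask[cbind(sample.int(150, 30), sample.int(6, 30, TRUE))] <- TRUE
  dm <- d
  dm$codes[miss_mask] <- NA
  out <- impute_missing(dm, seed = 3)
  expect_false(anyNA(out$codes))
  expect_identical(out$codes[!miss_mask], d$codes[!miss_mask])
  expect_true(all(out$codes >= 1 & out$codes <= 4))
  # deterministic
  out2 <- impute_missing(dm, seed = 3)
  expect_identical(out$codes, out2$codes)
  # complete input is returned unchanged
  expect_identical(impute_missing(d, seed = 1), d)
})

test_that("a deterministic item dependency is imputed to the mapped category", {
  # item 2 is a fixed bijection of item 1 in every observed row
  set.seed(21)
  x1 <- sample.int(3, 120, TRUE)
  map <- c(2L, 3L, 1L)
  codes <- cbind(x1, map[x1], sample.int(3, 120, TRUE))
  codes[7, 2] <- NA
  d <- lcca_data_from_codes(codes, n_categories = rep(3, 3))
  out <- impute_missing(d, seed = 5)
  expect_equal(unname(out$codes[7, 2]), unname(map[codes[7, 1]]))
})

test_that("imputation rejects inputs it cannot handle", {
  bad <- lcca_data_from_codes(matrix(c(NA, NA, 1L, 2L), 2, 2, byrow = TRUE),
                              n_categories = c(2, 2))
  expect_error(impute_missing(bad), "all-missing rows")
  col <- lcca_data_from_codes(cbind(c(1L, 2L, 1L), c(NA, NA, NA)),
                              n_categories = c(2, 2))
  expect_error(impute_missing(col), "zero observed")
})

test_that("category frequencies are exact and flag rare categories", {
  codes <- cbind(rep(1:4, each = 10),
                 c(rep(1L, 37), 2L, 3L, 4L))
  d <- lcca_data_from_codes(codes, n_categories = c(4, 4))
  freq <- category_frequencies(d)
  even <- freq[freq$item == "item1", ]
  expect_equal(even$proportion, rep(0.25, 4))
  expect_false(any(even$flagged))
  skewed <- freq[freq$item == "item2", ]
  expect_equal(skewed$count, c(37L, 1L, 1L, 1L))
  expect_equal(sum(skewed$flagged), 3)
  expect_equal(sum(skewed$proportion), 1)
  # missing tallied separately, not in the proportions
  d$codes[1, 1] <- NA
  freq2 <- category_frequencies(d)
  expect_equal(sum(freq2[freq2$item == "item1", "count"]), 39)
  expect_equal(attr(freq2, "missing")[["item1"]], 1)
})
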