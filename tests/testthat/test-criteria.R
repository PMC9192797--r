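test_that("free-parameter counts follow (K-1) + K * sum(m_j - 1)", {
  expect_equal(n_free_params(4, rep(4, 6)), 75)
  expect_equal(n_free_params(6, rep(4, 6)), 113)
  expect_equal(n_free_params(1, 2), 1)
  expect_error(n_free_params(2, c(4, 1)), "at least 2")
})

test_that("BIC matches the hand-worked binary example and is linear in nu", {
  ll <- 3 * log(0.75) + log(0.25)
  expect_equal(bic(ll, 1, 4), -2 * ll + log(4), tolerance = 1e-12)
  expect_equal(bic(ll, 1, 4), 5.88497, tolerance = 1e-5)
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(-5, 6, 50) - bic(-5, 3, 50), 3 * log(50), tolerance = 1e-12)
})

test_that("responsibility entropy: one-hot is 0, uniform is n log K", {
  expect_equal(responsibilities_entropy(diag(3)[c(1, 2, 3, 1), ]), 0)
  expect_equal(responsibilities_entropy(matrix(0.5, 10, 2)), 10 * log(2),
               tolerance = 1e-12)
  tau <- matrix(c(0.2, 0.7, 0.8, 0.3), 2, 2)
  expect_equal(responsibilities_entropy(tau),
               responsibilities_entropy(tau[, 2:1]), tolerance = 1e-12)
})

test_that("ICL is BIC plus twice the entropy", {
  expect_equal(icl(5.885, 0), 5.885)
  expect_equal(icl(5.88497, 6.93147), 19.74791, tolerance = 1e-5)
  expect_error(icl(1, -0.1), "non-negative")
})

test_that("Hamming dissimilarity is the proportion of mismatching items", {
  expect_equal(hamming_dissimilarity(c(1, 1), c(1, 2)), 0.5)
  expect_equal(hamming_dissimilarity(c(3, 2, 1), c(3, 2, 1)), 0)
  expect_equal(hamming_dissimilarity(c(1, 2, 3), c(2, 3, 1)), 1)
  expect_error(hamming_dissimilarity(1:3, 1:2), "equal length")
})

test_that("ASW matches the hand-computed 4-point configuration", {
  d <- lcca_data_from_codes(rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(2L, 2L)),
                            n_categories = c(2, 2))
  z <- c(1, 1, 2, 2)
  expect_equal(silhouette_widths(d, z), c(0.5, 0, 1, 1), tolerance = 1e-12)
  expect_equal(average_silhouette_width(d, z), 0.625, tolerance = 1e-12)
})

test_that("ASW is 1 for duplicated mutually distinct patterns and errors at K=1", {
  codes <- rbind(matrix(rep(c(1L, 1L, 1L), 5), ncol = 3, byrow = TRUE),
                 matrix(rep(c(2L, 3L, 2L), 4), ncol = 3, byrow = TRUE))
  d <- lcca_data_from_codes(codes, n_categories = c(2, 3, 2))
  z <- rep(c(1, 2), c(5, 4))
  expect_equal(average_silhouette_width(d, z), 1)
  expect_error(average_silhouette_width(d, rep(1, 9)), "single cluster")
})

test_that("production ASW equals the O(n^2) pairwise oracle", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(50:300, 1)
    d <- random_dataset(n, sample(3:6, 1), sample(2:4, 1), seed = s + 70)
    z <- sample.int(sample(2:5, 1), n, replace = TRUE)
    if (length(unique(z)) < 2) next
    expect_equal(silhouette_widths(d, z), asw_oracle(d, z), tolerance = 1e-12)
  }
})

test_that("ASW agrees with cluster::silhouette on a shared dissimilarity", {
  skip_if_not_installed("cluster")
  set.seed(3)
  sim <- simulate_from_model(separated_model_4(), n = 120, seed = 9)
  z <- sim$labels
  D <- matrix(0, 120, 120)
  for (j in 1:6) D <- D + outer(sim$data$codes[, j], sim$data$codes[, j], "!=")
  sil <- cluster::silhouette(z, dmatrix = D / 6)
  expect_equal(mean(sil[, "sil_width"]),
               average_silhouette_width(sim$data, z), tolerance = 1e-12)
})

test_that("a random partition of i.i.d. data has ASW near zero", {
  vals <- vapply(1:20, function(s) {
    d <- random_dataset(200, 5, 3, seed = 900 + s)
    set.seed(1000 + s)
    average_silhouette_width(d, sample.int(3, 200, TRUE))
  }, 0)
  expect_true(all(abs(vals) < 0.1))
})

test_that("the elbow finds the flattening point and honours tie rules", {
  expect_equal(elbow_candidate(c(100, 80, 40, 38, 37)), 3)
  expect_equal(elbow_candidate(c(50, 40, 30, 20, 10)), 2)   # linear: smallest
  expect_equal(elbow_candidate(c(10, 20, 30, 40)), 2)       # worsening: first
  expect_equal(elbow_candidate(c(100, 80, 40, 38, 37), k = 3:7), 5)
  expect_error(elbow_candidate(c(1, 2)), "at least 3")
})

test_that("the selection table is consistent, deterministic and complete", {
  sim <- simulate_from_model(separated_model_4(), n = 350, seed = 77)
  sel <- selection_table(sim$data, 1, 5, restarts = 4, seed = 11)
  tab <- sel$table
  expect_equal(tab$K, 1:5)
  expect_true(is.na(tab$asw[1]) && all(!is.na(tab$asw[-1])))
  expect_true(all(diff(tab$nu) > 0))
  # ICL - BIC = 2 * entropy, identically
  expect_equal(tab$icl - tab$bic, 2 * tab$entropy, tolerance = 1e-10)
  expect_true(all(tab$icl >= tab$bic - 1e-12))
  expect_true(all(tab$asw[-1] >= -1 & tab$asw[-1] <= 1))
  # K = 1 row is the closed-form pooled fit
  f1 <- fit_em(sim$data, 1, seed = 1)
  expect_equal(tab$bic[1], bic(f1$loglik, tab$nu[1], 350), tolerance = 1e-9)
  # deterministic given the same seed
  sel2 <- selection_table(sim$data, 1, 5, restarts = 4, seed = 11)
  expect_equal(sel$table, sel2$table, tolerance = 1e-12)
  expect_error(selection_table(sim$data, 3, 2), "k_min")
})

test_that("selection on well-separated 4-cluster data recovers K = 4", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_from_model(separated_model_4(), n = 500, seed = 130 + s)
    sel <- selection_table(sim$data, 1, 6, restarts = 5, seed = s,
                           keep_fits = FALSE)
    hits <- hits + (sel$best_bic_k == 4 && sel$best_asw_k == 4)
  }
  expect_gte(hits, 4)
})

test_that("selection tables export to CSV with the documented columns", {
  sim <- simulate_from_model(separated_model_4(), n = 150, seed = 88)
  sel <- selection_table(sim$data, 1, 3, restarts = 2, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_selection_csv(sel, f)
  back <- read.csv(f)
  expect_equal(names(back), c("K", "loglik", "nu", "bic", "entropy", "icl", "asw"))
  expect_equal(back$bic, sel$table$bic, tolerance = 1e-6)
  fj <- tempfile(fileext = ".json")
  write_selection_json(sel, fj)
  bj <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(bj$best_bic_k, sel$best_bic_k)
  expect_equal(bj$table$bic, sel$table$bic, tolerance = 1e-9)
})
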