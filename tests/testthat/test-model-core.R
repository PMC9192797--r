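binary_mix <- function() {
  lcca_model(c(0.5, 0.5), list(list(c(0.9, 0.1)), list(c(0.1, 0.9))))
}

test_that("log-likelihood matches closed forms and hand-worked mixtures", {
  # K = 1, uniform probabilities over 4 categories, 10 x 6 table
  unif <- lcca_model(1, list(rep(list(rep(0.25, 4)), 6)))
  d <- random_dataset(10, 6, 4, seed = 1)
  expect_equal(log_likelihood(unif, d), -10 * 6 * log(4), tolerance = 1e-12)

  # two symmetric classes over one binary item, observations {1, 2}
  d2 <- lcca_data_from_codes(matrix(c(1L, 2L)), n_categories = 2)
  expect_equal(log_likelihood(binary_mix(), d2), 2 * log(0.5), tolerance = 1e-12)
})

test_that("log-likelihood equals the naive per-row oracle on random instances", {
  for (s in 1:8) {
    set.seed(s)
    J <- sample(2:4, 1)
    m <- sample(2:4, 1)
    K <- sample(1:3, 1)
    d <- random_dataset(sample(10:50, 1), J, m, seed = s + 100)
    w <- rexp(K); w <- w / sum(w)
    ip <- lapply(seq_len(K), function(k) lapply(seq_len(J), function(j) {
      a <- rexp(m); a / sum(a)
    }))
    model <- lcca_model(w, ip)
    expect_equal(log_likelihood(model, d), naive_loglik(model, d),
                 tolerance = 1e-9)
  }
})

test_that("log-likelihood is invariant to observation order", {
  d <- random_dataset(40, 3, 3, seed = 5)
  set.seed(9)
  perm <- sample.int(40)
  dp <- lcca_data_from_codes(d$codes[perm, ], n_categories = d$n_categories)
  model <- fit_em(d, 2, restarts = 3, seed = 2)$model
  expect_equal(log_likelihood(model, d), log_likelihood(model, dp),
               tolerance = 1e-9)
  expect_equal(e_step(model, d)[perm, ], e_step(model, dp), tolerance = 1e-12)
})

test_that("the E-step applies Bayes rule and normalises rows", {
  d1 <- lcca_data_from_codes(matrix(1L), n_categories = 2)
  expect_equal(e_step(binary_mix(), d1), matrix(c(0.9, 0.1), 1), tolerance = 1e-12)

  # K = 1: all responsibilities are 1
  one <- lcca_model(1, list(list(c(0.3, 0.7))))
  d <- lcca_data_from_codes(matrix(sample(1:2, 7, TRUE)), n_categories = 2)
  expect_equal(e_step(one, d), matrix(1, 7, 1))

  # identical classes: responsibilities equal the mixture weights
  same <- lcca_model(c(0.3, 0.7), rep(list(list(c(0.4, 0.6))), 2))
  expect_equal(e_step(same, d), matrix(rep(c(0.3, 0.7), each = 7), 7, 2),
               tolerance = 1e-12)
})

test_that("the M-step recovers empirical frequencies and obeys symmetry", {
  d <- lcca_data_from_codes(matrix(c(1L, 2L)), n_categories = 2)
  hard <- matrix(1, 2, 1)
  m0 <- m_step(hard, d, smoothing = 0)
  expect_equal(m0$item_probs[[1]][[1]], c(0.5, 0.5))

  # uniform responsibilities over two classes: both get pooled frequencies
  d4 <- lcca_data_from_codes(matrix(c(1L, 1L, 2L, 1L)), n_categories = 2)
  mu <- m_step(matrix(0.5, 4, 2), d4, smoothing = 0)
  expect_equal(mu$item_probs[[1]][[1]], mu$item_probs[[2]][[1]])
  expect_equal(mu$item_probs[[1]][[1]], c(0.75, 0.25))
  expect_error(m_step(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2), d4),
               "degenerate")
})

test_that("EM reaches a fixed point: m_step(e_step(.)) is idempotent there", {
  sim <- simulate_from_model(separated_model_4(), n = 400, seed = 11)
  fit <- fit_em(sim$data, 4, restarts = 5, seed = 3, tol = 1e-12,
                max_iter = 3000)
  refreshed <- m_step(e_step(fit$model, sim$data), sim$data,
                      smoothing = 1e-10)
  expect_equal(refreshed$weights, fit$model$weights, tolerance = 1e-5)
  for (k in 1:4) for (j in 1:6)
    expect_equal(refreshed$item_probs[[k]][[j]],
                 fit$model$item_probs[[k]][[j]], tolerance = 1e-5)
})

test_that("fit_em is deterministic, monotone and beats the generating model", {
  sim <- simulate_from_model(separated_model_4(), n = 600, seed = 21)
  f1 <- fit_em(sim$data, 4, restarts = 4, seed = 7)
  f2 <- fit_em(sim$data, 4, restarts = 4, seed = 7)
  expect_identical(f1, f2)
  expect_true(all(diff(f1$loglik_trace) >= -1e-8))
  expect_true(f1$converged)
  # maximum-likelihood estimate beats the true generating parameters
  expect_gte(f1$loglik, log_likelihood(separated_model_4(), sim$data))
})

test_that("EM log-likelihood traces are non-decreasing on random instances", {
  worst <- 0
  for (s in 1:50) {
    set.seed(s)
    d <- random_dataset(sample(20:60, 1), sample(2:4, 1), sample(2:4, 1),
                        seed = s + 500)
    f <- fit_em(d, sample(2:3, 1), restarts = 2, seed = s, max_iter = 400)
    worst <- max(worst, max(c(0, -diff(f$loglik_trace))))
  }
  expect_lte(worst, 1e-8)
})

test_that("K = 1 is the closed-form pooled-frequency fit", {
  d <- random_dataset(50, 3, 3, seed = 31)
  f <- fit_em(d, 1, seed = 1, smoothing = 0)
  ll <- 0
  for (j in 1:3) {
    cnt <- tabulate(d$codes[, j], 3)
    ll <- ll + sum(cnt[cnt > 0] * log(cnt[cnt > 0] / 50))
  }
  expect_equal(f$loglik, ll, tolerance = 1e-9)
  expect_true(f$converged)
  expect_equal(f$responsibilities, matrix(1, 50, 1))
})

test_that("fit validation errors fire: K > n, missing data, bad restarts", {
  d <- random_dataset(5, 2, 2, seed = 41)
  expect_error(fit_em(d, 6), "cannot exceed")
  expect_error(fit_em(d, 0), "at least 1")
  expect_error(fit_em(d, 2, restarts = 0), "restarts")
  dm <- d
  dm$codes[1, 1] <- NA
  expect_error(fit_em(dm, 2), "missing")
  all_same <- lcca_data_from_codes(matrix(1L, 6, 2), n_categories = c(2, 2))
  expect_warning(fit_em(all_same, 2, restarts = 2, seed = 1), "identical")
})

test_that("MAP partition takes the argmax with ties to the lowest class", {
  expect_equal(map_partition(matrix(c(0.9, 0.1), 1)), 1L)
  expect_equal(map_partition(matrix(c(0.5, 0.5), 1)), 1L)
  tau <- matrix(c(0.2, 0.8, 0.4, 0.4, 0.4, 0.2), 3, 2)
  expect_equal(map_partition(tau), c(2L, 1L, 1L))
})

test_that("permuting model class labels permutes the partition identically", {
  sim <- simulate_from_model(separated_model_4(), n = 200, seed = 51)
  fit <- fit_em(sim$data, 4, restarts = 3, seed = 5)
  perm <- c(3L, 1L, 4L, 2L)
  pm <- lcca_model(fit$model$weights[perm], fit$model$item_probs[perm])
  z_perm <- map_partition(e_step(pm, sim$data))
  expect_equal(perm[z_perm], fit$partition)
})

test_that("a fit serialises to JSON with weights, probabilities and partition", {
  sim <- simulate_from_model(separated_model_4(), n = 80, seed = 61)
  fit <- fit_em(sim$data, 2, restarts = 2, seed = 1)
  f <- tempfile(fileext = ".json")
  write_fit_json(fit, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$K, 2)
  expect_equal(back$weights, fit$model$weights, tolerance = 1e-12)
  expect_equal(back$partition, fit$partition)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
})
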