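# Independent oracle implementations used to cross-check the production
# code paths. These deliberately use naive loops / full pairwise matrices.

# observed-data log-likelihood by a naive double loop over rows and classes
naive_loglik <- function(model, data) {
  total <- 0
  for (i in seq_len(data$n)) {
    p <- 0
    for (k in seq_len(model$K)) {
      pk <- model$weights[k]
      for (j in seq_len(data$J))
        pk <- pk * model$item_probs[[k]][[j]][data$codes[i, j]]
      p <- p + pk
    }
    total <- total + log(p)
  }
  total
}

# full O(n^2) pairwise-dissimilarity silhouette oracle
asw_oracle <- function(data, partition) {
  n <- data$n
  D <- matrix(0, n, n)
  for (j in seq_len(data$J))
    D <- D + outer(data$codes[, j], data$codes[, j], "!=")
  D <- D / data$J
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- partition == partition[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(partition), partition[i]),
                    function(cl) mean(D[i, partition == cl]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# pair-enumeration ARI and Jaccard over all C(n,2) observation pairs
pair_count_oracle <- function(z1, z2) {
  n <- length(z1)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s1 <- z1[i] == z1[j]
      s2 <- z2[i] == z2[j]
      if (s1 && s2) n11 <- n11 + 1
      else if (s1) n10 <- n10 + 1
      else if (s2) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  total <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  ari <- if (max_index == expected) 1 else (n11 - expected) / (max_index - expected)
  jac <- if (n11 + n10 + n01 == 0) 1 else n11 / (n11 + n10 + n01)
  list(ari = ari, jaccard = jac)
}

# draw complete data directly from a latent class model (known parameters)
simulate_from_model <- function(model, n, seed) {
  set.seed(seed)
  J <- length(model$item_probs[[1]])
  z <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
  codes <- matrix(0L, n, J)
  for (j in seq_len(J)) {
    m_j <- length(model$item_probs[[1]][[j]])
    for (k in seq_len(model$K)) {
      idx <- which(z == k)
      if (length(idx))
        codes[idx, j] <- sample.int(m_j, length(idx), replace = TRUE,
                                    prob = model$item_probs[[k]][[j]])
    }
  }
  list(data = lcca_data_from_codes(codes, n_categories = vapply(
    model$item_probs[[1]], length, 1L)), labels = z)
}

# a well-separated 4-class reference model: 6 items, 4 categories,
# each class concentrated on its own category pattern
separated_model_4 <- function(concentration = 0.9) {
  spread <- (1 - concentration) / 3
  prof <- outer(1:4, 1:6, function(k, j) (k + j - 2) %% 4 + 1)
  item_probs <- lapply(1:4, function(k) {
    lapply(1:6, function(j) {
      a <- rep(spread, 4)
      a[prof[k, j]] <- concentration
      a
    })
  })
  lcca_model(c(0.35, 0.30, 0.20, 0.15), item_probs)
}

# best label alignment of a fitted K-class model to a reference by
# exhaustive permutation (K small), minimising total weight distance
align_permutation <- function(fit_model, ref_model) {
  K <- ref_model$K
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == K), ,
                 drop = FALSE]
  best <- NULL
  best_err <- Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    err <- sum(abs(fit_model$weights[p] - ref_model$weights))
    for (k in seq_len(K))
      for (j in seq_along(ref_model$item_probs[[1]]))
        err <- err + sum(abs(fit_model$item_probs[[p[k]]][[j]] -
                               ref_model$item_probs[[k]][[j]]))
    if (err < best_err) { best_err <- err; best <- p }
  }
  best
}

# maximum absolute parameter error after aligning labels
max_param_error <- function(fit_model, ref_model, perm) {
  err <- max(abs(fit_model$weights[perm] - ref_model$weights))
  for (k in seq_len(ref_model$K))
    for (j in seq_along(ref_model$item_probs[[1]]))
      err <- max(err, max(abs(fit_model$item_probs[[perm[k]]][[j]] -
                                ref_model$item_probs[[k]][[j]])))
  err
}

# small complete random dataset
random_dataset <- function(n, J, m, seed) {
  set.seed(seed)
  lcca_data_from_codes(matrix(sample.int(m, n * J, TRUE), n, J),
                       n_categories = rep(m, J))
}
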