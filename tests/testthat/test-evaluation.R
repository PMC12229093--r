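# Retrieval accuracy, correlation and error metrics.

test_that("adjacent candidate sets match a brute-force distance sort", {
  coords <- as.matrix(expand.grid(x = 0:4, y = 0:4))
  q <- 13L                                  # interior spot (2, 2)
  cs <- adjacent_candidates(coords, q, 5L)
  expect_equal(cs$query_index, q)
  expect_true(q %in% cs$candidate_indices)
  expect_equal(length(cs$candidate_indices), 6L)
  d <- sqrt(rowSums((coords - matrix(coords[q, ], 25, 2, TRUE))^2))
  oracle <- setdiff(order(d, 1:25), q)[1:5]
  expect_setequal(setdiff(cs$candidate_indices, q), oracle)
  # 4 rook neighbors at distance 1 plus one tie-broken diagonal
  expect_equal(sort(d[setdiff(cs$candidate_indices, q)]),
               c(1, 1, 1, 1, sqrt(2)))
  all_cs <- adjacent_candidates(coords, 3L, 24L)
  expect_setequal(all_cs$candidate_indices, 1:25)
  expect_error(adjacent_candidates(coords, 1L, 25L), "smaller")
})

test_that("random candidate sets are seeded and uniformly inclusive", {
  cs1 <- random_candidates(50L, 7L, 10L, rng_seed = 3L)
  expect_identical(cs1, random_candidates(50L, 7L, 10L, rng_seed = 3L))
  expect_false(7L %in% setdiff(cs1$candidate_indices, 7L))
  expect_equal(random_candidates(2L, 1L, 1L, 1L)$candidate_indices,
               c(1L, 2L))
  # marginal inclusion frequency of a fixed spot is ~ k / (n - 1)
  n <- 12L; k <- 4L
  hits <- vapply(1:10000, function(s)
    3L %in% random_candidates(n, 1L, k, s)$candidate_indices, logical(1))
  p <- k / (n - 1)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(hits) - p), 3 * se)
})

test_that("alignment accuracy counts strict cosine wins", {
  set.seed(71)
  V <- matrix(rnorm(60), 10, 6)
  cs <- lapply(1:10, function(q) random_candidates(10L, q, 4L, q))
  expect_equal(alignment_accuracy(V, V, cs), 1.0)   # V = E, distinct rows
  # 3 correct of 5 queries -> 0.6
  E <- V
  E[1:2, ] <- -V[1:2, ]                            # break two pairs
  cs5 <- lapply(1:5, function(q) adjacent_candidates(
    as.matrix(expand.grid(0:4, 0:1)), q, 3L))
  acc <- alignment_accuracy(V[1:10, ], E[1:10, ], cs5)
  expect_equal(acc, mean(vapply(1:5, function(q) q > 2, logical(1))))
  # exact ties count as incorrect
  Vt <- rbind(c(1, 0), c(1, 0))
  expect_equal(alignment_accuracy(Vt, Vt,
                                  list(adjacent_candidates(diag(2), 1L, 1L))),
               0)
})

test_that("alignment accuracy sits at chance for random embeddings and is
           rotation invariant", {
  set.seed(72)
  k <- 5L
  trials <- 1000L
  correct <- vapply(seq_len(trials), function(t) {
    V <- matrix(rnorm(8 * 16), 8, 16)
    E <- matrix(rnorm(8 * 16), 8, 16)
    cs <- list(random_candidates(8L, 1L, k, t))
    alignment_accuracy(V, E, cs)
  }, numeric(1))
  p <- 1 / (k + 1)
  se <- sqrt(p * (1 - p) / trials)
  expect_lt(abs(mean(correct) - p), 3 * se)
  # common rotation preserves every cosine
  V <- matrix(rnorm(12 * 6), 12, 6)
  E <- matrix(rnorm(12 * 6), 12, 6)
  R <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  cs <- lapply(1:12, function(q) random_candidates(12L, q, 5L, q))
  expect_equal(alignment_accuracy(V %*% R, E %*% R, cs),
               alignment_accuracy(V, E, cs))
})

test_that("pearson matches the textbook formula and flags degeneracy", {
  set.seed(73)
  x <- rnorm(50)
  expect_equal(pearson(x, 2 * x + 3), 1.0, tolerance = 1e-10)
  expect_equal(pearson(x, -x), -1.0, tolerance = 1e-10)
  for (i in 1:5) {
    y <- rnorm(50)
    expect_equal(pearson(x, y), stats::cor(x, y), tolerance = 1e-10)
  }
  expect_warning(out <- pearson(x, rep(1, 50)), "constant")
  expect_true(is.na(out))
  # sign property for affine maps
  for (a in c(-2.5, 0.3, 7)) {
    expect_equal(pearson(x, a * x + 1), sign(a), tolerance = 1e-10)
  }
})

test_that("mse_mae and the correlation histogram match loop oracles", {
  X <- matrix(0, 4, 5)
  expect_equal(mse_mae(X, X), c(mse = 0, mae = 0))
  expect_equal(mse_mae(X, X + 1), c(mse = 1, mae = 1))
  set.seed(74)
  A <- matrix(rnorm(20), 4, 5)
  B <- matrix(rnorm(20), 4, 5)
  sq <- 0; ab <- 0
  for (i in 1:4) for (j in 1:5) {
    sq <- sq + (A[i, j] - B[i, j])^2
    ab <- ab + abs(A[i, j] - B[i, j])
  }
  expect_equal(mse_mae(A, B), c(mse = sq / 20, mae = ab / 20))
  expect_error(mse_mae(A, B[, 1:3]), "mismatch")

  v <- c(0.05, 0.15, 0.15, 0.95, 0.4, -0.2)
  edges <- seq(0, 1, by = 0.1)
  h <- correlation_histogram(v, edges)
  expect_equal(sum(h), sum(v >= 0 & v < 1))
  expect_equal(unname(h[2]), 2L)              # [0.1, 0.2)
  one_bin <- correlation_histogram(c(0.55, 0.51), c(0.5, 0.6))
  expect_equal(unname(one_bin), 2L)
  # sort-and-count oracle
  set.seed(75)
  vals <- runif(200, -1, 1)
  h2 <- correlation_histogram(vals, edges)
  oracle <- vapply(seq_len(10), function(b)
    sum(vals >= edges[b] & vals < edges[b + 1]), numeric(1))
  expect_equal(unname(h2), as.integer(oracle))
})

test_that("evaluate_predictions aggregates per-gene and per-spot metrics", {
  set.seed(76)
  X <- matrix(rnorm(60), 6, 10)
  noise <- matrix(rnorm(60, sd = 0.1), 6, 10)
  rep_ <- evaluate_predictions(X, X + noise)
  expect_length(rep_$pcc_gene, 10)
  expect_length(rep_$pcc_spot, 6)
  expect_true(all(rep_$pcc_gene > 0.8, na.rm = TRUE))
  expect_equal(rep_$mse, mean(noise^2))
})
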