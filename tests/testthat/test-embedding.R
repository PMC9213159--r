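random_model <- function(n, d, seed, sd = 0.4) {
  m <- embedding_model(n, d, seed = seed)
  withr::with_seed(seed + 100, {
    m$source <- matrix(stats::rnorm(n * d, sd = sd), n, d)
    m$context <- matrix(stats::rnorm(n * d, sd = sd), n, d)
  })
  m
}

zero_model <- function(n, d) {
  m <- embedding_model(n, d, seed = 1)
  m$source[] <- 0
  m$context[] <- 0
  m
}

test_that("full-softmax context probability matches the naive double loop", {
  z <- zero_model(4, 6)
  expect_equal(softmax_context_prob(z, 2, 1), 0.25)

  for (seed in 1:4) {
    m <- random_model(6, 5, seed)
    for (u in 1:6) {
      probs <- vapply(1:6, function(ni) softmax_context_prob(m, ni, u),
                      numeric(1))
      expect_equal(sum(probs), 1, tolerance = 1e-12)
      for (ni in 1:6) {
        expect_equal(softmax_context_prob(m, ni, u),
                     brute_softmax_prob(m$source, ni, u), tolerance = 1e-12)
      }
    }
  }
})

test_that("node2vec objective has its closed form at zero and matches the oracle", {
  pairs <- cbind(c(1, 2, 3, 1), c(2, 3, 1, 4))
  z <- zero_model(5, 4)
  expect_equal(node2vec_objective(z, pairs), -4 * log(5))

  for (seed in 1:4) {
    m <- random_model(6, 4, seed)
    p <- withr::with_seed(seed, cbind(sample.int(6, 10, TRUE),
                                      sample.int(6, 10, TRUE)))
    expect_equal(node2vec_objective(m, p),
                 brute_node2vec_objective(m$source, p), tolerance = 1e-10)
  }

  # adding a constant shift changes the objective: no translation invariance
  m <- random_model(5, 3, 9)
  shifted <- m
  shifted$source <- m$source + 1
  expect_false(isTRUE(all.equal(node2vec_objective(m, pairs),
                                node2vec_objective(shifted, pairs))))
})

test_that("negative-sampling surrogate has the zero closed form and right expectation", {
  z <- zero_model(5, 4)
  pairs <- cbind(c(1, 2, 3), c(2, 3, 4))
  degs <- c(2, 3, 2, 2, 1)
  expect_equal(negative_sampling_objective(z, pairs, N = 4, degs, seed = 1),
               3 * (1 + 4) * log(0.5))

  # raising the positive score strictly increases the objective
  m <- random_model(5, 4, 3)
  base <- negative_sampling_objective(m, pairs, N = 2, degs, seed = 7)
  m_up <- m
  m_up$source[2, ] <- m$source[1, ] * 5
  up <- negative_sampling_objective(m_up, pairs[1, , drop = FALSE], N = 2,
                                    degs, seed = 7)
  lo <- negative_sampling_objective(m, pairs[1, , drop = FALSE], N = 2,
                                    degs, seed = 7)
  expect_gt(up, lo)

  # Monte-Carlo mean matches the enumerated expectation within 3 sigma
  m5 <- random_model(5, 3, 11)
  pn <- degs^0.75 / sum(degs^0.75)
  exact <- 0
  for (r in seq_len(nrow(pairs))) {
    u <- pairs[r, 1]; ni <- pairs[r, 2]
    pos <- sum(m5$source[ni, ] * m5$source[u, ])
    exact <- exact + log(1 / (1 + exp(-pos)))
    exact <- exact + 2 * sum(pn * vapply(1:5, function(v) {
      log(1 / (1 + exp(sum(m5$source[v, ] * m5$source[u, ]))))
    }, numeric(1)))
  }
  reps <- vapply(1:800, function(s) {
    negative_sampling_objective(m5, pairs, N = 2, degs, seed = 1000 + s)
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - exact), 3 * se)
})

test_that("first-order proximity is a symmetric sigmoid with known values", {
  z <- zero_model(4, 3)
  expect_equal(line1_prob(z, 1, 2), 0.5)
  m <- random_model(6, 4, 2)
  expect_equal(line1_prob(m, 2, 5), line1_prob(m, 5, 2))
  m$source[1, ] <- c(log(3), 0, 0, 0)
  m$source[2, ] <- c(1, 0, 0, 0)
  expect_equal(line1_prob(m, 1, 2), 0.75)
})

test_that("line1 objective equals the per-edge oracle and decreases with similarity", {
  tri <- make_triangle()
  z <- zero_model(3, 4)
  expect_equal(line1_objective(z, tri), 3 * log(2))

  for (seed in 1:4) {
    m <- random_model(3, 4, seed)
    oracle <- 0
    for (r in seq_len(n_edges(tri))) {
      i <- tri$edges[r, 1]; j <- tri$edges[r, 2]
      oracle <- oracle - log(1 / (1 + exp(-sum(m$source[i, ] * m$source[j, ]))))
    }
    expect_equal(line1_objective(m, tri), oracle, tolerance = 1e-12)
    expect_gte(line1_objective(m, tri), 0)
  }

  m <- random_model(3, 4, 8)
  closer <- m
  closer$source[2, ] <- closer$source[2, ] + 0.5 * closer$source[1, ]
  # only edge (1,2)'s dot product raised
  g12 <- graph_from_edges(1, 2, isolated_labels = 3)
  expect_lt(line1_objective(closer, g12), line1_objective(m, g12))
})

test_that("second-order proximity uses context vectors and matches its oracle", {
  z <- zero_model(5, 3)
  expect_equal(line2_prob(z, 2, 1), 1 / 5)
  tri <- make_triangle()
  expect_equal(line2_objective(zero_model(3, 3), tri), 2 * 3 * log(3))

  for (seed in 1:4) {
    m <- random_model(6, 4, seed)
    for (i in 1:6) {
      probs <- vapply(1:6, function(j) line2_prob(m, j, i), numeric(1))
      expect_equal(sum(probs), 1, tolerance = 1e-12)
    }
    m3 <- random_model(3, 4, seed + 20)
    oracle <- 0
    for (r in seq_len(n_edges(tri))) {
      i <- tri$edges[r, 1]; j <- tri$edges[r, 2]
      oracle <- oracle - log(brute_line2_prob(m3$source, m3$context, j, i)) -
        log(brute_line2_prob(m3$source, m3$context, i, j))
    }
    expect_equal(line2_objective(m3, tri), oracle, tolerance = 1e-12)
  }

  # equal source vectors give identical conditional profiles
  m <- random_model(5, 3, 31)
  m$source[2, ] <- m$source[1, ]
  p1 <- vapply(1:5, function(j) line2_prob(m, j, 1), numeric(1))
  p2 <- vapply(1:5, function(j) line2_prob(m, j, 2), numeric(1))
  expect_equal(p1, p2)
})

test_that("sage loss matches hand evaluation and its limits", {
  expect_equal(sage_loss(rep(0, 3), rep(0, 3), matrix(0, 1, 3)), 2 * log(2))
  expect_equal(sage_loss(rep(0, 3), rep(0, 3), matrix(0, 4, 3)), 5 * log(2))

  # strongly aligned positive pair with orthogonal negatives -> N log 2
  zu <- c(40, 0, 0)
  zn <- rbind(c(0, 1, 0), c(0, 0, 1))
  expect_equal(sage_loss(zu, zu, zn), 2 * log(2) +
                 -log(1 / (1 + exp(-1600))), tolerance = 1e-6)

  withr::with_seed(4, {
    zu <- stats::rnorm(4); zv <- stats::rnorm(4); zn <- matrix(stats::rnorm(12), 3, 4)
  })
  hand <- -log(1 / (1 + exp(-sum(zu * zv))))
  for (r in 1:3) hand <- hand - log(1 / (1 + exp(sum(zu * zn[r, ]))))
  expect_equal(sage_loss(zu, zv, zn), hand, tolerance = 1e-12)
  expect_error(sage_loss(zu, zv, zn[0, , drop = FALSE]), "at least one")
})

test_that("mean aggregation is permutation invariant and unit normalized", {
  d <- 4
  v <- c(1, 0, 0, 0)
  expect_equal(aggregate_mean(diag(d), rep(0, d), v, linear = TRUE), v)

  withr::with_seed(6, {
    W <- matrix(stats::rnorm(d * d), d, d)
    b <- stats::rnorm(d)
    X <- matrix(stats::rnorm(5 * d), 5, d)
  })
  out <- aggregate_mean(W, b, X)
  expect_equal(sqrt(sum(out^2)), 1)
  perm <- X[c(3, 1, 5, 2, 4), ]
  expect_equal(aggregate_mean(W, b, perm), out)
  expect_equal(aggregate_mean(matrix(0, d, d), rep(0, d), X, linear = TRUE),
               rep(0, d))
  expect_error(aggregate_mean(W, b, X[0, , drop = FALSE]), "at least one")
})

test_that("analytic gradients agree with central finite differences", {
  n <- 5; d <- 3
  m <- random_model(n, d, 17)
  g <- graph_from_edges(c(1, 1, 2, 3), c(2, 3, 4, 5), w = c(1, 2, 1, 0.5))
  pairs <- rbind(c(1, 2), c(2, 3), c(4, 1))

  f_n2v <- function(v) {
    mm <- m; mm$source <- matrix(v, n, d); node2vec_objective(mm, pairs)
  }
  expect_lt(rel_err(as.vector(node2vec_objective_gradient(m, pairs)),
                    pracma::grad(f_n2v, as.vector(m$source))), 1e-5)

  f_l1 <- function(v) {
    mm <- m; mm$source <- matrix(v, n, d); line1_objective(mm, g)
  }
  expect_lt(rel_err(as.vector(line1_objective_gradient(m, g)),
                    pracma::grad(f_l1, as.vector(m$source))), 1e-5)

  f_l2 <- function(v) {
    mm <- m
    mm$source <- matrix(v[1:(n * d)], n, d)
    mm$context <- matrix(v[-(1:(n * d))], n, d)
    line2_objective(mm, g)
  }
  g2 <- line2_objective_gradient(m, g)
  expect_lt(rel_err(c(as.vector(g2$source), as.vector(g2$context)),
                    pracma::grad(f_l2, c(as.vector(m$source),
                                         as.vector(m$context)))), 1e-5)

  withr::with_seed(21, {
    zu <- stats::rnorm(d); zv <- stats::rnorm(d); zn <- matrix(stats::rnorm(2 * d), 2, d)
  })
  f_sage <- function(v) {
    sage_loss(v[1:d], v[(d + 1):(2 * d)], matrix(v[-(1:(2 * d))], 2, d))
  }
  gs <- sage_loss_gradient(zu, zv, zn)
  expect_lt(rel_err(c(gs$z_u, gs$z_v, as.vector(gs$z_negatives)),
                    pracma::grad(f_sage, c(zu, zv, as.vector(zn)))), 1e-5)
})

test_that("training reduces every loss and is bit-reproducible", {
  sb <- generate_sbm(c(30, 30), 0.25, 0.02, seed = 5)
  for (L in c("node2vec", "line1", "line2", "sage")) {
    cfg <- train_config(loss = L, dim = 8, epochs = 4, seed = 3,
                        walk_length = 8, walks_per_node = 1, window = 3,
                        fanout = 4)
    fit <- suppressWarnings(train_embeddings(sb$graph, cfg))
    expect_lt(fit$loss_trajectory[4], fit$loss_trajectory[1])
    fit2 <- suppressWarnings(train_embeddings(sb$graph, cfg))
    expect_identical(fit$loss_trajectory, fit2$loss_trajectory)
    expect_identical(fit$model$source, fit2$model$source)
  }
})

test_that("partition-aware sage training runs end to end", {
  sb <- generate_sbm(c(25, 25), 0.3, 0.02, seed = 8)
  cfg <- train_config(loss = "sage", dim = 6, epochs = 2, seed = 2,
                      walk_length = 6, walks_per_node = 1, window = 2,
                      fanout = 3, partition_aware = TRUE, k = 2, epsilon = 0.2)
  fit <- suppressWarnings(train_embeddings(sb$graph, cfg))
  expect_true(all(is.finite(fit$loss_trajectory)))
  expect_equal(dim(fit$model$source), c(50, 6))
})

test_that("community recovery scoring behaves at its extremes", {
  # embeddings that are exact block indicators recover labels perfectly
  labels <- rep(1:2, each = 10)
  m <- zero_model(20, 2)
  m$source <- cbind(as.numeric(labels == 1), as.numeric(labels == 2)) +
    withr::with_seed(3, matrix(stats::rnorm(40, sd = 0.01), 20, 2))
  expect_equal(evaluate_community_recovery(m, labels, seed = 1), 1)

  # labels unrelated to structure: ARI near zero
  m2 <- random_model(200, 4, 5)
  rnd <- withr::with_seed(9, sample(rep(1:2, each = 100)))
  expect_lt(abs(evaluate_community_recovery(m2, rnd, seed = 2)), 0.05)

  expect_identical(evaluate_community_recovery(m2, rnd, seed = 2),
                   evaluate_community_recovery(m2, rnd, seed = 2))
  expect_error(evaluate_community_recovery(zero_model(3, 2), 1:2), "one label")
})
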