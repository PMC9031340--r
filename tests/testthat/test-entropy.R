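# Shannon and Tsallis-Havrda-Charvat entropy family: exact values, limits,
# invariants, and analytic gradients.

test_that("shannon entropy matches closed forms and direct summation", {
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  # direct summation oracle: -(0.9 log 0.9 + 0.1 log 0.1)
  expect_equal(shannon_entropy(c(0.9, 0.1)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)))
  expect_equal(shannon_entropy(c(0.9, 0.1)), 0.325083, tolerance = 1e-6)
  # maximal on the uniform distribution
  for (k in 2:6) {
    expect_equal(shannon_entropy(rep(1 / k, k)), log(k))
  }
})

test_that("probability vectors are validated", {
  expect_error(shannon_entropy(c(0.5, 0.6)), "sum to 1")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "outside")
  expect_error(shannon_entropy(numeric(0)), "non-empty")
  expect_error(shannon_cross_entropy(c(0.5, 0.5), c(1, 0, 0)), "same number")
})

test_that("shannon cross-entropy evaluates the Dirac and self cases", {
  expect_equal(shannon_cross_entropy(c(0.8, 0.2), c(1, 0)), -log(0.8))
  expect_equal(shannon_cross_entropy(c(0.5, 0.5), c(0.5, 0.5)), log(2))
  # near-perfect prediction of a Dirac truth: loss within 2 * eps of 0
  eps <- 1e-7
  expect_lt(shannon_cross_entropy(c(1 - eps, eps), c(1, 0)), 2 * eps)
})

test_that("h_alpha generator matches its closed form and endpoints", {
  expect_equal(h_alpha(1, 0.5), 0)
  expect_equal(h_alpha(1, 2), 0)
  expect_equal(h_alpha(0, 0.5), 0)
  expect_equal(h_alpha(0, 3), 0)
  expect_equal(h_alpha(0.5, 2), -0.25)
  expect_equal(h_alpha(0.25, 0.5), -0.5)
  # alpha within dispatch tolerance of 1 uses u log u
  expect_equal(h_alpha(0.5, 1), 0.5 * log(0.5))
  expect_error(h_alpha(0.5, -1), "alpha")
})

test_that("thc entropy matches direct summation and the uniform closed form", {
  expect_equal(thc_entropy(c(0.5, 0.5), 2), 0.5)
  expect_equal(thc_entropy(c(1, 0), 2), 0)
  expect_equal(thc_entropy(c(0, 1), 0.5), 0)
  # uniform closed form (1 - k^(1 - alpha)) / (alpha - 1) vs direct summation
  for (k in 2:10) {
    for (a in c(0.5, 2, 3)) {
      p <- rep(1 / k, k)
      direct <- (1 - sum(p^a)) / (a - 1)
      expect_equal(thc_entropy(p, a), (1 - k^(1 - a)) / (a - 1))
      expect_equal(thc_entropy(p, a), direct)
    }
  }
})

test_that("thc entropy equals the negative sum of its generator", {
  set.seed(1)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    p <- random_prob_vector(k)
    a <- runif(1, 0.2, 4)
    if (abs(a - 1) < 1e-3) a <- a + 0.01
    expect_equal(thc_entropy(p, a), -sum(h_alpha(p, a)), tolerance = 1e-12)
  }
})

test_that("thc cross-entropy matches hand-computed values", {
  expect_equal(thc_cross_entropy(c(0.8, 0.2), c(1, 0), 2), 0.2)
  # (1 / (0.5 - 1)) * (1 - 0.25^(-0.5)) = -2 * (1 - 2) = 2
  expect_equal(thc_cross_entropy(c(0.25, 0.75), c(1, 0), 0.5), 2)
  # both arguments the same (clamped) Dirac: zero within clamping tolerance
  for (a in c(0.5, 2, 3.5)) {
    expect_equal(thc_cross_entropy(c(1, 0), c(1, 0), a), 0, tolerance = 1e-5)
  }
})

test_that("the alpha -> 1 limit recovers the Shannon family", {
  set.seed(2)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    p <- random_prob_vector(k)
    q <- random_prob_vector(k)
    a <- sample(c(1 - 1e-4, 1 + 1e-4), 1)
    expect_lt(abs(thc_entropy(p, a) - shannon_entropy(p)), 1e-3)
    expect_lt(abs(thc_cross_entropy(q, p, a) - shannon_cross_entropy(q, p)),
              1e-3)
  }
})

test_that("thc entropy and cross-entropy are nonnegative on random draws", {
  set.seed(3)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    p <- random_prob_vector(k)
    q <- random_prob_vector(k)
    a <- runif(1, 1e-3, 4)
    expect_gte(thc_entropy(p, a), 0)
    expect_gte(thc_cross_entropy(q, p, a), -1e-12)
  }
})

test_that("all four entropies vanish on matching Dirac distributions", {
  for (k in 2:4) {
    p <- c(1, rep(0, k - 1))
    expect_equal(shannon_entropy(p), 0)
    expect_lt(shannon_cross_entropy(p, p), 1e-5)
    for (a in c(0.5, 2, 3)) {
      expect_equal(thc_entropy(p, a), 0)
      expect_lt(abs(thc_cross_entropy(p, p, a)), 1e-5)
    }
  }
})

test_that("binary shannon loss matches direct evaluation", {
  expect_equal(binary_shannon_loss(1, 0.5), log(2))
  expect_equal(binary_shannon_loss(c(1, 0), c(0.9, 0.1)), -log(0.9))
  expect_equal(binary_shannon_loss(c(1, 0), c(0.9, 0.1)), 0.105361,
               tolerance = 1e-5)
  expect_lt(binary_shannon_loss(1, 1 - 1e-7), 1e-6)
  expect_error(binary_shannon_loss(numeric(0), numeric(0)), "empty")
  expect_error(binary_shannon_loss(c(1, 0), 0.5), "equal length")
})

test_that("binary thc loss matches direct evaluation and the Shannon limit", {
  expect_equal(binary_thc_loss(1, 0.8, alpha = 2), 0.2)
  expect_equal(binary_thc_loss(c(1, 0), c(0.8, 0.2), alpha = 2), 0.2)
  set.seed(4)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    labels <- rbinom(n, 1, 0.5)
    q <- runif(n, 0.05, 0.95)
    a <- sample(c(1 - 1e-4, 1 + 1e-4), 1)
    expect_lt(abs(binary_thc_loss(labels, q, a) -
                    binary_shannon_loss(labels, q)), 1e-3)
  }
})

test_that("analytic gradient matches central finite differences on a grid", {
  qs <- seq(0.01, 0.99, by = 0.02)
  h <- 1e-6
  for (a in c(0.3, 0.5, 1.0, 1.5, 2.3, 3.5)) {
    for (label in c(0, 1)) {
      grad <- binary_thc_loss_gradient(rep(label, length(qs)), qs, a) *
        length(qs) # undo the 1/N factor for per-sample comparison
      fd <- vapply(qs, function(q) {
        (binary_thc_loss(label, q + h, a) - binary_thc_loss(label, q - h, a)) /
          (2 * h)
      }, numeric(1))
      rel <- abs(grad - fd) / pmax(abs(fd), 1e-8)
      expect_lt(max(rel), 1e-5)
    }
  }
})

test_that("gradient closed-form spot checks hold", {
  expect_equal(binary_thc_loss_gradient(1, 0.8, 2), -1)
  expect_equal(binary_thc_loss_gradient(0, 0.5, 2), 1)
  # Shannon gradient at alpha = 1
  expect_equal(binary_thc_loss_gradient(1, 0.8, 1), -1 / 0.8)
})

test_that("mse reconstruction loss averages per-patient squared norms", {
  expect_equal(mse_reconstruction_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_reconstruction_loss(c(1, 2), c(0, 0)), 5)
  expect_equal(
    mse_reconstruction_loss(list(c(2, 1), c(1, 1, 1)),
                            list(c(0, 0), c(0, 0, 0))),
    4
  )
  a <- array(runif(8), dim = c(2, 2, 2))
  expect_equal(mse_reconstruction_loss(a, a), 0)
  expect_error(
    mse_reconstruction_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 1))),
    "shape mismatch"
  )
})

test_that("total loss is the exact sum of its parts", {
  lb <- total_loss(5, 0.2)
  expect_identical(lb$total, lb$rec + lb$pred)
  expect_equal(lb$total, 5.2)
  expect_equal(total_loss(0, 0)$total, 0)
  expect_equal(total_loss(3.7, 0)$total, 3.7)
  expect_error(total_loss(-1, 0), "non-negative")
})
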