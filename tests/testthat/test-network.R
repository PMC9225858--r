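test_that("layer output sides follow the floor convention", {
  expect_identical(output_shape(layer_spec("conv", 7, 2, 0, 32), 32L), 13L)
  expect_identical(output_shape(layer_spec("maxpool", 2, 2, 0), 6L), 3L)
  expect_identical(output_shape(layer_spec("conv", 1, 1, 0, 8), 21L), 21L)
  expect_error(output_shape(layer_spec("conv", 9, 1, 0, 8), 4L), "larger")
})

test_that("the realized shape chain matches the declared architecture", {
  sh <- spec_shapes(gacnn_spec())
  conv_pool <- sh[sh$kind %in% c("conv", "maxpool"), ]
  expect_identical(conv_pool$side, c(13L, 13L, 13L, 6L, 6L, 3L))
  expect_identical(conv_pool$depth, c(32L, 32L, 192L, 192L, 256L, 256L))
})

test_that("per-layer parameter counts and their total are exact", {
  cp <- count_parameters(gacnn_spec())
  expect_identical(cp$params[cp$kind == "conv"], c(1600L, 153792L, 442624L))
  expect_identical(cp$params[cp$kind == "fc"], c(9441280L, 8194L))
  expect_identical(cp$params[cp$kind %in% c("maxpool", "softmax")], rep(0L, 4))
  expect_identical(attr(cp, "total"), 10047490L)
})

test_that("LRN matches its closed form and a triple-loop oracle", {
  expect_identical(lrn(array(0, c(3, 3, 4))), array(0, c(3, 3, 4)))
  # single channel, alpha = 0: b = a / k^beta
  p <- lrn_params(k = 2, alpha = 0, beta = 0.75, n = 1)
  expect_equal(lrn(1, p), 2^-0.75, tolerance = 1e-12)
  a <- c(0.3, -1.2)
  expect_equal(lrn(array(a, c(1, 1, 2)), lrn_params(k = 1.5, alpha = 0.2,
                                                    beta = 0.6, n = 1))[1, 1, ],
               a / (1.5 + 0.2 * a^2)^0.6, tolerance = 1e-12)

  set.seed(10)
  for (i in 1:5) {
    a <- array(rnorm(7 * 6 * 5), c(7, 6, 5))
    pr <- lrn_params(k = 2, alpha = 1e-4, beta = 0.75, n = 5)
    expect_equal(lrn(a, pr), lrn_oracle(a, 2, 1e-4, 0.75, 5), tolerance = 1e-6)
    # and the C++ kernel used inside the network agrees too
    m <- matrix(aperm(a, c(3, 1, 2)), 5)          # channels as rows
    got <- livercnn:::cpp_lrn(m, 2, 1e-4, 0.75, 5L)
    want <- matrix(aperm(lrn_oracle(a, 2, 1e-4, 0.75, 5), c(3, 1, 2)), 5)
    expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("LRN is monotone in neighboring channel energy", {
  set.seed(11)
  a <- abs(rnorm(5)) + 0.1
  p <- lrn_params()
  base <- lrn(a, p)
  for (j in 1:5) {
    a2 <- a; a2[j] <- a2[j] * 2
    out <- lrn(a2, p)
    others <- setdiff(seq_len(5), j)
    expect_true(all(abs(out[others]) <= abs(base[others]) + 1e-12))
  }
})

test_that("Gaussian initialization is seeded, zero-biased, and has the stated scale", {
  m1 <- init_gaussian(seed = 5L)
  m2 <- init_gaussian(seed = 5L)
  expect_identical(m1$params, m2$params)
  for (b in c("b1", "b2", "b3", "b4", "b5"))
    expect_identical(m1$params[[b]], numeric(length(m1$params[[b]])))
  expect_equal(sd(m1$params$W4), 1e-4, tolerance = 0.01)
  expect_equal(mean(m1$params$W4), 0, tolerance = 1e-6)
  expect_error(init_gaussian(sigma = 0), "sigma")
})

test_that("forward produces normalized, deterministic eval-mode probabilities", {
  m <- init_gaussian(seed = 2L)
  set.seed(3)
  X <- matrix(runif(1024 * 6), 1024, 6)
  p1 <- forward(m, X)
  expect_equal(rowSums(p1), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, forward(m, X))
  # near-zero logits at sigma = 1e-4: both classes indistinguishable
  expect_true(all(abs(p1 - 0.5) < 0.01))
  # array input forms agree with the matrix form
  expect_identical(forward(m, array(X, c(32, 32, 6))), p1)
  expect_identical(forward(m, array(X, c(32, 32, 1, 6))), p1)
  expect_error(forward(m, matrix(0, 100, 2)), "pixels")
})

test_that("the C++ backward pass matches central finite differences", {
  m <- init_he(seed = 3L)
  set.seed(4)
  X <- matrix(runif(1024 * 4), 1024, 4)
  y <- c(0L, 1L, 1L, 0L)
  geom <- livercnn:::geom_matrix(m$spec)
  lrnp <- unclass(m$spec$lrn)
  out <- livercnn:::cpp_gacnn_loss_grads(m$params, X, y, geom, lrnp, 0)
  lossfun <- function(params)
    livercnn:::cpp_gacnn_loss_grads(params, X, y, geom, lrnp, 0)$loss
  set.seed(5)
  relerr <- c()
  for (k in names(m$params)) {
    for (i in sample(length(m$params[[k]]), min(3L, length(m$params[[k]])))) {
      h <- 1e-5
      pp <- m$params; pp[[k]][i] <- pp[[k]][i] + h; lp <- lossfun(pp)
      pp[[k]][i] <- pp[[k]][i] - 2 * h; lm <- lossfun(pp)
      fd <- (lp - lm) / (2 * h)
      an <- out$grads[[k]][i]
      relerr <- c(relerr, abs(fd - an) / max(1e-10, abs(fd) + abs(an)))
    }
  }
  # almost all coordinates agree to high precision; finite differences may
  # cross a ReLU / max-pool kink at a handful of coordinates
  expect_gte(mean(relerr < 1e-5), 0.9)
  expect_lt(median(relerr), 1e-6)
})

test_that("dropout is active in train mode only", {
  m <- init_he(seed = 6L)
  set.seed(7)
  X <- matrix(runif(1024 * 3), 1024, 3)
  mt <- set_mode(m, "train")
  set.seed(1); a <- forward(mt, X)
  set.seed(2); b <- forward(mt, X)
  expect_false(identical(a, b))       # stochastic under different RNG states
  set.seed(1); a2 <- forward(mt, X)
  expect_identical(a, a2)             # but reproducible under the same state
  expect_identical(forward(m, X), forward(m, X))
})
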