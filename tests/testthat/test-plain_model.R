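# Plaintext reference model: cell algebra, forward pass against an
# independent recurrence, Weibull head, concordance index vs the survival
# package.

test_that("weight containers validate dimensions", {
  expect_error(gru_cell_weights(matrix(0, 4, 3), matrix(0, 4, 4), numeric(4),
                                matrix(0, 4, 3), matrix(0, 4, 4), numeric(4),
                                matrix(0, 4, 3), matrix(0, 4, 4), numeric(3)),
               class = "hegru_shape_error")
  m <- zero_gru_model()
  expect_identical(m$layer1$n_i, 70L)
  expect_true(m$layer2_returns_last_state_only)
})

test_that("zero-weight cell halves the state in both modes", {
  w <- zero_gru_model(c(8L, 4L, 3L))$layer1
  set.seed(23)
  v <- runif(4, -1, 1)
  x <- runif(8, -1, 1)
  exact <- gru_cell_plain(x, v, w, mode = "exact")
  clamped <- gru_cell_plain(x, v, w, mode = "clamped")
  expect_equal(exact, 0.5 * v, tolerance = 1e-12)
  expect_lt(max(abs(clamped - 0.5 * v)), 10 * EPS_CHEB)
})

test_that("exact and clamped modes agree when nothing clips", {
  set.seed(24)
  w <- rand_gru_layer(6L, 10L, sd = 0.15)
  for (trial in 1:20) {
    x <- runif(10, -0.5, 0.5)
    h <- runif(6, -0.5, 0.5)
    a <- gru_cell_plain(x, h, w, mode = "exact")
    b <- gru_cell_plain(x, h, w, mode = "clamped")
    expect_lt(max(abs(a - b)), 20 * EPS_CHEB)
  }
})

test_that("the two state-update forms are algebraically identical", {
  set.seed(25)
  z <- runif(16); h <- runif(16, -2, 2); g <- runif(16, -1, 1)
  expect_lt(max(abs((z * h + (1 - z) * g) - (g + z * (h - g)))), 1e-12)
})

test_that("model_forward matches an independent 2-step recurrence", {
  # hand-rolled recurrence with its own algebra on a tiny 2x2 model
  W <- matrix(c(0.5, -0.3, 0.2, 0.1), 2, 2)
  U <- matrix(c(0.1, 0.4, -0.2, 0.3), 2, 2)
  b <- c(0.05, -0.1)
  l1 <- gru_cell_weights(W, U, b, W * 0.5, U * 0.5, b * 2, W * -1, U * 2, b)
  l2 <- gru_cell_weights(W * 0.8, U * 1.2, b, W, U, b, W * 0.3, U * -0.4, b)
  dW <- matrix(c(1, 0, 0, 1), 2, 2)
  model <- gru_model_weights(l1, l2, dW, c(0.1, 0.2))
  x <- matrix(c(0.3, -0.2, 0.7, 0.1), 2, 2, byrow = TRUE)
  step <- function(xt, h, L) {
    z <- 1 / (1 + exp(-(L$W_z %*% xt + L$U_z %*% h + L$b_z)))
    r <- 1 / (1 + exp(-(L$W_r %*% xt + L$U_r %*% h + L$b_r)))
    g <- tanh(L$W_g %*% xt + L$U_g %*% (h * r) + L$b_g_vec)
    as.numeric(z * h + (1 - z) * g)
  }
  h1a <- step(x[1, ], c(0, 0), l1)
  h1b <- step(x[2, ], h1a, l1)
  h2a <- step(h1a, c(0, 0), l2)
  h2b <- step(h1b, h2a, l2)
  want <- as.numeric(dW %*% h2b + c(0.1, 0.2))
  got <- model_forward(x, model, mode = "exact")
  expect_equal(c(got$a, got$b), want, tolerance = 1e-12)
})

test_that("zero model returns the dense bias; visit order matters otherwise", {
  m0 <- zero_gru_model(c(6L, 4L, 3L))
  m0$dense$b <- c(0.7, -0.3)
  got <- model_forward(matrix(runif(6), 1, 6), m0)
  expect_equal(c(got$a, got$b), c(0.7, -0.3), tolerance = 1e-12)
  m <- rand_gru_model(26, sd = 0.5, dims = c(6L, 4L, 3L))
  x <- matrix(rnorm(12), 2, 6)
  f1 <- model_forward(x, m)
  f2 <- model_forward(x[2:1, ], m)
  expect_gt(abs(f1$a - f2$a) + abs(f1$b - f2$b), 1e-6)
})

test_that("Weibull activation is positive, monotone, and fixed at the anchors", {
  w <- weibull_activate(0, 0)
  expect_equal(w$alpha, 1)
  expect_equal(w$beta, log(2))
  a <- seq(-5, 5, length.out = 21L)
  expect_true(all(diff(weibull_activate(a, 0)$alpha) > 0))
  expect_true(all(diff(weibull_activate(0, a)$beta) > 0))
  big <- weibull_activate(1000, 1000)
  expect_true(is.finite(big$beta) && big$beta > 0)
  expect_equal(weibull_median(2, 1), 2 * log(2))
})

test_that("concordance index: perfect, reversed, and null orderings", {
  t <- c(1, 2, 3, 4, 5)
  e <- rep(1L, 5)
  expect_equal(concordance_index(t, e, -t), 1)   # higher risk, earlier event
  expect_equal(concordance_index(t, e, t), 0)
  set.seed(27)
  tt <- rexp(5000); rr <- rnorm(5000)
  cnull <- concordance_index(tt, rep(1L, 5000), rr)
  expect_gt(cnull, 0.47); expect_lt(cnull, 0.53)
  expect_error(concordance_index(c(1, 2), c(0L, 0L), c(1, 2)),
               class = "hegru_input_error")
})

test_that("concordance agrees with survival::concordance on censored data", {
  skip_if_not_installed("survival")
  set.seed(28)
  for (trial in 1:100) {
    n <- 60L
    t <- rexp(n) + 1e-3
    e <- rbinom(n, 1L, 0.6)
    if (sum(e) == 0L) e[1L] <- 1L
    r <- rnorm(n)
    ours <- concordance_index(t, e, r)
    theirs <- survival::concordance(survival::Surv(t, e) ~ r,
                                    reverse = TRUE)$concordance
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("weights JSON roundtrip preserves the model exactly", {
  m <- rand_gru_model(29, dims = c(7L, 5L, 4L))
  f <- withr::local_tempfile(fileext = ".json")
  write_weights_json(m, f)
  m2 <- read_weights_json(f)
  expect_equal(m2$layer1$W_z, m$layer1$W_z, tolerance = 1e-15)
  expect_equal(m2$dense$b, m$dense$b, tolerance = 1e-15)
  x <- matrix(rnorm(21), 3, 7)
  expect_equal(model_forward(x, m)$a, model_forward(x, m2)$a,
               tolerance = 1e-12)
  expect_error(read_weights_json(file.path(tempdir(), "nope.json")),
               class = "hegru_io_error")
})
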