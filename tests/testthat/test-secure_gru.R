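# Secure GRU: masked refresh, cell equivalence with the clamped reference,
# full inference (single and batch), refresh sufficiency, transcript growth.

test_that("masked refresh restores the full level and preserves the message", {
  params <- he_params()
  ses <- secure_session(params, crypto_seed = 61L)
  keys <- ses$client$keys
  set.seed(30)
  v <- runif(params$slot_count, -5, 5)
  ct <- he_encrypt(v, keys)
  for (i in 1:params$max_level) ct <- he_mul(ct, rep(1, params$slot_count))
  expect_identical(ct$level, 0L)
  rf <- masked_refresh(ct, ses)
  expect_identical(rf$level, params$max_level)
  expect_lt(max(abs(he_decrypt(rf, keys) - v)), 1e-5)
  rf2 <- masked_refresh(rf, ses)
  expect_lt(max(abs(he_decrypt(rf2, keys) - he_decrypt(rf, keys))), 1e-5)
  # both directions logged
  df <- transcript_df(ses$transcript)
  expect_true(all(c("s2c", "c2s") %in% df$direction[df$round == "refresh"]))
})

test_that("zero-weight secure cell returns 0.5 * h_prev", {
  params <- he_params()
  ses <- secure_session(params, crypto_seed = 62L)
  lay <- packed_layout(4096L, 128L, "single")
  sm <- hegru:::prep_server_model(ses, zero_gru_model(), lay, 1L)
  set.seed(31)
  hv <- runif(32, -1, 1)
  xv <- runif(70, -1, 1)
  ct_x <- pack_batch(list(xv), lay, ses$client$keys)
  ct_h <- he_encrypt(c(hv, numeric(4096 - 32)), ses$client$keys)
  ht <- secure_gru_cell(ct_x, ct_h, sm$layer1, ses, lay, 1L)
  expect_lt(max(abs(he_decrypt(ht, ses$client$keys)[1:32] - 0.5 * hv)),
            EPS_CELL)
})

test_that("secure cell matches the plain cell when nothing clips, and the
           clamped reference when pre-activations exceed the range", {
  params <- he_params()
  ses <- secure_session(params, crypto_seed = 63L)
  lay <- packed_layout(4096L, 128L, "single")
  set.seed(32)
  small <- rand_gru_layer(32L, 70L, sd = 0.05)
  big <- rand_gru_layer(32L, 70L, sd = 1.2)
  for (cw in list(small, big)) {
    model <- gru_model_weights(cw, rand_gru_layer(20L, 32L, 0.1),
                               matrix(0, 2, 20), c(0, 0))
    sm <- hegru:::prep_server_model(ses, model, lay, 1L)
    xv <- runif(70, -1, 1)
    hv <- runif(32, -1, 1)
    ct_x <- pack_batch(list(xv), lay, ses$client$keys)
    ct_h <- he_encrypt(c(hv, numeric(4096 - 32)), ses$client$keys)
    got <- he_decrypt(secure_gru_cell(ct_x, ct_h, sm$layer1, ses, lay, 1L),
                      ses$client$keys)[1:32]
    ref <- gru_cell_plain(xv, hv, cw, mode = "clamped", cheb = ses$cheb,
                          cfg = ses$cfg)
    expect_lt(max(abs(got - ref)), EPS_CELL)
    if (identical(cw, small)) {
      # no clipping: the unclamped plain cell agrees too
      exact <- gru_cell_plain(xv, hv, cw, mode = "exact")
      expect_lt(max(abs(got - exact)), 20 * EPS_CHEB)
    } else {
      # clipping active: the secure cell matches the clamped oracle, NOT the
      # unclamped plain cell
      pre <- cw$W_z %*% xv + cw$U_z %*% hv + cw$b_z
      expect_gt(max(abs(pre)), 10) # confirm the range is actually exceeded
      exact <- gru_cell_plain(xv, hv, cw, mode = "exact")
      expect_gt(max(abs(got - exact)), EPS_CELL)
    }
  }
})

test_that("single-query inference: cell counter is 2N and output matches the
           clamped-reference pipeline", {
  params <- he_params()
  ses <- secure_session(params, crypto_seed = 64L)
  model <- rand_gru_model(33, sd = 0.35)
  set.seed(34)
  for (n_visits in c(1L, 5L)) {
    x <- matrix(runif(n_visits * 70, -1, 1), n_visits, 70)
    res <- secure_infer(x, model, ses)
    expect_identical(res$cells, 2L * n_visits)
    ref <- model_forward(x, model, mode = "clamped", cheb = ses$cheb,
                         cfg = ses$cfg)
    expect_lt(abs(res$a - ref$a), EPS_MODEL)
    expect_lt(abs(res$b - ref$b), EPS_MODEL)
    wp <- weibull_activate(ref$a, ref$b)
    expect_equal(res$alpha, wp$alpha, tolerance = 1e-3)
    expect_gt(res$refreshes, 0L)
  }
  expect_error(secure_infer(matrix(0, 1, 69), model, ses),
               class = "hegru_shape_error")
  expect_error(secure_infer(matrix(0, 0, 70), model, ses),
               class = "hegru_input_error")
})

test_that("batch inference equals the single-query path patient by patient", {
  params <- he_params()
  ses <- secure_session(params, crypto_seed = 65L)
  model <- rand_gru_model(35, sd = 0.35)
  set.seed(36)
  pats <- lapply(1:4, function(i) matrix(runif(2 * 70, -1, 1), 2, 70))
  bres <- secure_infer_batch(pats, model, ses)
  for (i in c(1L, 4L)) {
    sres <- secure_infer(pats[[i]], model, ses)
    expect_lt(abs(bres[[i]]$a - sres$a), EPS_MODEL)
    expect_lt(abs(bres[[i]]$b - sres$b), EPS_MODEL)
  }
  # degenerate batch of one equals the single path
  b1 <- secure_infer_batch(pats[1], model, ses)
  s1 <- secure_infer(pats[[1]], model, ses)
  expect_lt(abs(b1[[1]]$a - s1$a), EPS_MODEL)
  expect_error(secure_infer_batch(list(pats[[1]], matrix(0, 3, 70)), model, ses),
               class = "hegru_batch_error")
  expect_error(secure_infer_batch(rep(pats[1], 33), model, ses),
               class = "hegru_capacity_error")
})

test_that("no depth exhaustion surfaces for long sequences; transcript grows
           linearly and every round moves bytes in both directions", {
  params <- he_params()
  ses <- secure_session(params, crypto_seed = 66L)
  model <- rand_gru_model(37, sd = 0.3)
  set.seed(38)
  x <- matrix(runif(50 * 70, -1, 1), 50, 70)
  t0 <- transcript_total(ses$transcript)
  res <- expect_no_error(secure_infer(x, model, ses))
  expect_identical(res$cells, 100L)
  df <- transcript_df(ses$transcript)
  for (rd in c("adjust-step1", "adjust-step2", "refresh", "2pc-compare")) {
    expect_gt(sum(df$bytes[startsWith(df$round, rd)]), 0)
  }
  # linear growth in N for the single-query path: per-visit byte cost stable
  ses2 <- secure_session(params, crypto_seed = 66L)
  secure_infer(x[1:10, , drop = FALSE], model, ses2)
  b10 <- transcript_total(ses2$transcript)
  ses3 <- secure_session(params, crypto_seed = 66L)
  secure_infer(x[1:20, , drop = FALSE], model, ses3)
  b20 <- transcript_total(ses3$transcript)
  expect_equal((b20 - b10) / b10, 1, tolerance = 0.15)
})
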