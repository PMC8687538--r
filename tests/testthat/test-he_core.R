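# HE simulator: roundtrip accuracy, homomorphism against plaintext oracles,
# level accounting, rotation semantics, key discipline, serialization.

test_that("parameter validation rejects bad slot counts and noise", {
  expect_error(he_params(slot_count = 4095L), class = "hegru_param_error")
  expect_error(he_params(max_level = 0L), class = "hegru_param_error")
  expect_error(he_params(encode_noise_std = -1), class = "hegru_param_error")
  expect_s3_class(he_params(), "he_params")
})

test_that("keygen is deterministic per seed and params", {
  p <- tiny_params()
  k1 <- he_keygen(p, 42L)
  k2 <- he_keygen(p, 42L)
  expect_identical(k1, k2)
  expect_false(identical(k1$key_id, he_keygen(p, 43L)$key_id))
  expect_false(identical(k1$key_id,
                         he_keygen(tiny_params(slot_count = 512L), 42L)$key_id))
})

test_that("encrypt/decrypt roundtrips within eps_enc, zero-pads, checks bounds", {
  p <- tiny_params()
  keys <- he_keygen(p, 1L)
  eps <- hegru:::he_eps_enc(p)
  zero <- he_decrypt(he_encrypt(numeric(16L), keys), keys)
  expect_lt(max(abs(zero)), eps)
  set.seed(10)
  worst <- 0
  for (i in 1:1000) {
    v <- runif(p$slot_count, -50, 50)
    worst <- max(worst, max(abs(he_decrypt(he_encrypt(v, keys), keys) - v)))
  }
  expect_lte(worst, eps)
  ct <- he_encrypt(c(1, 2, 3), keys)
  expect_equal(ct$level, p$max_level)
  expect_lt(max(abs(he_decrypt(ct, keys)[4:p$slot_count])), eps)
  expect_error(he_encrypt(numeric(p$slot_count + 1L), keys),
               class = "hegru_shape_error")
})

test_that("decryption requires the matching secret key", {
  p <- tiny_params()
  keys <- he_keygen(p, 1L)
  ct <- he_encrypt(1:4, keys)
  expect_error(he_decrypt(ct, he_public(keys)), class = "hegru_key_error")
  expect_error(he_decrypt(ct, he_keygen(p, 2L)), class = "hegru_key_error")
  # the public part still encrypts
  expect_silent(he_encrypt(1:4, he_public(keys)))
})

test_that("add/mul agree with plaintext oracles and account levels", {
  p <- tiny_params()
  keys <- he_keygen(p, 2L)
  eps <- hegru:::he_eps_enc(p)
  set.seed(11)
  u <- runif(p$slot_count, -5, 5)
  v <- runif(p$slot_count, -5, 5)
  eu <- he_encrypt(u, keys); ev <- he_encrypt(v, keys)
  expect_lt(max(abs(he_decrypt(he_add(eu, ev), keys) - (u + v))), 3 * eps)
  expect_lt(max(abs(he_decrypt(he_add(eu, numeric(4L)), keys) - u)), eps)
  expect_lt(max(abs(he_decrypt(he_sub(eu, ev), keys) - (u - v))), 3 * eps)
  m <- he_mul(eu, ev)
  expect_lt(max(abs(he_decrypt(m, keys) - u * v)), 20 * eps)
  expect_equal(m$level, p$max_level - 1L)
  mp <- he_mul(eu, rep(1, p$slot_count))
  expect_equal(mp$level, p$max_level - 1L)
  expect_lt(max(abs(he_decrypt(mp, keys) - u)), eps)
  other <- he_keygen(tiny_params(slot_count = 512L), 2L)
  expect_error(he_add(eu, he_encrypt(1, other)), class = "hegru_shape_error")
})

test_that("chained multiplications exhaust the level budget exactly", {
  p <- tiny_params(max_level = 3L)
  keys <- he_keygen(p, 3L)
  ct <- he_encrypt(rep(1, 8L), keys)
  for (i in 1:3) ct <- he_mul(ct, rep(1, p$slot_count))
  expect_equal(ct$level, 0L)
  expect_error(he_mul(ct, rep(1, p$slot_count)), class = "hegru_depth_error")
})

test_that("rotation is a cyclic left shift and level-free", {
  p <- tiny_params()
  keys <- he_keygen(p, 4L)
  v <- c(1, 2, 3, numeric(p$slot_count - 3L))
  ct <- he_encrypt(v, keys)
  eps <- hegru:::he_eps_enc(p)
  r1 <- he_decrypt(he_rotate(ct, 1L), keys)
  expect_lt(abs(r1[1] - 2), eps)
  expect_lt(abs(r1[p$slot_count] - 1), eps)
  expect_identical(he_rotate(ct, 0L)$payload$slots, ct$payload$slots)
  expect_identical(he_rotate(ct, p$slot_count)$payload$slots, ct$payload$slots)
  expect_equal(he_rotate(ct, 5L)$level, ct$level)
  # homomorphism over random expression trees: ops commute with decrypt
  set.seed(12)
  for (trial in 1:20) {
    u <- runif(p$slot_count, -2, 2); w <- runif(p$slot_count, -2, 2)
    ct1 <- he_encrypt(u, keys); ct2 <- he_encrypt(w, keys)
    got <- he_decrypt(he_rotate(he_mul(he_add(ct1, ct2), ct1), 7L), keys)
    ref <- ((u + w) * u)[c(8:p$slot_count, 1:7)]
    expect_lt(max(abs(got - ref)), 50 * eps)
  }
})

test_that("ciphertext and key files roundtrip and refuse mismatched params", {
  p <- tiny_params()
  keys <- he_keygen(p, 5L)
  ct <- he_encrypt(c(3, 1, 4), keys)
  f <- withr::local_tempfile()
  he_save_ct(ct, f)
  back <- he_load_ct(f, p)
  expect_identical(back$payload$slots, ct$payload$slots)
  expect_identical(back$level, ct$level)
  expect_error(he_load_ct(f, tiny_params(slot_count = 512L)),
               class = "hegru_io_error")
  fk <- withr::local_tempfile()
  he_save_keys(keys, fk)
  kb <- he_load_keys(fk, p)
  expect_identical(kb$secret_key, keys$secret_key)
  expect_lt(max(abs(he_decrypt(ct, kb) - he_decrypt(ct, keys))), 1e-12)
  expect_error(he_load_keys(fk, tiny_params(slot_count = 512L)),
               class = "hegru_io_error")
})
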