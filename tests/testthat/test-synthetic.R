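# Synthetic cohort, weight and outcome generators: schema, encoding
# invariants, determinism, calibration targets, survival-signal strength.

test_that("cohort schema: 70 columns, one-hot blocks, bins, z-scores", {
  cfg <- cohort_config(n_patients = 300L, seed = 51L)
  coh <- gen_cohort(cfg)
  expect_length(coh, 300L)
  expect_true(all(vapply(coh, function(p) ncol(p$features), integer(1L)) == 70L))
  expect_true(all(vapply(coh, function(p) nrow(p$features) >= 1L, logical(1L))))
  X <- do.call(rbind, lapply(coh, function(p) p$features))
  off <- 0L
  for (bs in cfg$onehot_blocks) {
    expect_true(all(rowSums(X[, off + seq_len(bs), drop = FALSE]) == 1))
    off <- off + bs
  }
  cont <- off + seq_len(cfg$n_continuous)
  expect_lt(max(abs(colMeans(X[, cont]))), 0.05)
  expect_lt(max(abs(apply(X[, cont], 2L, sd) - 1)), 0.05)
  expect_true(all(X[, 70L] %in% seq(0.05, 0.95, by = 0.1)))
  expect_true(all(is.finite(X)))
  # visits stay inside the window, chronologically ordered
  for (p in coh[1:20]) {
    expect_true(all(p$months >= 0 & p$months < cfg$visit_window_months))
    expect_true(!is.unsorted(p$months))
  }
})

test_that("generation is deterministic per seed and schema errors are caught", {
  a <- gen_cohort(cohort_config(n_patients = 20L, seed = 5L))
  b <- gen_cohort(cohort_config(n_patients = 20L, seed = 5L))
  expect_identical(a, b)
  c <- gen_cohort(cohort_config(n_patients = 20L, seed = 6L))
  expect_false(identical(a, c))
  expect_error(cohort_config(n_continuous = 28L), class = "hegru_config_error")
})

test_that("missingness is imputed (finite features) at high missing rates", {
  coh <- gen_cohort(cohort_config(n_patients = 50L, missing_rate = 0.6,
                                  seed = 52L))
  X <- do.call(rbind, lapply(coh, function(p) p$features))
  expect_true(all(is.finite(X)))
})

test_that("gen_weights: shapes, zero scale, and in-range calibration", {
  m0 <- gen_weights(preact_scale = 0, seed = 53L)
  expect_true(all(m0$layer1$W_z == 0))
  m <- gen_weights(outlier_frac = 0.05, seed = 53L)
  expect_identical(dim(m$layer1$W_z), c(32L, 70L))
  expect_identical(dim(m$layer2$W_z), c(20L, 32L))
  expect_identical(dim(m$dense$W), c(2L, 20L))
  cfg <- adjust_config()
  ref <- gen_cohort(cohort_config(n_patients = 500L, seed = 54L))
  fr <- vapply(ref, function(p) {
    pa <- model_forward(p$features, m, mode = "exact")$preacts
    v <- unlist(lapply(pa, function(g) {
      c(abs(g$z) <= cfg$R - 1, abs(g$r) <= cfg$R - 1,
        abs(g$g) <= cfg$R_tanh - 1)
    }))
    c(sum(v), length(v))
  }, numeric(2L))
  frac <- sum(fr[1L, ]) / sum(fr[2L, ])
  expect_lt(abs(frac - 0.95), 0.05)
  expect_identical(gen_weights(outlier_frac = 0.05, seed = 53L,
                               ref_cohort = ref)$layer1$W_z[1:3],
                   gen_weights(outlier_frac = 0.05, seed = 53L,
                               ref_cohort = ref)$layer1$W_z[1:3])
})

test_that("outcomes: null effect gives chance concordance, strong effect
           strong concordance, censoring calibrated", {
  coh <- gen_cohort(cohort_config(n_patients = 2000L, seed = 55L))
  null_out <- gen_outcomes(coh, effect_size = 0, censor_frac = 0, seed = 56L)
  tm <- vapply(null_out, function(p) p$survival$time, numeric(1L))
  ev <- vapply(null_out, function(p) p$survival$event, integer(1L))
  cnull <- concordance_index(tm, ev, attr(null_out, "risk_score"))
  expect_gt(cnull, 0.47); expect_lt(cnull, 0.53)
  strong <- gen_outcomes(coh, effect_size = 2, censor_frac = 0.3, seed = 56L)
  tm2 <- vapply(strong, function(p) p$survival$time, numeric(1L))
  ev2 <- vapply(strong, function(p) p$survival$event, integer(1L))
  expect_gte(concordance_index(tm2, ev2, attr(strong, "risk_score")), 0.8)
  expect_lt(abs(mean(1 - ev2) - 0.3), 0.05)
  expect_error(gen_outcomes(coh, censor_frac = 0.95),
               class = "hegru_config_error")
})

test_that("generated cohorts flow through both inference paths unchanged", {
  coh <- gen_cohort(cohort_config(n_patients = 2L, seed = 57L))
  model <- rand_gru_model(58, sd = 0.3)
  plain <- model_forward(coh[[1L]], model, mode = "clamped")
  ses <- secure_session(he_params(), crypto_seed = 59L)
  sec <- secure_infer(coh[[1L]], model, ses)
  expect_lt(abs(sec$a - plain$a), EPS_MODEL)
})

test_that("records and survival CSV files roundtrip", {
  coh <- gen_outcomes(gen_cohort(cohort_config(n_patients = 5L, seed = 60L)),
                      seed = 61L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(coh, f)
  back <- read_records_csv(f)
  expect_length(back, 5L)
  p1 <- back[[coh[[1L]]$patient_id]]
  expect_equal(unname(p1$features), unname(coh[[1L]]$features),
               tolerance = 1e-9)
  fs <- withr::local_tempfile(fileext = ".csv")
  write_survival_csv(coh, fs)
  surv <- read.csv(fs)
  expect_identical(nrow(surv), 5L)
  expect_true(all(surv$time > 0))
})
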