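# Shared fixture builders: small HE parameter sets for module tests (the
# protocol-shaped defaults are exercised in the acceptance tests) and compact
# random GRU models.

tiny_params <- function(slot_count = 256L, max_level = 8L,
                        encode_noise_std = 1e-7) {
  he_params(slot_count = slot_count, max_level = max_level,
            encode_noise_std = encode_noise_std)
}

rand_gru_layer <- function(n_h, n_i, sd = 0.4, bias_sd = 0.2) {
  gru_cell_weights(
    W_z = matrix(rnorm(n_h * n_i, 0, sd), n_h, n_i),
    U_z = matrix(rnorm(n_h * n_h, 0, sd), n_h, n_h),
    b_z = rnorm(n_h, 0, bias_sd),
    W_r = matrix(rnorm(n_h * n_i, 0, sd), n_h, n_i),
    U_r = matrix(rnorm(n_h * n_h, 0, sd), n_h, n_h),
    b_r = rnorm(n_h, 0, bias_sd),
    W_g = matrix(rnorm(n_h * n_i, 0, sd), n_h, n_i),
    U_g = matrix(rnorm(n_h * n_h, 0, sd), n_h, n_h),
    b_g_vec = rnorm(n_h, 0, bias_sd))
}

rand_gru_model <- function(seed, sd = 0.3, dims = c(70L, 32L, 20L)) {
  set.seed(seed)
  gru_model_weights(
    rand_gru_layer(dims[2L], dims[1L], sd),
    rand_gru_layer(dims[3L], dims[2L], sd),
    matrix(rnorm(2L * dims[3L], 0, sd), 2L, dims[3L]),
    rnorm(2L, 0, 0.2))
}

zero_gru_model <- function(dims = c(70L, 32L, 20L)) {
  zl <- function(n_h, n_i) {
    gru_cell_weights(matrix(0, n_h, n_i), matrix(0, n_h, n_h), numeric(n_h),
                     matrix(0, n_h, n_i), matrix(0, n_h, n_h), numeric(n_h),
                     matrix(0, n_h, n_i), matrix(0, n_h, n_h), numeric(n_h))
  }
  gru_model_weights(zl(dims[2L], dims[1L]), zl(dims[3L], dims[2L]),
                    matrix(0, 2L, dims[3L]), c(0, 0))
}

# enumerate every (m_s, m_c, b_g, b_l) whose reconstructed message keeps the
# comparator's intermediate sums representable in k bits
compare_enumeration <- function(k, R) {
  vals <- seq(-2^(k - 1), 2^(k - 1) - 1)
  grid <- expand.grid(m_s = vals, m_c = vals)
  m <- hegru:::wrap_signed(grid$m_s + grid$m_c, k)
  keep <- abs(m) <= 2^(k - 1) - R - 1
  list(m_s = grid$m_s[keep], m_c = grid$m_c[keep], m = m[keep])
}

# pinned approximation-quality constants (measured once with the dense-grid
# oracle, then frozen; the tests re-verify they never regress)
EPS_CHEB <- 5.5e-4   # degree-24 sigmoid interpolant on [-10, 10]
EPS_CELL <- 1e-4     # secure cell vs plaintext clamped-reference cell
EPS_MODEL <- 1e-4    # end-to-end dense outputs vs clamped-reference model
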