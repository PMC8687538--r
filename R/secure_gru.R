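# The secure GRU cell workflow and full-model two-party inference:
#   Linear 1 (HE):        z_in = W_z x + U_z h + b_z,  r_in likewise
#   Input adjustment:     secure clamp of z_in, r_in at R
#   Non-linear 1 (HE):    z = sigma(z_in), r = sigma(r_in)  (Chebyshev)
#   Linear 2 (HE):        h (.) r, then g_in = W_g x + U_g (h (.) r) + b_g
#   Input adjustment:     secure clamp of g_in at R_tanh
#   Non-linear 2 (HE):    g = tanh(g_in) = 2 sigma(2 g_in) - 1
#   Linear 3 (HE):        h_t = g + z (.) (h - g)
# A level accountant inserts interactive masked refreshes wherever the
# remaining depth is short of the next stage's requirement.

#' Interactive masked ciphertext refresh
#'
#' Restores a ciphertext to the full level budget without native
#' bootstrapping: the server adds a random mask (hiding the intermediate
#' result), the client decrypts and re-encrypts fresh, and the server removes
#' the mask. The message is preserved up to encoding noise; works at any
#' level, including 0.
#'
#' @param ct An `he_ct` ciphertext.
#' @param session A [secure_session()].
#' @return An `he_ct` with `level = max_level` and the same message.
#' @export
masked_refresh <- function(ct, session) {
  stopifnot(inherits(ct, "he_ct"), inherits(session, "secure_session"))
  mask <- crypto_reals(session, ct$n_slots, -2^20, 2^20)
  ct_masked <- he_add(ct, mask)
  transcript_log(session$transcript, "refresh", "s2c",
                 ct_bytes(session$params), "ciphertext")
  v <- session_decrypt(session, ct_masked)
  ct_fresh <- he_encrypt(v, session$client$keys)
  transcript_log(session$transcript, "refresh", "c2s",
                 ct_bytes(session$params), "ciphertext")
  session$counters$refreshes <- session$counters$refreshes + 1L
  he_sub(ct_fresh, mask)
}

# level accountant: refresh iff remaining depth is short of `need`
ensure_level <- function(ct, need, session) {
  if (ct$level < need) masked_refresh(ct, session) else ct
}

model_fingerprint <- function(model) {
  sums <- vapply(c(model$layer1[1:6], model$layer2[1:6], list(model$dense$W)),
                 function(m) sum(m) + sum(dim(m) * c(1e3, 1)), numeric(1L))
  cpp_hash_str(paste(sprintf("%.10e", sums), collapse = "|"))
}

# replicate a bias vector across the active blocks of a layout
bias_slots <- function(b, layout, n_blocks) {
  v <- numeric(layout$slot_count)
  for (j in seq_len(n_blocks)) v[(j - 1L) * layout$pad_len + seq_along(b)] <- b
  v
}

# server-side preparation: packed diagonals for every weight matrix, cached in
# the session by model fingerprint and layout mode
prep_server_model <- function(session, model, layout, n_blocks) {
  key <- sprintf("%s_%s_%d", model_fingerprint(model), layout$mode, n_blocks)
  cache <- session$server$matrix_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  prep_layer <- function(layer) {
    list(W_z = prep_weight_matrix(layer$W_z, layout),
         U_z = prep_weight_matrix(layer$U_z, layout),
         W_r = prep_weight_matrix(layer$W_r, layout),
         U_r = prep_weight_matrix(layer$U_r, layout),
         W_g = prep_weight_matrix(layer$W_g, layout),
         U_g = prep_weight_matrix(layer$U_g, layout),
         b_z = bias_slots(layer$b_z, layout, n_blocks),
         b_r = bias_slots(layer$b_r, layout, n_blocks),
         b_g = bias_slots(layer$b_g_vec, layout, n_blocks),
         n_h = nrow(layer$W_z))
  }
  sm <- list(layer1 = prep_layer(model$layer1),
             layer2 = prep_layer(model$layer2),
             dense = prep_weight_matrix(model$dense$W, layout),
             dense_b = bias_slots(model$dense$b, layout, n_blocks),
             layout = layout, n_blocks = n_blocks)
  cache[[key]] <- sm
  sm
}

# active slot indices: leading n entries of each used block
active_slots <- function(layout, n, n_blocks) {
  as.integer(outer(seq_len(n), (seq_len(n_blocks) - 1L) * layout$pad_len, `+`))
}

#' Evaluate one secure GRU cell
#'
#' Runs the full seven-stage workflow (three homomorphic linear stages, two
#' secure input adjustments, two Chebyshev activations) on encrypted input and
#' state, inserting masked refreshes as the level accountant requires. The
#' decrypted result matches the plaintext clamped-reference cell
#' ([gru_cell_plain()] with `mode = "clamped"`) up to encoding noise.
#'
#' @param ct_x Encrypted (packed) input vector(s) for this time step.
#' @param ct_h Encrypted (packed) previous state.
#' @param layer A prepared layer from the server model (packed matrices plus
#'   bias slot vectors).
#' @param session A [secure_session()].
#' @param layout The active `packed_layout`.
#' @param n_blocks Number of occupied sample blocks.
#' @return An `he_ct` holding the new state `h_t`.
#' @export
secure_gru_cell <- function(ct_x, ct_h, layer, session, layout, n_blocks = 1L) {
  cfg <- session$cfg
  slots <- active_slots(layout, layer$n_h, n_blocks)
  ct_x <- ensure_level(ct_x, 1L, session)
  ct_h <- ensure_level(ct_h, 1L, session)
  # Linear 1
  z_in <- he_add(he_add(packed_product(layer$W_z, ct_x),
                        packed_product(layer$U_z, ct_h)), layer$b_z)
  r_in <- he_add(he_add(packed_product(layer$W_r, ct_x),
                        packed_product(layer$U_r, ct_h)), layer$b_r)
  # Input adjustment + Non-linear 1
  act_depth <- cheb_he_depth(session$cheb$degree)
  z_in <- ensure_level(z_in, 1L, session)
  z_adj <- secure_clamp(z_in, slots, session, R = cfg$R)
  z_adj <- ensure_level(z_adj, act_depth, session)
  z <- cheb_eval_he(session$cheb, z_adj)
  r_in <- ensure_level(r_in, 1L, session)
  r_adj <- secure_clamp(r_in, slots, session, R = cfg$R)
  r_adj <- ensure_level(r_adj, act_depth, session)
  r <- cheb_eval_he(session$cheb, r_adj)
  # Linear 2
  ct_h <- ensure_level(ct_h, 1L, session)
  r <- ensure_level(r, 1L, session)
  hr <- he_mul(ct_h, r)
  hr <- ensure_level(hr, 1L, session)
  g_in <- he_add(he_add(packed_product(layer$W_g, ct_x),
                        packed_product(layer$U_g, hr)), layer$b_g)
  # Input adjustment + Non-linear 2 (tanh via the sigmoid interpolant)
  g_in <- ensure_level(g_in, 1L, session)
  g_adj <- secure_clamp(g_in, slots, session, R = cfg$R_tanh)
  g_adj <- ensure_level(g_adj, act_depth, session)
  g <- cheb_tanh_he(session$cheb, g_adj)
  # Linear 3: h_t = g + z (.) (h - g)
  z <- ensure_level(z, 1L, session)
  g <- ensure_level(g, 1L, session)
  diff <- he_sub(ct_h, g)
  diff <- ensure_level(diff, 1L, session)
  h_t <- he_add(g, he_mul(z, diff))
  session$counters$cells <- session$counters$cells + 1L
  h_t
}

validate_records <- function(records, n_in) {
  if (inherits(records, "patient_record")) records <- records$features
  if (!is.matrix(records)) records <- matrix(records, nrow = 1L)
  if (nrow(records) < 1L) {
    he_error("hegru_input_error", "at least one visit record is required")
  }
  if (ncol(records) != n_in) {
    he_error("hegru_shape_error",
             sprintf("feature vectors have length %d, model expects %d",
                     ncol(records), n_in))
  }
  records
}

#' Privacy-preserving inference for one patient (single query)
#'
#' The client encrypts each visit vector into its own ciphertext; the server
#' evaluates the two GRU layers (2N secure cell evaluations for N visits; the
#' second layer emits only its last state) and the final dense product, then
#' returns that ciphertext. The client decrypts the two dense outputs `(a, b)`
#' and applies the Weibull activation in plain — the dense output and the
#' Weibull parameters carry the same information, so stopping the encrypted
#' computation at the matrix product leaks nothing extra.
#'
#' @param records Visit matrix (`N` x `n_in`) or a `patient_record`.
#' @param model A `gru_model_weights` object (server side).
#' @param session A [secure_session()].
#' @return List with `a`, `b`, the Weibull parameters `alpha`, `beta`, and
#'   the `cells` (= 2N) and `refreshes` counters for this call.
#' @export
secure_infer <- function(records, model, session) {
  stopifnot(inherits(model, "gru_model_weights"),
            inherits(session, "secure_session"))
  n_in <- ncol(model$layer1$W_z)
  x <- validate_records(records, n_in)
  n_visits <- nrow(x)
  layout <- packed_layout(session$params$slot_count,
                          2^ceiling(log2(n_in)), "single")
  run_secure_model(lapply(seq_len(n_visits), function(t) list(x[t, ])),
                   model, session, layout, n_blocks = 1L)[[1L]]
}

#' Privacy-preserving inference for a batch of patients
#'
#' Packs up to `block_count` (32 with the default parameters) patients with an
#' equal number of visits into shared ciphertexts, so each homomorphic linear
#' stage and activation serves the whole batch at the cost of one; the
#' garbled-circuit comparisons still grow with the batch size. Per-patient
#' outputs match the corresponding single-query results.
#'
#' @param cohort List of visit matrices (or `patient_record`s), all with the
#'   same number of visits.
#' @param model A `gru_model_weights` object.
#' @param session A [secure_session()].
#' @return List of per-patient results as in [secure_infer()].
#' @export
secure_infer_batch <- function(cohort, model, session) {
  stopifnot(inherits(model, "gru_model_weights"),
            inherits(session, "secure_session"))
  n_in <- ncol(model$layer1$W_z)
  mats <- lapply(cohort, validate_records, n_in = n_in)
  ns <- vapply(mats, nrow, integer(1L))
  if (length(unique(ns)) != 1L) {
    he_error("hegru_batch_error",
             "all patients in a batch must have the same number of visits")
  }
  layout <- packed_layout(session$params$slot_count,
                          2^ceiling(log2(n_in)), "batch")
  if (length(mats) > layout$block_count) {
    he_error("hegru_capacity_error",
             sprintf("batch of %d exceeds the capacity of %d patients",
                     length(mats), layout$block_count))
  }
  steps <- lapply(seq_len(ns[1L]), function(t) lapply(mats, function(m) m[t, ]))
  run_secure_model(steps, model, session, layout, n_blocks = length(mats))
}

# shared engine: steps[[t]] is the list of per-patient feature vectors at t
run_secure_model <- function(steps, model, session, layout, n_blocks) {
  cells0 <- session$counters$cells
  refr0 <- session$counters$refreshes
  sm <- prep_server_model(session, model, layout, n_blocks)
  n_visits <- length(steps)
  # client encrypts each record vector into a separate (packed) ciphertext
  ct_x <- lapply(steps, function(s) {
    ct <- pack_batch(s, layout, session$client$keys)
    transcript_log(session$transcript, "query", "c2s",
                   ct_bytes(session$params), "ciphertext")
    ct
  })
  # initial states are fresh encryptions of the zero vector by the server
  zero_ct <- function() he_encrypt(numeric(session$params$slot_count),
                                   session$server$keys)
  h1 <- zero_ct()
  h1_seq <- vector("list", n_visits)
  for (t in seq_len(n_visits)) {
    h1 <- secure_gru_cell(ct_x[[t]], h1, sm$layer1, session, layout, n_blocks)
    h1_seq[[t]] <- h1
  }
  h2 <- zero_ct()
  for (t in seq_len(n_visits)) {
    h2 <- secure_gru_cell(h1_seq[[t]], h2, sm$layer2, session, layout, n_blocks)
  }
  h2 <- ensure_level(h2, 1L, session)
  out_ct <- he_add(packed_product(sm$dense, h2), sm$dense_b)
  transcript_log(session$transcript, "result", "s2c",
                 ct_bytes(session$params), "ciphertext")
  slots <- session_decrypt(session, out_ct)
  cells <- session$counters$cells - cells0
  refreshes <- session$counters$refreshes - refr0
  ab <- unpack_batch(slots, layout, len = 2L, n_samples = n_blocks)
  lapply(ab, function(v) {
    wp <- weibull_activate(v[1L], v[2L])
    list(a = v[1L], b = v[2L], alpha = wp$alpha, beta = wp$beta,
         cells = cells, refreshes = refreshes)
  })
}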