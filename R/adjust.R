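# The secure input-adjustment protocol: convert an HE ciphertext into blinded
# additive shares, run the garbled-circuit comparison, and homomorphically
# recover the clamped message
#   m' = (1 - c_g - c_l) * m + R * (c_g - c_l),
# where c_g = (m > R) and c_l = (m < -R). Shares are rounded to integers
# (masks r are drawn as integers, so only the client-side rounding contributes
# error, at most 1/2), which makes the comparison act on round(m): values with
# |m| <= R - 1 always pass through, |m| >= R + 1 are always clamped, and the
# boundary band yields one of {m, sign(m) * R}.

#' Input-adjustment configuration
#'
#' Protocol parameters for the secure clamp. The defaults follow the
#' activation ranges: with the sigmoid interpolant on `[-10, 10]` and the rule
#' that the target function is approximated on `[-R - 1, R + 1]`, the sigmoid
#' gates use `R = 9`; the candidate gate evaluates tanh via
#' `tanh(x) = 2 sigma(2x) - 1`, so its threshold satisfies
#' `2 (R_tanh + 1) <= 10`, i.e. `R_tanh = 4`.
#'
#' @param R Clamp threshold for sigmoid-gate pre-activations.
#' @param R_tanh Clamp threshold for the candidate (tanh) gate.
#' @param k Comparator bit width (two's complement).
#' @param mask_bound Masks are drawn uniformly from `[-mask_bound,
#'   mask_bound]`; must leave `2^stat_sec` hiding margin over `message_bound`
#'   while `message_bound + mask_bound` stays below `2^(k-1)`.
#' @param message_bound Asserted ceiling on `|m|` for adjusted slots.
#' @param stat_sec Statistical hiding margin in bits.
#' @return An `adjust_config` object.
#' @export
adjust_config <- function(R = 9L, R_tanh = 4L, k = 32L, mask_bound = 2^30,
                          message_bound = 512, stat_sec = 20L) {
  if (R < 1 || R_tanh < 1) {
    he_error("hegru_param_error", "clamp thresholds must be positive")
  }
  if (message_bound + mask_bound >= 2^(k - 1)) {
    he_error("hegru_param_error",
             "message_bound + mask_bound must stay below 2^(k-1) (overflow)")
  }
  if (mask_bound < 2^stat_sec * message_bound) {
    he_error("hegru_param_error",
             "mask_bound leaves less than 2^stat_sec hiding margin")
  }
  structure(list(R = R, R_tanh = R_tanh, k = as.integer(k),
                 mask_bound = mask_bound, message_bound = message_bound,
                 stat_sec = as.integer(stat_sec)),
            class = "adjust_config")
}

#' Convert ciphertext slots to blinded additive shares
#'
#' Step 1 of the adjustment protocol: the server samples one integer mask `r`
#' per selected slot, homomorphically adds it and sends the masked ciphertext
#' to the client, who decrypts and rounds. The shares satisfy
#' `m_s + m_c = round(m)` per slot (`|share sum - m| <= 1/2`); the decrypted
#' masked values never leave the client. The server also samples the blind
#' bits `b_g`, `b_l` used by the comparison step.
#'
#' @param ct_m An `he_ct` holding the messages.
#' @param slots 1-based slot indices to adjust.
#' @param session A [secure_session()].
#' @return A `share_state`: server-side `m_s`, `b_g`, `b_l`; client-side
#'   `m_c`; plus the slot set.
#' @export
ct_to_shares <- function(ct_m, slots, session) {
  stopifnot(inherits(ct_m, "he_ct"), inherits(session, "secure_session"))
  if (any(slots < 1L) || any(slots > ct_m$n_slots)) {
    he_error("hegru_shape_error", "slot index out of range")
  }
  cfg <- session$cfg
  r <- crypto_integers(session, length(slots), -cfg$mask_bound, cfg$mask_bound)
  mask <- numeric(ct_m$n_slots)
  mask[slots] <- r
  ct_masked <- he_add(ct_m, mask)
  transcript_log(session$transcript, "adjust-step1", "s2c",
                 ct_bytes(session$params), "ciphertext")
  v <- session_decrypt(session, ct_masked)
  m_c <- round(v[slots])
  structure(
    list(slots = slots,
         server = list(m_s = -r,
                       b_g = crypto_bits(session, length(slots)),
                       b_l = crypto_bits(session, length(slots))),
         client = list(m_c = m_c)),
    class = "share_state"
  )
}

#' Homomorphic recovery of the clamped message
#'
#' Step 3 of the adjustment protocol, run by the server. The client's
#' encrypted blinded bits are unblinded homomorphically (`c = h` when `b = 0`,
#' `c = 1 - h` when `b = 1`; the blind is the server's own plaintext secret),
#' then the recovery polynomial
#' `m' = (1 - c_g - c_l) m + R (c_g - c_l)` is evaluated. Consumes at most two
#' levels from `ct_m`.
#'
#' @param ct_m The original message ciphertext.
#' @param ct_hg,ct_hl Client-encrypted blinded comparison bits (full slot
#'   vectors, zero outside the adjusted slots).
#' @param blinds List with plaintext 0/1 vectors `b_g`, `b_l` over all slots
#'   (zero outside the adjusted slots).
#' @param R Clamp threshold.
#' @return An `he_ct` of the adjusted message `m'`.
#' @export
recover_clamped <- function(ct_m, ct_hg, ct_hl, blinds, R) {
  stopifnot(inherits(ct_m, "he_ct"))
  n <- ct_m$n_slots
  b_g <- as_plain_slots(blinds$b_g, n)
  b_l <- as_plain_slots(blinds$b_l, n)
  # unblinding c = b + (1 - 2b) h folded into the recovery polynomial:
  #   1 - c_g - c_l = (1 - b_g - b_l) - (1-2b_g) h_g - (1-2b_l) h_l
  #   R (c_g - c_l) = R (b_g - b_l) + R (1-2b_g) h_g - R (1-2b_l) h_l
  # so each h ciphertext is touched by plaintext products only and ct_m
  # spends a single level on the product with (1 - c_g - c_l).
  t <- he_add(he_add(he_mul(ct_hg, -(1 - 2 * b_g)),
                     he_mul(ct_hl, -(1 - 2 * b_l))),
              1 - b_g - b_l)
  keep <- he_mul(t, ct_m)
  shift <- he_add(he_add(he_mul(ct_hg, R * (1 - 2 * b_g)),
                         he_mul(ct_hl, -R * (1 - 2 * b_l))),
                  R * (b_g - b_l))
  he_add(keep, shift)
}

#' Secure clamp of ciphertext slots (full protocol)
#'
#' Runs the three-step adjustment end to end: share conversion, the blinded
#' garbled-circuit comparison, client encryption of the blinded bits, and
#' homomorphic recovery. Per selected slot the result satisfies `m' = m` when
#' `|m| <= R - 1`, `m' = sign(m) * R` when `|m| >= R + 1`, and one of
#' `{m, sign(m) * R}` inside the rounding band; unselected slots pass through
#' unchanged. Neither party learns `m` or the comparison outcome in the clear.
#'
#' @param ct_m An `he_ct` holding the messages.
#' @param slots 1-based slot indices to adjust.
#' @param session A [secure_session()].
#' @param R Clamp threshold (defaults to the session's sigmoid threshold).
#' @return An `he_ct` of the adjusted messages.
#' @export
secure_clamp <- function(ct_m, slots, session, R = session$cfg$R) {
  stopifnot(inherits(session, "secure_session"))
  if (ct_m$level < 1L) {
    he_error("hegru_depth_error",
             "secure clamp needs at least one level on the message ciphertext")
  }
  st <- ct_to_shares(ct_m, slots, session)
  h <- run_2pc_compare(st$server, st$client, session$cfg$k, R,
                       seed = crypto_seed_draw(session),
                       transcript = session$transcript)
  n <- ct_m$n_slots
  hg_plain <- numeric(n); hg_plain[slots] <- h$h_g
  hl_plain <- numeric(n); hl_plain[slots] <- h$h_l
  keys_pub <- session$server$keys # client encrypts under the shared public key
  ct_hg <- he_encrypt(hg_plain, keys_pub)
  ct_hl <- he_encrypt(hl_plain, keys_pub)
  transcript_log(session$transcript, "adjust-step2", "c2s",
                 2 * ct_bytes(session$params), "ciphertext")
  b_g <- numeric(n); b_g[slots] <- st$server$b_g
  b_l <- numeric(n); b_l[slots] <- st$server$b_l
  recover_clamped(ct_m, ct_hg, ct_hl, list(b_g = b_g, b_l = b_l), R)
}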