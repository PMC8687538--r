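# SIMD leveled homomorphic-encryption abstraction with an exact-arithmetic
# simulator backend. The simulator holds the slot vector privately inside the
# ciphertext payload, enforces level/scale bookkeeping, and optionally injects
# Gaussian encoding noise; a real-crypto backend can be plugged in behind the
# same interface (every operation dispatches on params$backend).

#' HE parameter set
#'
#' Parameters for the SIMD leveled homomorphic-encryption backend. The defaults
#' follow the protocol's deployment shape: 4096 real slots, a multiplicative
#' depth budget of 8 (enough for one GRU-cell segment between interactive
#' refreshes), and encoding noise tuned so that a fresh encrypt/decrypt
#' roundtrip is accurate to `eps_enc = 5 * encode_noise_std <= 1e-6` per slot.
#'
#' @param slot_count Number of real slots per ciphertext; must be a power of
#'   two.
#' @param max_level Multiplicative depth budget of a fresh ciphertext. Every
#'   multiplication (ciphertext or plaintext operand alike) consumes one level.
#' @param scale Fixed-point encoding scale carried as ciphertext metadata.
#' @param encode_noise_std Standard deviation of simulated per-slot encoding
#'   noise injected at encryption (0 disables noise).
#' @param message_bound Largest absolute slot value the backend guarantees to
#'   encode faithfully.
#' @param backend Backend identifier; `"simulator"` is the mandatory
#'   exact-arithmetic backend.
#' @return An object of class `he_params`.
#' @export
he_params <- function(slot_count = 4096L, max_level = 8L, scale = 2^30,
                      encode_noise_std = 1e-7, message_bound = 2^40,
                      backend = "simulator") {
  slot_count <- as.integer(slot_count)
  max_level <- as.integer(max_level)
  if (length(slot_count) != 1L || is.na(slot_count) || slot_count < 1L ||
      bitwAnd(slot_count, slot_count - 1L) != 0L) {
    he_error("hegru_param_error", "slot_count must be a power of two")
  }
  if (max_level < 1L) he_error("hegru_param_error", "max_level must be >= 1")
  if (encode_noise_std < 0) {
    he_error("hegru_param_error", "encode_noise_std must be non-negative")
  }
  if (scale <= 0 || message_bound <= 0) {
    he_error("hegru_param_error", "scale and message_bound must be positive")
  }
  if (!identical(backend, "simulator")) {
    he_error("hegru_param_error",
             sprintf("unknown HE backend '%s' (only 'simulator' is built in)",
                     backend))
  }
  structure(
    list(slot_count = slot_count, max_level = max_level, scale = scale,
         encode_noise_std = encode_noise_std, message_bound = message_bound,
         backend = backend),
    class = "he_params"
  )
}

#' @export
print.he_params <- function(x, ...) {
  cat(sprintf(
    "<he_params backend=%s slots=%d max_level=%d scale=2^%.1f noise_sd=%g>\n",
    x$backend, x$slot_count, x$max_level, log2(x$scale), x$encode_noise_std))
  invisible(x)
}

# eps_enc: componentwise roundtrip accuracy guaranteed by the parameters
he_eps_enc <- function(params) 5 * params$encode_noise_std

he_params_fingerprint <- function(params) {
  cpp_hash_str(paste(params$backend, params$slot_count, params$max_level,
                     format(params$scale, digits = 17),
                     format(params$encode_noise_std, digits = 17),
                     format(params$message_bound, digits = 17), sep = "|"))
}

he_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "hegru_error")))
}

#' Generate HE key material
#'
#' Deterministic per `(params, seed)` in the simulator backend: the same seed
#' and parameters regenerate identical keys. The returned object carries the
#' secret key; use [he_public()] to derive the share handed to the other party.
#'
#' @param params An [he_params()] object.
#' @param seed Integer key-generation seed.
#' @return An object of class `he_keys` with secret, public and rotation key
#'   material plus the originating parameters.
#' @export
he_keygen <- function(params, seed) {
  stopifnot(inherits(params, "he_params"))
  if (length(seed) != 1L || is.na(seed)) {
    he_error("hegru_param_error", "seed must be a single integer")
  }
  key_id <- cpp_hash_str(paste("hegru-key", format(seed, digits = 17),
                               he_params_fingerprint(params), sep = "|"))
  structure(
    list(params = params,
         key_id = key_id,
         secret_key = cpp_hash_str(paste0("sk|", key_id)),
         public_key = list(key_id = key_id),
         rotation_keys = TRUE,
         seed = seed),
    class = "he_keys"
  )
}

#' Public part of a key set
#'
#' Strips the secret key so the result can encrypt (and rotate) but not
#' decrypt.
#'
#' @param keys An `he_keys` object.
#' @return An `he_keys` object without secret key material.
#' @export
he_public <- function(keys) {
  stopifnot(inherits(keys, "he_keys"))
  keys$secret_key <- NULL
  keys
}

new_he_ct <- function(slots, level, scale, key_id, params) {
  structure(
    list(payload = list(slots = slots, key_id = key_id),
         level = as.integer(level), scale = scale,
         n_slots = length(slots), params = params),
    class = "he_ct"
  )
}

#' @export
print.he_ct <- function(x, ...) {
  cat(sprintf("<he_ct slots=%d level=%d scale=2^%.1f>\n",
              x$n_slots, x$level, log2(x$scale)))
  invisible(x)
}

#' Encrypt a real vector
#'
#' Vectors shorter than the slot count are zero-padded. A fresh ciphertext sits
#' at the full level budget `params$max_level`.
#'
#' @param v Numeric vector of length at most `slot_count`, all entries within
#'   `message_bound`.
#' @param keys Key material from [he_keygen()] (the public part suffices).
#' @return An `he_ct` ciphertext.
#' @export
he_encrypt <- function(v, keys) {
  stopifnot(inherits(keys, "he_keys"))
  p <- keys$params
  if (!is.numeric(v) || length(v) < 1L) {
    he_error("hegru_shape_error", "plaintext must be a non-empty numeric vector")
  }
  if (length(v) > p$slot_count) {
    he_error("hegru_shape_error",
             sprintf("vector of length %d exceeds slot count %d",
                     length(v), p$slot_count))
  }
  if (any(!is.finite(v))) {
    he_error("hegru_param_error", "plaintext entries must be finite")
  }
  if (any(abs(v) > p$message_bound)) {
    he_error("hegru_param_error",
             "plaintext entries exceed the backend's message bound")
  }
  slots <- c(as.numeric(v), numeric(p$slot_count - length(v)))
  if (p$encode_noise_std > 0) {
    slots <- slots + stats::rnorm(p$slot_count, 0, p$encode_noise_std)
  }
  new_he_ct(slots, p$max_level, p$scale, keys$key_id, p)
}

#' Decrypt a ciphertext
#'
#' Requires the full key set holding the secret key; decrypting with a public
#' share or a key from a different generation is an explicit error in the
#' simulator backend.
#'
#' @param ct An `he_ct` ciphertext.
#' @param keys An `he_keys` object with secret key material.
#' @return Numeric vector of length `slot_count`.
#' @export
he_decrypt <- function(ct, keys) {
  stopifnot(inherits(ct, "he_ct"), inherits(keys, "he_keys"))
  if (is.null(keys$secret_key)) {
    he_error("hegru_key_error", "decryption requires the secret key")
  }
  if (!identical(keys$secret_key, cpp_hash_str(paste0("sk|", ct$payload$key_id)))) {
    he_error("hegru_key_error", "ciphertext was not encrypted under this key")
  }
  ct$payload$slots
}

he_check_pair <- function(a, b) {
  if (a$n_slots != b$n_slots) {
    he_error("hegru_shape_error", "ciphertext slot counts differ")
  }
  if (!identical(a$payload$key_id, b$payload$key_id)) {
    he_error("hegru_key_error", "ciphertexts belong to different key sets")
  }
}

as_plain_slots <- function(b, n) {
  if (!is.numeric(b)) {
    he_error("hegru_shape_error", "operand must be a ciphertext or numeric")
  }
  if (length(b) == 1L) return(rep(as.numeric(b), n))
  if (length(b) > n) {
    he_error("hegru_shape_error", "plaintext operand longer than slot count")
  }
  c(as.numeric(b), numeric(n - length(b)))
}

#' Homomorphic addition
#'
#' Componentwise addition of a ciphertext and either another ciphertext or a
#' plaintext vector (zero-padded, scalars recycled). Ciphertext operands at
#' different levels are aligned by mod-switching to the lower level; addition
#' itself consumes no level.
#'
#' @param a An `he_ct` ciphertext.
#' @param b An `he_ct` ciphertext or numeric vector.
#' @return An `he_ct` ciphertext at `min(level(a), level(b))`.
#' @export
he_add <- function(a, b) {
  stopifnot(inherits(a, "he_ct"))
  if (inherits(b, "he_ct")) {
    he_check_pair(a, b)
    new_he_ct(a$payload$slots + b$payload$slots, min(a$level, b$level),
              a$scale, a$payload$key_id, a$params)
  } else {
    new_he_ct(a$payload$slots + as_plain_slots(b, a$n_slots), a$level,
              a$scale, a$payload$key_id, a$params)
  }
}

#' Homomorphic subtraction
#'
#' @inheritParams he_add
#' @return An `he_ct` ciphertext.
#' @export
he_sub <- function(a, b) {
  if (inherits(b, "he_ct")) {
    b$payload$slots <- -b$payload$slots
    he_add(a, b)
  } else {
    he_add(a, -as_plain_slots(b, a$n_slots))
  }
}

#' Homomorphic multiplication
#'
#' Componentwise product with a ciphertext or plaintext operand. Either form
#' consumes exactly one level (this artifact's conservative accounting) and
#' rescales the result to the parameter scale. A ciphertext at level 0 raises a
#' depth-exhausted error, the signal that [masked_refresh()] is required.
#'
#' @inheritParams he_add
#' @return An `he_ct` ciphertext one level below its inputs.
#' @export
he_mul <- function(a, b) {
  stopifnot(inherits(a, "he_ct"))
  if (a$level < 1L) {
    he_error("hegru_depth_error",
             "multiplicative depth exhausted; masked refresh required")
  }
  if (inherits(b, "he_ct")) {
    he_check_pair(a, b)
    if (b$level < 1L) {
      he_error("hegru_depth_error",
               "multiplicative depth exhausted; masked refresh required")
    }
    new_he_ct(a$payload$slots * b$payload$slots, min(a$level, b$level) - 1L,
              a$params$scale, a$payload$key_id, a$params)
  } else {
    new_he_ct(a$payload$slots * as_plain_slots(b, a$n_slots), a$level - 1L,
              a$params$scale, a$payload$key_id, a$params)
  }
}

#' Cyclic slot rotation
#'
#' Left-rotates the slot vector: slot `i` of the result holds slot
#' `(i + k) mod n` of the input (0-based). Rotation keys are required; no level
#' is consumed.
#'
#' @param ct An `he_ct` ciphertext.
#' @param k Integer rotation amount (negative rotates right).
#' @return An `he_ct` ciphertext at the same level.
#' @export
he_rotate <- function(ct, k) {
  stopifnot(inherits(ct, "he_ct"))
  n <- ct$n_slots
  k <- ((as.integer(k) %% n) + n) %% n
  if (k == 0L) return(ct)
  idx <- c((k + 1L):n, 1L:k)
  new_he_ct(ct$payload$slots[idx], ct$level, ct$scale, ct$payload$key_id,
            ct$params)
}

# ---- versioned binary serialization -----------------------------------------

HE_MAGIC <- "HEGRU01"

#' Write a ciphertext to a versioned binary file
#'
#' The header carries magic bytes, the backend id and a parameter fingerprint;
#' [he_load_ct()] refuses to load under mismatching parameters.
#'
#' @param ct An `he_ct` ciphertext.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
he_save_ct <- function(ct, path) {
  stopifnot(inherits(ct, "he_ct"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(HE_MAGIC, con, eos = NULL)
  writeChar(sprintf("%-12s", ct$params$backend), con, eos = NULL)
  writeChar(he_params_fingerprint(ct$params), con, eos = NULL)
  writeChar(ct$payload$key_id, con, eos = NULL)
  writeBin(c(ct$level, ct$n_slots), con, size = 4L)
  writeBin(ct$scale, con, size = 8L)
  writeBin(ct$payload$slots, con, size = 8L)
  invisible(path)
}

#' Load a ciphertext written by [he_save_ct()]
#'
#' @param path File path.
#' @param params The [he_params()] the ciphertext must have been produced
#'   under.
#' @return An `he_ct` ciphertext.
#' @export
he_load_ct <- function(path, params) {
  stopifnot(inherits(params, "he_params"))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(HE_MAGIC))
  if (!identical(magic, HE_MAGIC)) {
    he_error("hegru_io_error", "not a hegru ciphertext file (bad magic bytes)")
  }
  backend <- trimws(readChar(con, 12L))
  fp <- readChar(con, 16L)
  if (!identical(backend, params$backend) ||
      !identical(fp, he_params_fingerprint(params))) {
    he_error("hegru_io_error",
             "ciphertext file was written under different HE parameters")
  }
  key_id <- readChar(con, 16L)
  meta <- readBin(con, integer(), n = 2L, size = 4L)
  scale <- readBin(con, numeric(), n = 1L, size = 8L)
  slots <- readBin(con, numeric(), n = meta[2L], size = 8L)
  new_he_ct(slots, meta[1L], scale, key_id, params)
}

#' Write key material to a versioned binary file
#'
#' @param keys An `he_keys` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
he_save_keys <- function(keys, path) {
  stopifnot(inherits(keys, "he_keys"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(HE_MAGIC, con, eos = NULL)
  writeChar(sprintf("%-12s", keys$params$backend), con, eos = NULL)
  writeChar(he_params_fingerprint(keys$params), con, eos = NULL)
  writeChar(keys$key_id, con, eos = NULL)
  has_sk <- !is.null(keys$secret_key)
  writeBin(as.integer(has_sk), con, size = 4L)
  if (has_sk) writeChar(keys$secret_key, con, eos = NULL)
  writeBin(as.numeric(keys$seed), con, size = 8L)
  invisible(path)
}

#' Load key material written by [he_save_keys()]
#'
#' @param path File path.
#' @param params The [he_params()] the keys were generated under.
#' @return An `he_keys` object.
#' @export
he_load_keys <- function(path, params) {
  stopifnot(inherits(params, "he_params"))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(HE_MAGIC))
  if (!identical(magic, HE_MAGIC)) {
    he_error("hegru_io_error", "not a hegru key file (bad magic bytes)")
  }
  backend <- trimws(readChar(con, 12L))
  fp <- readChar(con, 16L)
  if (!identical(backend, params$backend) ||
      !identical(fp, he_params_fingerprint(params))) {
    he_error("hegru_io_error",
             "key file was written under different HE parameters")
  }
  key_id <- readChar(con, 16L)
  has_sk <- readBin(con, integer(), n = 1L, size = 4L)
  sk <- if (has_sk) readChar(con, 16L) else NULL
  seed <- readBin(con, numeric(), n = 1L, size = 8L)
  structure(
    list(params = params, key_id = key_id, secret_key = sk,
         public_key = list(key_id = key_id), rotation_keys = TRUE,
         seed = seed),
    class = "he_keys"
  )
}
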