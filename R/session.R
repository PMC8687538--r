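# Two-party session plumbing: transcript accounting for every inter-party
# message, an in-process transport (client and server are separate
# environments; the client side holds the secret key, the server side the
# public key and model material), and a dedicated crypto RNG stream so protocol
# randomness is independent of simulation randomness.

#' Create a message transcript
#'
#' Append-only log of inter-party messages with byte counts, round labels and
#' payload kinds; the basis for the protocol's communication accounting.
#'
#' @return A `transcript` object.
#' @export
new_transcript <- function() {
  env <- new.env(parent = emptyenv())
  env$round <- character(0L)
  env$direction <- character(0L)
  env$bytes <- numeric(0L)
  env$kind <- character(0L)
  class(env) <- "transcript"
  env
}

#' Log one message into a transcript
#'
#' @param transcript A [new_transcript()] object.
#' @param round Round label (e.g. `"adjust-step1"`).
#' @param direction `"s2c"`, `"c2s"` or `"both"`.
#' @param bytes Non-negative byte count.
#' @param kind Payload kind (`"ciphertext"`, `"garbled tables"`, `"OT"`,
#'   `"labels"`, `"bits"`).
#' @return The transcript, invisibly.
#' @export
transcript_log <- function(transcript, round, direction, bytes, kind) {
  stopifnot(inherits(transcript, "transcript"), bytes >= 0)
  i <- length(transcript$round) + 1L
  transcript$round[i] <- round
  transcript$direction[i] <- direction
  transcript$bytes[i] <- bytes
  transcript$kind[i] <- kind
  invisible(transcript)
}

#' Transcript as a data frame
#'
#' @param transcript A `transcript`.
#' @return A data frame with columns `round`, `direction`, `bytes`, `kind`.
#' @export
transcript_df <- function(transcript) {
  stopifnot(inherits(transcript, "transcript"))
  data.frame(round = transcript$round, direction = transcript$direction,
             bytes = transcript$bytes, kind = transcript$kind,
             stringsAsFactors = FALSE)
}

#' Total transcript bytes
#'
#' @param transcript A `transcript`.
#' @param round Optional round-label prefix filter.
#' @return Total bytes logged (optionally restricted to one round prefix).
#' @export
transcript_total <- function(transcript, round = NULL) {
  stopifnot(inherits(transcript, "transcript"))
  if (is.null(round)) return(sum(transcript$bytes))
  sum(transcript$bytes[startsWith(transcript$round, round)])
}

#' Export a transcript to JSON
#'
#' @param transcript A `transcript`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
transcript_save <- function(transcript, path) {
  df <- transcript_df(transcript)
  jsonlite::write_json(
    list(entries = df, total_bytes = sum(df$bytes)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript entries=%d total=%.0f bytes>\n",
              length(x$round), sum(x$bytes)))
  invisible(x)
}

ct_bytes <- function(params) 32 + 8 * params$slot_count

# crypto RNG stream: swap .Random.seed in and out so protocol randomness never
# interferes with (or depends on) the caller's simulation RNG
with_crypto_rng <- function(session, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else NULL
  on.exit({
    session$rng_state <- get(".Random.seed", envir = genv, inherits = FALSE)
    if (is.null(old)) {
      rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  if (is.null(session$rng_state)) {
    set.seed(session$crypto_seed)
  } else {
    assign(".Random.seed", session$rng_state, envir = genv)
  }
  expr
}

crypto_integers <- function(session, n, lower, upper) {
  with_crypto_rng(session, {
    floor(stats::runif(n, lower, upper + 1))
  })
}

crypto_bits <- function(session, n) {
  with_crypto_rng(session, {
    as.integer(stats::runif(n) < 0.5)
  })
}

crypto_reals <- function(session, n, lower, upper) {
  with_crypto_rng(session, stats::runif(n, lower, upper))
}

crypto_seed_draw <- function(session) {
  with_crypto_rng(session, floor(stats::runif(1, 0, 2^31)))
}

#' Open a two-party secure-inference session
#'
#' Sets up the in-process transport: the client environment holds the full key
#' set (including the secret key), the server environment only the public part
#' plus caches for prepared weight diagonals and comparator circuits. All
#' protocol randomness (masks, blind bits, garbling seeds) is drawn from a
#' dedicated stream seeded by `crypto_seed`.
#'
#' @param params An [he_params()] object.
#' @param crypto_seed Integer seed for key generation and protocol randomness.
#' @param cfg An [adjust_config()] (clamp thresholds, comparator width, mask
#'   bound).
#' @param cheb The sigmoid `cheb_poly` used for gate activations (defaults to
#'   the protocol's degree-24 interpolant on `[-10, 10]`).
#' @return An object of class `secure_session`.
#' @export
secure_session <- function(params = he_params(), crypto_seed = 1L,
                           cfg = adjust_config(), cheb = NULL) {
  stopifnot(inherits(params, "he_params"))
  if (is.null(cheb)) cheb <- cheb_sigmoid(24L, c(-10, 10))
  keys <- he_keygen(params, crypto_seed)
  s <- new.env(parent = emptyenv())
  s$params <- params
  s$cfg <- cfg
  s$cheb <- cheb
  s$crypto_seed <- crypto_seed
  s$rng_state <- NULL
  s$transcript <- new_transcript()
  s$client <- new.env(parent = emptyenv())
  s$client$keys <- keys
  s$server <- new.env(parent = emptyenv())
  s$server$keys <- he_public(keys)
  s$server$matrix_cache <- new.env(parent = emptyenv())
  s$server$circuit_cache <- new.env(parent = emptyenv())
  s$counters <- new.env(parent = emptyenv())
  s$counters$cells <- 0L
  s$counters$refreshes <- 0L
  class(s) <- "secure_session"
  s
}

#' @export
print.secure_session <- function(x, ...) {
  cat(sprintf(
    "<secure_session slots=%d level=%d R=%g/%g cells=%d refreshes=%d comm=%.2f MB>\n",
    x$params$slot_count, x$params$max_level, x$cfg$R, x$cfg$R_tanh,
    x$counters$cells, x$counters$refreshes,
    transcript_total(x$transcript) / 2^20))
  invisible(x)
}

session_compare_circuit <- function(session, R, n_slots) {
  key <- sprintf("k%d_R%g_n%d", session$cfg$k, R, n_slots)
  cache <- session$server$circuit_cache
  if (is.null(cache[[key]])) {
    cache[[key]] <- build_compare_circuit(session$cfg$k, R, n_slots)
  }
  cache[[key]]
}

# client-side decrypt (the only place the secret key is used)
session_decrypt <- function(session, ct) he_decrypt(ct, session$client$keys)

# logging that never prints plaintext features or decrypted intermediates
hegru_log <- function(session, ...) {
  if (isTRUE(session$verbose)) message("[hegru] ", sprintf(...))
  invisible(NULL)
}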