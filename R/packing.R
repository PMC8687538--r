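# Packed homomorphic linear algebra. Vectors are zero-padded to a power-of-two
# block length (70 -> 128); with 4096 slots a ciphertext carries
# B = 4096/128 = 32 blocks, so a batch of up to 32 samples shares one
# ciphertext and one matrix product serves them all.
#
# Matrix-vector products use Halevi-Shoup diagonal packing: the padded matrix
# is split into generalized diagonals, each multiplied slot-wise against a
# rotation of the input. Because the padded matrix rows beyond the output
# dimension are zero, the non-output slots of the result are exactly zero — no
# garbage masking step (and no extra level) is needed. One product costs one
# level regardless of mode.

#' Zero-pad a vector to the next power of two
#'
#' @param v Non-empty numeric vector.
#' @return `v` zero-padded to the smallest power of two at least `length(v)`.
#' @export
pad_pow2 <- function(v) {
  if (length(v) < 1L) he_error("hegru_shape_error", "cannot pad an empty vector")
  n <- length(v)
  p <- 2^ceiling(log2(n))
  c(as.numeric(v), numeric(p - n))
}

#' Packed slot layout
#'
#' Describes how samples occupy ciphertext slots: each sample lives in a
#' contiguous block of `pad_len` slots, and a ciphertext holds
#' `B = slot_count / pad_len` blocks. `mode = "single"` uses block 0 only;
#' `mode = "batch"` packs up to `B` samples.
#'
#' @param slot_count HE slot count (power of two).
#' @param pad_len Power-of-two block length, at most `slot_count`.
#' @param mode `"single"` or `"batch"`.
#' @return A `packed_layout` with fields `pad_len`, `block_count`, `mode`.
#' @export
packed_layout <- function(slot_count = 4096L, pad_len = 128L,
                          mode = c("single", "batch")) {
  mode <- match.arg(mode)
  pad_len <- as.integer(pad_len)
  slot_count <- as.integer(slot_count)
  if (bitwAnd(pad_len, pad_len - 1L) != 0L || pad_len < 1L) {
    he_error("hegru_param_error", "pad_len must be a power of two")
  }
  if (pad_len > slot_count) {
    he_error("hegru_param_error", "pad_len cannot exceed the slot count")
  }
  structure(list(slot_count = slot_count, pad_len = pad_len,
                 block_count = slot_count %/% pad_len, mode = mode),
            class = "packed_layout")
}

#' @export
print.packed_layout <- function(x, ...) {
  cat(sprintf("<packed_layout %s pad_len=%d blocks=%d>\n",
              x$mode, x$pad_len, x$block_count))
  invisible(x)
}

layout_blocks <- function(layout) {
  if (layout$mode == "single") 1L else layout$block_count
}

#' Pack a batch of sample vectors into one ciphertext
#'
#' Sample `j` occupies slot block `[(j-1) * pad_len, j * pad_len)` (zero-padded
#' within the block); at most `block_count` samples fit.
#'
#' @param samples List of numeric vectors, each of length at most `pad_len`.
#' @param layout A `packed_layout` with `mode = "batch"` (or `"single"` with
#'   one sample).
#' @param keys HE key material (public part suffices).
#' @return An `he_ct` carrying the packed batch.
#' @export
pack_batch <- function(samples, layout, keys) {
  stopifnot(inherits(layout, "packed_layout"))
  if (!is.list(samples)) samples <- list(samples)
  cap <- layout_blocks(layout)
  if (length(samples) > cap) {
    he_error("hegru_capacity_error",
             sprintf("%d samples exceed the layout capacity of %d",
                     length(samples), cap))
  }
  slots <- numeric(layout$slot_count)
  for (j in seq_along(samples)) {
    v <- as.numeric(samples[[j]])
    if (length(v) > layout$pad_len) {
      he_error("hegru_shape_error",
               sprintf("sample %d longer than pad_len %d", j, layout$pad_len))
    }
    slots[(j - 1L) * layout$pad_len + seq_along(v)] <- v
  }
  he_encrypt(slots, keys)
}

#' Unpack block values from a decrypted slot vector
#'
#' @param slots Decrypted slot vector.
#' @param layout The `packed_layout` used for packing.
#' @param len Entries to keep per block.
#' @param n_samples Number of blocks to extract.
#' @return A list of numeric vectors, one per sample.
#' @export
unpack_batch <- function(slots, layout, len, n_samples = layout_blocks(layout)) {
  lapply(seq_len(n_samples), function(j) {
    slots[(j - 1L) * layout$pad_len + seq_len(len)]
  })
}

#' Prepare a weight matrix for packed products
#'
#' Precomputes the nonzero generalized diagonals of the zero-padded matrix as
#' full-width plaintext masks (replicated across blocks in batch mode), so
#' repeated products against the same matrix reuse them.
#'
#' @param w Numeric matrix (`n_out` x `n_in`), `n_in` and `n_out` at most
#'   `pad_len`.
#' @param layout A `packed_layout`.
#' @return A `packed_matrix` object.
#' @export
prep_weight_matrix <- function(w, layout) {
  stopifnot(is.matrix(w), inherits(layout, "packed_layout"))
  if (any(!is.finite(w))) {
    he_error("hegru_param_error", "weight matrix entries must be finite")
  }
  p <- layout$pad_len
  n_out <- nrow(w); n_in <- ncol(w)
  if (n_in > p || n_out > p) {
    he_error("hegru_shape_error",
             sprintf("matrix %dx%d does not fit the pad length %d",
                     n_out, n_in, p))
  }
  wp <- matrix(0, p, p)
  wp[seq_len(n_out), seq_len(n_in)] <- w
  nb <- layout_blocks(layout)
  i <- seq_len(p) - 1L
  diags <- list()
  for (j in seq_len(p) - 1L) {
    main <- numeric(p)
    wrap <- numeric(p)
    keep <- i + j < p
    if (any(keep)) main[i[keep] + 1L] <- wp[cbind(i[keep] + 1L, i[keep] + j + 1L)]
    if (any(!keep)) wrap[i[!keep] + 1L] <- wp[cbind(i[!keep] + 1L, i[!keep] + j - p + 1L)]
    if (any(main != 0)) {
      mask <- numeric(layout$slot_count)
      for (b in seq_len(nb)) mask[(b - 1L) * p + seq_len(p)] <- main
      diags[[length(diags) + 1L]] <- list(rot = j, mask = mask)
    }
    if (any(wrap != 0)) {
      mask <- numeric(layout$slot_count)
      for (b in seq_len(nb)) mask[(b - 1L) * p + seq_len(p)] <- wrap
      diags[[length(diags) + 1L]] <- list(rot = j - p, mask = mask)
    }
  }
  structure(list(diags = diags, n_out = n_out, n_in = n_in, layout = layout),
            class = "packed_matrix")
}

#' Homomorphic matrix-vector product (single query)
#'
#' Computes `W v` for an encrypted vector packed in block 0. The decrypted
#' leading `n_out` slots hold the product; all other slots are exactly zero
#' (up to encoding noise). Consumes one level.
#'
#' @param w A numeric matrix or a prepared `packed_matrix`.
#' @param ct_v An `he_ct` with the (padded) input vector in block 0.
#' @param layout A `packed_layout` with `mode = "single"`.
#' @param expected_len Optional declared input length; a mismatch with the
#'   matrix's column count raises a shape error.
#' @return An `he_ct` holding `W v` in the leading slots.
#' @export
he_matvec <- function(w, ct_v, layout = NULL, expected_len = NULL) {
  pm <- as_packed_matrix(w, layout, mode = "single")
  if (!is.null(expected_len) && pm$n_in != expected_len) {
    he_error("hegru_shape_error",
             sprintf("matrix has %d columns but the input layout declares %d",
                     pm$n_in, expected_len))
  }
  packed_product(pm, ct_v)
}

#' Homomorphic batched matrix product
#'
#' Applies `W` to every sample block of a batch-packed ciphertext at once: per
#' block `j` the result holds `W x_j`. One ciphertext (and one level) serves
#' the whole batch, which is what makes the homomorphic cost of a linear stage
#' independent of the number of samples up to the block capacity.
#'
#' @param w A numeric matrix or a prepared `packed_matrix`.
#' @param ct_x A batch-packed `he_ct` from [pack_batch()].
#' @param layout A `packed_layout` with `mode = "batch"`.
#' @return An `he_ct` with per-block products.
#' @export
he_matmat <- function(w, ct_x, layout = NULL) {
  pm <- as_packed_matrix(w, layout, mode = "batch")
  packed_product(pm, ct_x)
}

as_packed_matrix <- function(w, layout, mode) {
  if (inherits(w, "packed_matrix")) return(w)
  if (is.null(layout)) {
    he_error("hegru_param_error",
             "a packed_layout is required when passing a raw matrix")
  }
  if (layout$mode != mode) {
    he_error("hegru_param_error",
             sprintf("layout mode must be '%s' for this operation", mode))
  }
  prep_weight_matrix(w, layout)
}

packed_product <- function(pm, ct) {
  stopifnot(inherits(ct, "he_ct"))
  if (ct$n_slots != pm$layout$slot_count) {
    he_error("hegru_shape_error", "ciphertext and layout slot counts differ")
  }
  acc <- NULL
  for (d in pm$diags) {
    term <- he_mul(he_rotate(ct, d$rot), d$mask)
    acc <- if (is.null(acc)) term else he_add(acc, term)
  }
  if (is.null(acc)) acc <- he_mul(ct, 0) # all-zero matrix
  acc
}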