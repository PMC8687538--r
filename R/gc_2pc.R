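# Two-party garbled-circuit execution: garbling (point-and-permute, free-XOR),
# an ideal in-process oblivious-transfer backend, decoding with output-label
# verification, and the blinded comparison protocol built on top.

#' Garble a Boolean circuit
#'
#' Produces the garbler-side material (all wire label pairs via `label0` and
#' the global free-XOR `delta`) and the evaluator package (AND-gate tables plus
#' output decode information). The same `(circuit, seed)` pair regenerates an
#' identical garbling.
#'
#' @param circuit A `bool_circuit` from [build_compare_circuit()] or the
#'   circuit-builder helpers.
#' @param seed Numeric garbling seed (any value exactly representable as a
#'   double).
#' @return An object of class `garbled_circuit`: `tables`, `and_pos`,
#'   `decode` (per-output verification hashes for both labels), the garbler
#'   secrets `label0`/`delta`, and byte-accounting metadata.
#' @export
gc_garble <- function(circuit, seed) {
  stopifnot(inherits(circuit, "bool_circuit"))
  g <- cpp_garble(circuit$kind, circuit$in1, circuit$in2, circuit$out,
                  circuit$n_wires, as.numeric(seed))
  ow <- circuit_output_wires(circuit)
  lab0 <- g$label0[ow]
  # decode hints: keyed hashes of both valid labels per output wire, so the
  # evaluator can decode and detect corrupted labels without learning delta
  l1 <- vapply(seq_along(ow), function(i) xor_hex(g$label0[ow[i]], g$delta),
               character(1L))
  decode <- list(
    wires = ow,
    hash0 = cpp_hash_labels(lab0, ow),
    hash1 = cpp_hash_labels(l1, ow)
  )
  structure(
    list(circuit = circuit, tables = g$tables, and_pos = g$and_pos,
         n_and = g$n_and, decode = decode,
         label0 = g$label0, delta = g$delta, seed = as.numeric(seed)),
    class = "garbled_circuit"
  )
}

# XOR of two 16-hex-char labels (R side, used for garbler label arithmetic)
xor_hex <- function(a, b) {
  av <- strtoi(substring(a, seq(1, 16, 2), seq(2, 16, 2)), 16L)
  bv <- strtoi(substring(b, seq(1, 16, 2), seq(2, 16, 2)), 16L)
  paste(sprintf("%02x", bitwXor(av, bv)), collapse = "")
}

# garbler-side label selection for its own input bits
gc_select_labels <- function(garbled, wires, bits) {
  vapply(seq_along(wires), function(i) {
    l0 <- garbled$label0[wires[i]]
    if (bits[i] == 0L) l0 else xor_hex(l0, garbled$delta)
  }, character(1L))
}

#' Ideal oblivious transfer
#'
#' In-process OT backend: for each wire the receiver obtains exactly the label
#' matching its choice bit and nothing else; the sender's label pairs never
#' leave this call and the sender learns nothing about the choices (enforced
#' structurally by the call boundary).
#'
#' @param label_pairs A list (one element per wire) of `c(label0, label1)`
#'   character pairs, or a 2-row character matrix.
#' @param choice_bits 0/1 vector, one choice per wire.
#' @return Character vector of chosen labels.
#' @export
ot_choose <- function(label_pairs, choice_bits) {
  if (is.matrix(label_pairs)) {
    label_pairs <- lapply(seq_len(ncol(label_pairs)),
                          function(j) label_pairs[, j])
  }
  if (length(label_pairs) != length(choice_bits)) {
    he_error("hegru_shape_error", "one choice bit per label pair is required")
  }
  vapply(seq_along(choice_bits), function(i) {
    label_pairs[[i]][choice_bits[i] + 1L]
  }, character(1L))
}

#' Evaluate a garbled circuit
#'
#' Evaluator-side execution: walks the gate list with one valid label per
#' input wire and returns the output wire labels. Use [gc_decode()] to turn
#' them into bits.
#'
#' @param garbled A `garbled_circuit` (only its evaluator package is used).
#' @param input_labels Character vector of labels for all circuit input wires,
#'   in `input_map` order.
#' @return Character vector of output-wire labels.
#' @export
gc_eval <- function(garbled, input_labels) {
  stopifnot(inherits(garbled, "garbled_circuit"))
  circ <- garbled$circuit
  cpp_gc_eval(circ$kind, circ$in1, circ$in2, circ$out, circ$n_wires,
              garbled$and_pos, garbled$tables,
              circuit_input_wires(circ), input_labels,
              circuit_output_wires(circ))
}

#' Decode output labels to bits
#'
#' Matches each output label against the garbler-published verification hashes
#' of the wire's two valid labels. A label matching neither (a corrupted or
#' mixed-up label) raises a decode error instead of silently returning a wrong
#' bit.
#'
#' @param garbled A `garbled_circuit`.
#' @param output_labels Labels returned by [gc_eval()].
#' @return Named 0/1 integer vector over the circuit's outputs.
#' @export
gc_decode <- function(garbled, output_labels) {
  d <- garbled$decode
  h <- cpp_hash_labels(output_labels, d$wires)
  bits <- integer(length(h))
  for (i in seq_along(h)) {
    if (identical(h[i], d$hash0[i])) bits[i] <- 0L
    else if (identical(h[i], d$hash1[i])) bits[i] <- 1L
    else he_error("hegru_gc_error",
                  "output label failed verification (corrupted evaluation)")
  }
  ow <- circuit_output_wires(garbled$circuit)
  names(bits) <- rep(names(garbled$circuit$output_map),
                     lengths(garbled$circuit$output_map))
  bits
}

# Transcript byte model for one garbled execution (8-byte labels).
gc_bytes <- function(circuit, n_and) {
  list(tables = n_and * 4L * 8L,
       garbler_labels = (length(circuit$input_map$m_s) +
                           length(circuit$input_map$b_g) +
                           length(circuit$input_map$b_l)) * 8L,
       ot = length(circuit$input_map$m_c) * 2L * 8L,
       decode = length(circuit_output_wires(circuit)) * 2L * 8L)
}

#' Run the blinded two-party comparison
#'
#' Executes the comparison step of the secure input-adjustment protocol over
#' additive shares: the server (garbler) holds `m_s = -r` and the blind bits
#' `b_g`, `b_l`; the client (evaluator) holds `m_c = round(m + r)`. The client
#' obtains only the blinded bits `h_g = (m > R) XOR b_g` and
#' `h_l = (m < -R) XOR b_l`, never the comparison outcomes themselves; the
#' server obtains nothing.
#'
#' All arguments may be vectors (one entry per adjusted slot); the per-slot
#' comparators are concatenated into one circuit and garbled once.
#'
#' @param server List with integer `m_s`, and 0/1 `b_g`, `b_l`.
#' @param client List with integer `m_c`.
#' @param k Comparator bit width.
#' @param R Clamp threshold (circuit constant).
#' @param seed Garbling seed.
#' @param transcript Optional transcript to log communication into.
#' @param engine `"fused"` runs garble+OT+evaluate in one compiled pass;
#'   `"stepwise"` exercises the explicit [gc_garble()]/[ot_choose()]/
#'   [gc_eval()]/[gc_decode()] path. Both produce identical bits.
#' @return List with the client's `h_g` and `h_l` 0/1 vectors.
#' @export
run_2pc_compare <- function(server, client, k, R, seed = 1,
                            transcript = NULL, engine = c("fused", "stepwise")) {
  engine <- match.arg(engine)
  ns <- length(server$m_s)
  stopifnot(length(client$m_c) == ns, length(server$b_g) == ns,
            length(server$b_l) == ns)
  if (any(abs(server$m_s + client$m_c) >= 2^(k - 1) - R)) {
    he_error("hegru_overflow_error",
             "share sum overflows the comparator bit width; widen k or shrink the mask range")
  }
  circuit <- build_compare_circuit(k, R, n_slots = ns)
  bits <- compare_input_bits(circuit, server$m_s, client$m_c,
                             server$b_g, server$b_l)
  if (engine == "fused") {
    run <- cpp_compare_run(circuit$kind, circuit$in1, circuit$in2, circuit$out,
                           circuit$n_wires, circuit_input_wires(circuit),
                           bits, circuit_output_wires(circuit),
                           as.numeric(seed))
    out <- run$bits[1L, ]
    n_and <- run$n_and
  } else {
    garbled <- gc_garble(circuit, seed)
    im <- circuit$input_map
    server_wires <- c(im$m_s, im$b_g, im$b_l)
    iw <- circuit_input_wires(circuit)
    server_bits <- bits[1L, match(server_wires, iw)]
    client_bits <- bits[1L, match(im$m_c, iw)]
    server_labels <- gc_select_labels(garbled, server_wires, server_bits)
    pairs <- lapply(im$m_c, function(w) {
      c(garbled$label0[w], xor_hex(garbled$label0[w], garbled$delta))
    })
    client_labels <- ot_choose(pairs, client_bits)
    all_labels <- character(length(iw))
    all_labels[match(server_wires, iw)] <- server_labels
    all_labels[match(im$m_c, iw)] <- client_labels
    out <- unname(gc_decode(garbled, gc_eval(garbled, all_labels)))
    n_and <- garbled$n_and
  }
  if (!is.null(transcript)) {
    by <- gc_bytes(circuit, n_and)
    transcript_log(transcript, "2pc-compare", "s2c", by$tables, "garbled tables")
    transcript_log(transcript, "2pc-compare", "s2c", by$garbler_labels, "labels")
    transcript_log(transcript, "2pc-compare", "both", by$ot, "OT")
    transcript_log(transcript, "2pc-compare", "s2c", by$decode, "bits")
  }
  nh <- length(out) / 2L
  list(h_g = out[seq_len(nh)], h_l = out[nh + seq_len(nh)])
}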