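# Boolean circuits over {XOR, AND, NOT} and the adder+comparator circuit used
# by the secure input-adjustment protocol. Wires are 1-based; gates are stored
# in topological (construction) order, and every wire is written exactly once.

GATE_XOR <- 0L
GATE_AND <- 1L
GATE_NOT <- 2L

cc_new <- function() {
  env <- new.env(parent = emptyenv())
  env$kind <- integer(256L)
  env$in1 <- integer(256L)
  env$in2 <- integer(256L)
  env$out <- integer(256L)
  env$ng <- 0L
  env$n_wires <- 0L
  env
}

cc_wires <- function(cc, n) {
  w <- cc$n_wires + seq_len(n)
  cc$n_wires <- cc$n_wires + as.integer(n)
  w
}

cc_gate <- function(cc, kind, a, b = 0L) {
  force(a) # nested builder calls must allocate their wires before this gate's
  force(b)
  if (cc$ng == length(cc$kind)) {
    grow <- function(v) c(v, integer(length(v)))
    cc$kind <- grow(cc$kind); cc$in1 <- grow(cc$in1)
    cc$in2 <- grow(cc$in2); cc$out <- grow(cc$out)
  }
  o <- cc_wires(cc, 1L)
  i <- cc$ng + 1L
  cc$kind[i] <- kind; cc$in1[i] <- a; cc$in2[i] <- b; cc$out[i] <- o
  cc$ng <- i
  o
}

cc_xor <- function(cc, a, b) cc_gate(cc, GATE_XOR, a, b)
cc_and <- function(cc, a, b) cc_gate(cc, GATE_AND, a, b)
cc_not <- function(cc, a) cc_gate(cc, GATE_NOT, a)
cc_or <- function(cc, a, b) cc_xor(cc, cc_xor(cc, a, b), cc_and(cc, a, b))

cc_finalize <- function(cc, input_map, output_map, meta = list()) {
  i <- seq_len(cc$ng)
  structure(
    c(list(kind = cc$kind[i], in1 = cc$in1[i], in2 = cc$in2[i],
           out = cc$out[i], n_wires = cc$n_wires,
           input_map = input_map, output_map = output_map),
      meta),
    class = "bool_circuit"
  )
}

#' @export
print.bool_circuit <- function(x, ...) {
  cat(sprintf("<bool_circuit gates=%d (AND=%d) wires=%d inputs=%s outputs=%s>\n",
              length(x$kind), sum(x$kind == GATE_AND), x$n_wires,
              paste(names(x$input_map), collapse = ","),
              paste(names(x$output_map), collapse = ",")))
  invisible(x)
}

# Ordered vector of all circuit input wires (the order expected by the
# evaluation helpers: per slot, m_s bits, b_g, b_l, then m_c bits; generic
# circuits list their input_map entries in order).
circuit_input_wires <- function(circuit) {
  unlist(circuit$input_map, use.names = FALSE)
}

circuit_output_wires <- function(circuit) {
  unlist(circuit$output_map, use.names = FALSE)
}

#' Evaluate a Boolean circuit on plain bits
#'
#' Deterministic reference evaluation; this is the oracle the garbled execution
#' must match. Accepts one case (a 0/1 vector over the circuit's input wires,
#' in `input_map` order) or many cases as the rows of a 0/1 matrix.
#'
#' @param circuit A `bool_circuit`.
#' @param bits 0/1 vector of length `n_inputs`, or a matrix with `n_inputs`
#'   columns (rows are independent cases).
#' @return A 0/1 vector (or matrix, rows matching `bits`) over the circuit's
#'   output wires in `output_map` order.
#' @export
circuit_eval <- function(circuit, bits) {
  stopifnot(inherits(circuit, "bool_circuit"))
  iw <- circuit_input_wires(circuit)
  one_case <- is.null(dim(bits))
  m <- if (one_case) matrix(as.integer(bits), nrow = 1L) else {
    storage.mode(bits) <- "integer"
    bits
  }
  if (ncol(m) != length(iw)) {
    he_error("hegru_shape_error",
             sprintf("expected %d input bits, got %d", length(iw), ncol(m)))
  }
  w <- vector("list", circuit$n_wires)
  for (j in seq_along(iw)) w[[iw[j]]] <- m[, j]
  for (g in seq_along(circuit$kind)) {
    k <- circuit$kind[g]
    a <- w[[circuit$in1[g]]]
    w[[circuit$out[g]]] <- if (k == GATE_XOR) {
      bitwXor(a, w[[circuit$in2[g]]])
    } else if (k == GATE_AND) {
      bitwAnd(a, w[[circuit$in2[g]]])
    } else {
      1L - a
    }
  }
  ow <- circuit_output_wires(circuit)
  res <- vapply(ow, function(x) w[[x]], integer(nrow(m)))
  if (nrow(m) == 1L) res <- matrix(res, nrow = 1L)
  colnames(res) <- NULL
  if (one_case) drop(res) else res
}

# k-bit ripple-carry adder over wire vectors (LSB first), mod 2^k
cc_add_wires <- function(cc, a, b) {
  k <- length(a)
  s <- integer(k)
  x <- cc_xor(cc, a[1L], b[1L])
  s[1L] <- x
  carry <- cc_and(cc, a[1L], b[1L])
  if (k > 1L) {
    for (i in 2L:k) {
      x <- cc_xor(cc, a[i], b[i])
      s[i] <- cc_xor(cc, x, carry)
      if (i < k) {
        carry <- cc_xor(cc, cc_and(cc, a[i], b[i]), cc_and(cc, x, carry))
      }
    }
  }
  s
}

# Sign bit of (S + const) mod 2^k where const is a known k-bit constant.
# Only the carry chain plus the top sum bit are materialized; constant bits are
# folded into the gate structure (carry never becomes the constant 1 because
# the chain starts from a zero carry-in).
cc_add_const_sign <- function(cc, s, const_bits) {
  k <- length(s)
  carry <- NULL # NULL encodes a constant-zero carry
  if (k > 1L) {
    for (i in 1L:(k - 1L)) {
      if (const_bits[i] == 0L) {
        carry <- if (is.null(carry)) NULL else cc_and(cc, s[i], carry)
      } else {
        carry <- if (is.null(carry)) s[i] else cc_or(cc, s[i], carry)
      }
    }
  }
  top <- s[k]
  if (const_bits[k] == 1L) top <- cc_not(cc, top)
  if (is.null(carry)) top else cc_xor(cc, top, carry)
}

# bits of x mod 2^k, LSB first; returns a length(x) x k matrix
int_to_bits <- function(x, k) {
  x <- as.numeric(x) %% 2^k
  matrix(vapply(seq_len(k) - 1L, function(i) as.integer((x %/% 2^i) %% 2),
                integer(length(x))),
         nrow = length(x), ncol = k)
}

wrap_signed <- function(x, k) {
  y <- as.numeric(x) %% 2^k
  ifelse(y >= 2^(k - 1), y - 2^k, y)
}

#' Build the blinded adder+comparator circuit
#'
#' The circuit reconstructs `m = m_s + m_c` from the parties' k-bit
#' two's-complement additive shares, compares it against the clamp threshold
#' `R`, and outputs the two blinded bits `h_g = (m > R) XOR b_g` and
#' `h_l = (m < -R) XOR b_l` (strict inequalities). `m > R` is evaluated as the
#' complemented sign of `m - (R + 1)` and `m < -R` as the sign of `m + R`, so
#' correctness requires `|m| + R + 1 < 2^(k-1)` (no intermediate overflow).
#'
#' With `n_slots > 1` the per-slot comparator is replicated with disjoint
#' wires, giving one circuit (and one garbling) that adjusts a whole gate
#' vector at once.
#'
#' @param k Bit width of the two's-complement shares (`k >= 4`).
#' @param R Positive integer clamp threshold, `R < 2^(k-2)`.
#' @param n_slots Number of independent comparator instances.
#' @return A `bool_circuit` whose `input_map` holds per-slot wire ids for
#'   `m_s`, `b_g`, `b_l` (server) and `m_c` (client), and whose `output_map`
#'   holds the `h_g`, `h_l` wires.
#' @export
build_compare_circuit <- function(k, R, n_slots = 1L) {
  k <- as.integer(k)
  if (k < 4L) he_error("hegru_param_error", "bit width k must be >= 4")
  R <- as.numeric(R)
  if (R < 1 || R != floor(R)) {
    he_error("hegru_param_error", "R must be a positive integer")
  }
  if (R >= 2^(k - 2)) {
    he_error("hegru_param_error",
             sprintf("R = %.0f too large for bit width %d (need R < 2^(k-2))",
                     R, k))
  }
  base <- build_compare_slot(k, R)
  if (n_slots == 1L) return(base)
  replicate_circuit(base, as.integer(n_slots))
}

build_compare_slot <- function(k, R) {
  cc <- cc_new()
  m_s <- cc_wires(cc, k)
  b_g <- cc_wires(cc, 1L)
  b_l <- cc_wires(cc, 1L)
  m_c <- cc_wires(cc, k)
  s <- cc_add_wires(cc, m_s, m_c)
  # c_g = (m > R)  <=>  m - (R+1) >= 0  <=>  NOT sign(S + (2^k - R - 1))
  sign_a <- cc_add_const_sign(cc, s, int_to_bits(2^k - (R + 1), k))
  c_g <- cc_not(cc, sign_a)
  # c_l = (m < -R) <=>  sign(S + R) = 1
  c_l <- cc_add_const_sign(cc, s, int_to_bits(R, k))
  h_g <- cc_xor(cc, c_g, b_g)
  h_l <- cc_xor(cc, c_l, b_l)
  cc_finalize(
    cc,
    input_map = list(m_s = m_s, b_g = b_g, b_l = b_l, m_c = m_c),
    output_map = list(h_g = h_g, h_l = h_l),
    meta = list(k = k, R = R, n_slots = 1L)
  )
}

# Replicate a circuit n times with disjoint wire blocks (vectorized offsets).
replicate_circuit <- function(circuit, n) {
  nw <- circuit$n_wires
  off <- rep((seq_len(n) - 1L) * nw, each = length(circuit$kind))
  kind <- rep(circuit$kind, n)
  in1 <- rep(circuit$in1, n) + off
  in2 <- rep(circuit$in2, n) + ifelse(rep(circuit$kind, n) == GATE_NOT, 0L, off)
  out <- rep(circuit$out, n) + off
  woff <- (seq_len(n) - 1L) * nw
  rep_map <- function(map) {
    lapply(map, function(w) {
      as.integer(outer(w, woff, `+`))
    })
  }
  structure(
    list(kind = kind, in1 = in1, in2 = in2, out = out,
         n_wires = nw * n,
         input_map = rep_map(circuit$input_map),
         output_map = rep_map(circuit$output_map),
         k = circuit$k, R = circuit$R, n_slots = n * circuit$n_slots),
    class = "bool_circuit"
  )
}

# Encode compare-protocol inputs as a single-case bit row in circuit input
# order (all m_s bits slot by slot, then all b_g, all b_l, then all m_c bits,
# matching circuit_input_wires on a replicated circuit).
compare_input_bits <- function(circuit, m_s, m_c, b_g, b_l) {
  k <- circuit$k
  ns <- circuit$n_slots
  stopifnot(length(m_s) == ns, length(m_c) == ns,
            length(b_g) == ns, length(b_l) == ns)
  matrix(c(as.integer(t(int_to_bits(m_s, k))),
           as.integer(b_g), as.integer(b_l),
           as.integer(t(int_to_bits(m_c, k)))),
         nrow = 1L)
}
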