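# Garbled circuits: the comparator circuit against the arithmetic oracle,
# garbled evaluation against plain evaluation, OT semantics, blinding, and
# determinism of the garbling.

test_that("comparator circuit matches the arithmetic oracle exhaustively (k=6)", {
  k <- 6L
  for (R in c(1, 5, 9)) {
    circ <- build_compare_circuit(k, R)
    en <- compare_enumeration(k, R)
    for (bg in 0:1) {
      for (bl in 0:1) {
        bits <- cbind(hegru:::int_to_bits(en$m_s, k), bg, bl,
                      hegru:::int_to_bits(en$m_c, k))
        out <- circuit_eval(circ, bits)
        expect_identical(out[, 1L], bitwXor(as.integer(en$m > R), bg))
        expect_identical(out[, 2L], bitwXor(as.integer(en$m < -R), bl))
      }
    }
  }
})

test_that("boundary cases of the strict comparison", {
  circ <- build_compare_circuit(8L, 9)
  eval1 <- function(m_s, m_c, bg, bl) {
    circuit_eval(circ, cbind(hegru:::int_to_bits(m_s, 8L), bg, bl,
                             hegru:::int_to_bits(m_c, 8L)))
  }
  expect_identical(drop(eval1(4, 5, 0L, 0L)), c(0L, 0L))    # m = R exactly
  expect_identical(drop(eval1(5, 5, 1L, 0L)), c(0L, 0L))    # m = R+1, blinded
  expect_identical(drop(eval1(-5, -5, 0L, 1L)), c(0L, 0L))  # m = -R-1, blinded
  expect_identical(drop(eval1(-4, -5, 0L, 0L)), c(0L, 0L))  # m = -R exactly
})

test_that("R too large for the bit width is a parameter error", {
  expect_error(build_compare_circuit(6L, 16), class = "hegru_param_error")
  expect_error(build_compare_circuit(3L, 1), class = "hegru_param_error")
})

test_that("garbled evaluation equals plain evaluation on random k=16 inputs", {
  k <- 16L
  circ <- build_compare_circuit(k, 100)
  garbled <- gc_garble(circ, seed = 7)
  set.seed(13)
  iw <- hegru:::circuit_input_wires(circ)
  for (trial in 1:200) {
    m_s <- sample(-2^14:2^14, 1L)
    m_c <- sample(-2^14:2^14, 1L)
    bits <- cbind(hegru:::int_to_bits(m_s, k), sample(0:1, 1L),
                  sample(0:1, 1L), hegru:::int_to_bits(m_c, k))
    got <- hegru:::cpp_eval_batch(
      circ$kind, circ$in1, circ$in2, circ$out, circ$n_wires,
      garbled$and_pos, garbled$tables, garbled$label0, garbled$delta,
      iw, bits, hegru:::circuit_output_wires(circ))
    expect_identical(drop(got), unname(circuit_eval(circ, drop(bits))))
  }
})

test_that("garbling is seed-deterministic and seed-sensitive", {
  circ <- build_compare_circuit(8L, 5)
  g1 <- gc_garble(circ, 1)
  g2 <- gc_garble(circ, 1)
  g3 <- gc_garble(circ, 2)
  expect_identical(g1$tables, g2$tables)
  expect_identical(g1$label0, g2$label0)
  expect_false(identical(g1$label0, g3$label0))
  expect_false(identical(g1$tables, g3$tables))
})

test_that("ot_choose returns exactly the chosen label per wire", {
  pairs <- lapply(1:16, function(i) c(sprintf("%016x", i), sprintf("%016x", 100 + i)))
  expect_identical(ot_choose(pairs, rep(0L, 16)), sprintf("%016x", 1:16))
  expect_identical(ot_choose(pairs, rep(1L, 16)), sprintf("%016x", 101:116))
  set.seed(14)
  ch <- sample(0:1, 16, replace = TRUE)
  got <- ot_choose(pairs, ch)
  expect_identical(got, sprintf("%016x", 1:16 + 100 * ch))
  expect_error(ot_choose(pairs, ch[-1]), class = "hegru_shape_error")
})

test_that("stepwise garble/OT/eval path matches the fused engine and the oracle", {
  set.seed(15)
  for (trial in 1:10) {
    m <- sample(-40:40, 3L)
    r <- sample(-100:100, 3L)
    server <- list(m_s = -r, b_g = sample(0:1, 3L, TRUE),
                   b_l = sample(0:1, 3L, TRUE))
    client <- list(m_c = m + r)
    a <- run_2pc_compare(server, client, k = 10L, R = 9, seed = trial)
    b <- run_2pc_compare(server, client, k = 10L, R = 9, seed = trial,
                         engine = "stepwise")
    expect_identical(a, b)
    expect_identical(a$h_g, bitwXor(as.integer(m > 9), server$b_g))
    expect_identical(a$h_l, bitwXor(as.integer(m < -9), server$b_l))
  }
})

test_that("corrupted output labels fail decode instead of mis-decoding", {
  circ <- build_compare_circuit(8L, 5)
  garbled <- gc_garble(circ, 3)
  bits <- hegru:::compare_input_bits(circ, m_s = 1, m_c = 2, b_g = 0L, b_l = 0L)
  labels <- vapply(seq_along(bits), function(i) {
    w <- hegru:::circuit_input_wires(circ)[i]
    l0 <- garbled$label0[w]
    if (bits[i] == 1L) hegru:::xor_hex(l0, garbled$delta) else l0
  }, character(1L))
  out <- gc_eval(garbled, labels)
  expect_identical(unname(gc_decode(garbled, out)), c(0L, 0L))
  corrupted <- out
  corrupted[1L] <- hegru:::xor_hex(out[1L], "00000000000000ff")
  expect_error(gc_decode(garbled, corrupted), class = "hegru_gc_error")
})

test_that("share-sum overflow is rejected", {
  expect_error(
    run_2pc_compare(list(m_s = 100, b_g = 0L, b_l = 0L),
                    list(m_c = 100), k = 8L, R = 9),
    class = "hegru_overflow_error")
})

test_that("transcript bytes are deterministic for fixed circuit/seed/inputs", {
  tr1 <- new_transcript(); tr2 <- new_transcript()
  server <- list(m_s = c(-3, 8), b_g = c(1L, 0L), b_l = c(0L, 0L))
  client <- list(m_c = c(5, -2))
  run_2pc_compare(server, client, k = 12L, R = 5, seed = 9, transcript = tr1)
  run_2pc_compare(server, client, k = 12L, R = 5, seed = 9, transcript = tr2)
  expect_identical(transcript_df(tr1), transcript_df(tr2))
  expect_gt(transcript_total(tr1), 0)
})
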