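---
title: "Privacy-preserving GRU inference: model, protocol, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving GRU inference: model, protocol, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hegru)
```

## The problem

A server owns a trained clinical prediction model — a two-layer gated
recurrent unit (GRU) network whose dense head emits the two parameters of a
Weibull distribution over time to disease recurrence. A client owns a
patient's longitudinal record: a variable-length sequence of 70-dimensional
visit vectors. The two parties want the client to obtain the model's
prediction while the server learns nothing about the patient data and the
client learns nothing about the model weights beyond what the prediction
itself reveals. Both parties are assumed semi-honest: they follow the
protocol but may try to infer extra information from their view.

`hegru` implements this two-party inference engine: a SIMD leveled
homomorphic-encryption (HE) layer for all linear algebra and polynomial
activation evaluation, and a Yao garbled-circuit (GC) layer for the one step
polynomials cannot do safely — comparing an encrypted value against a
threshold.

## The model

A GRU cell with input $x_t$ and state $h_{t-1}$ computes

$$
z_t = \sigma(W_z x_t + U_z h_{t-1} + b_z), \qquad
r_t = \sigma(W_r x_t + U_r h_{t-1} + b_r),
$$
$$
g_t = \tanh(W_g x_t + U_g (h_{t-1} \odot r_t) + b_g), \qquad
h_t = z_t \odot h_{t-1} + (1 - z_t) \odot g_t,
$$

with $h_0 = 0$. The engine evaluates the state update in the rewritten
one-multiplication form $h_t = g_t + z_t \odot (h_{t-1} - g_t)$, which is
algebraically identical and saves a ciphertext product. The reset gate is
applied to the state *before* the recurrent multiplication in the candidate
gate ($U_g (h \odot r)$), which is the reading consistent with the staged
homomorphic workflow below. The reference architecture is
$70 \to 32 \to 20 \to 2$: layer 1 emits its full state sequence, layer 2 only
its last state, and the dense head returns $(a, b)$, from which the client
computes the Weibull parameters in plain.

The Weibull mapping is $\alpha = e^{a}$, $\beta = \mathrm{softplus}(b)$ —
both strictly monotone, so $(a,b)$ and $(\alpha,\beta)$ carry the same
information and the server can stop at the dense product without any loss of
privacy for itself. The mapping itself is a package default (the upstream
model family leaves it to the head's implementation) and is swappable.

## Why clamping, and the secure input-adjustment protocol

Non-linear activations are evaluated homomorphically as polynomials — here a
degree-24 Chebyshev interpolant of $\sigma$ on $[-10, 10]$, with
$\tanh(x) = 2\sigma(2x) - 1$ reusing the same interpolant. Polynomial
interpolants diverge violently outside their range, so one out-of-range
pre-activation would ruin the whole inference; yet the server cannot see the
encrypted pre-activations to know. Since $\sigma$ and $\tanh$ are essentially
flat outside a small interval, substituting any out-of-range input $m$ by
$\pm R$ changes the result only negligibly. The secure clamp computes, under
encryption,

$$
m' = (1 - c_g - c_l)\, m + R\,(c_g - c_l), \qquad
c_g = (m > R),\quad c_l = (m < -R),
$$

in three steps: (1) the server masks the ciphertext with a uniform integer
$r$ and sends it; the client decrypts and rounds, giving additive shares
$m_s = -r$, $m_c = \mathrm{round}(m + r)$; (2) a garbled adder+comparator
circuit reconstructs the share sum and hands the client only the *blinded*
bits $h_g = c_g \oplus b_g$, $h_l = c_l \oplus b_l$ (the blinds are the
server's secret coin flips, so the client learns nothing about the
comparison outcome); the client re-encrypts them; (3) the server unblinds
homomorphically ($c = h$ or $1 - h$ depending on its own plain blind) and
evaluates the recovery polynomial, spending one level of the message
ciphertext.

Because the masks are integers, the share sum is exactly
$\mathrm{round}(m)$: only the client-side rounding contributes error, at
most $1/2$ — within the protocol's one-unit error budget. Consequently the
comparison decision is deterministic in $m$: values with $|m| \le R - 1$
always pass through, $|m| \ge R + 1$ are always clamped, and inside the
band the result is one of $\{m, \pm R\}$. Two rules follow for choosing $R$:
the activation must already be flat at $R - 1$ (not just $R$), and the
interpolation range must cover $[-R - 1, R + 1]$. With the $[-10, 10]$
sigmoid range this gives $R = 9$ for the sigmoid gates; the candidate gate
feeds $2x$ into the same interpolant, so $2(R_{\tanh} + 1) \le 10$, i.e.
$R_{\tanh} = 4$.

The plaintext "clamped-reference" model (`gru_cell_plain(mode =
"clamped")`, `model_forward(mode = "clamped")`) implements exactly this
round-based rule, which is why secure and reference outputs agree to
encoding-noise accuracy rather than merely to approximation accuracy.

## HE layer: simulator semantics and parameters

The HE interface has CKKS-style semantics — encryption of real vectors,
slot-wise add/multiply, cyclic rotation, a level (multiplicative-depth)
budget, fixed-point scale metadata — with an exact-arithmetic simulator as
the mandatory backend. The simulator holds the slot vector privately,
enforces level/scale bookkeeping, refuses decryption under the wrong key,
and injects Gaussian encoding noise at encryption. The protocol logic is
identical under a real lattice backend plugged into the same interface; what
the simulator does *not* provide is actual cryptographic hardness, so no
security parameter estimation is meaningful or attempted here.

Defaults: 4096 slots, depth budget 8, scale $2^{30}$, encoding noise s.d.
$10^{-7}$ (so a roundtrip is accurate to $\varepsilon_{enc} = 5\times10^{-7}$
per slot). Level accounting is deliberately conservative: *every*
multiplication, plaintext or ciphertext operand alike, consumes one level.
This forces the interactive refresh machinery to be exercised rather than
quietly avoided. The moduli chain and scale of a real deployment are not
dictated by anything the protocol itself fixes; the defaults here are
package choices, with the slot count matching the deployment shape the
packing arithmetic is designed around.

Error propagation, not raw $\varepsilon_{enc}$, is the right yardstick for
derived quantities: the clamp's recovery polynomial multiplies the message
by a freshly encrypted bit expression, so its output error is bounded by
$\varepsilon_{enc}(1 + |m| + R)$ — the tolerance the clamp tests use.

## Packed linear algebra

Vectors are zero-padded to the next power of two (70 → 128), so a
4096-slot ciphertext carries $4096 / 128 = 32$ sample blocks. Matrix
products use Halevi–Shoup diagonal packing: the padded matrix is split into
generalized diagonals, each multiplied slot-wise against a rotation of the
input, with a second rotation term handling the wrap-around of each block.
Two properties motivated this choice over the naive rotate-and-sum
alternative: it costs exactly one level, and because the zero-padded
matrix rows beyond the output dimension are zero, the non-output slots of
the result are *exactly* zero — no garbage ever leaks into the next
recurrent step and no masking multiplication (or extra level) is needed.
In batch mode the same diagonals are replicated across blocks, so one
product serves up to 32 patients: the homomorphic cost of a linear stage is
independent of the batch size, while the garbled-circuit cost still grows
linearly with it.

## The secure cell, refresh placement, and depth arithmetic

One cell runs: Linear 1 (both sigmoid pre-activations), clamp at $R = 9$,
Chebyshev sigmoid; Linear 2 ($h \odot r$, then the candidate
pre-activation), clamp at $R_{\tanh} = 4$, tanh via the identity; Linear 3
(state update). The degree-24 interpolant is evaluated in the Chebyshev
basis with the product recurrences $T_{2m} = 2T_m^2 - 1$ and
$T_{2m+1} = 2 T_m T_{m+1} - T_1$ (doublings are free additions), so it
consumes $\lceil \log_2 24 \rceil + 2 = 7$ levels instead of 24 — which is
what lets a depth-8 budget host one activation between refreshes.

Refresh placement is handled by a level accountant: before every consuming
stage the remaining depth is checked against the stage's declared
requirement and an interactive masked refresh (server masks, client
decrypts-and-re-encrypts, server unmasks) is inserted if short. Whether the
state ciphertext is refreshed between cells or between layers is therefore
an internal cost policy, not a correctness question; every refresh is logged
in the transcript for audit. A patient with $N$ visits costs exactly $2N$
cell evaluations ($N$ per layer). The number of visits is revealed to the
server by the ciphertext count; the architecture is shared, and this
artifact treats the visit count as public metadata of the query.

## Garbled circuits

The comparator is a $k$-bit two's-complement ripple-carry adder over the
two shares followed by two constant-offset sign tests: $m > R$ as the
complemented sign of $m - (R+1)$ and $m < -R$ as the sign of $m + R$
(strict inequalities, constants folded into the gate structure). Garbling
uses point-and-permute with free XOR; NOT gates are label passthroughs.
The PRF behind the garbled tables is a SplitMix64-based keyed mixer
implemented in compiled code — structurally a PRF, sufficient for
protocol-correctness work, but not a vetted cryptographic primitive; a
deployment would swap in a standard cipher here. Output labels are decoded
against published verification hashes, so a corrupted label fails loudly
instead of silently mis-decoding. The oblivious transfer is an in-process
"ideal OT": the receiver obtains exactly the label of its choice bit, and
the sender's label pairs never cross the call boundary. The comparator width
defaults to $k = 32$, which holds the mask range ($2^{30}$) plus the message
bound with headroom; masks at that range give the shares a $2^{20}$
statistical hiding margin over the asserted message bound.

All per-slot comparators of one adjustment are concatenated into a single
circuit and garbled once — one garbled execution adjusts a whole gate
vector (32, 20, or batch multiples). The engine's fused compiled path
(garble, ideal-OT label selection, evaluate, decode in one pass) computes
exactly what the exposed stepwise `gc_garble()` / `ot_choose()` /
`gc_eval()` / `gc_decode()` surface computes; the tests hold the two paths
identical.

## Synthetic data: what it emulates and what it does not

The clinical registry behind the reference model is not public, so the
package generates cohorts with its statistical *shape*: visit sequences
within a 24-month window with on average about five visits (`1 +
Poisson(4.13)`, matching the upstream cohort's reported mean); 70 encoded
feature columns as 12 one-hot blocks totalling 40 columns, 29 z-scored
continuous columns, and one 10%-binned proportion feature in
$\{0.05, \dots, 0.95\}$; missing continuous values imputed by
last-observation-carried-forward with cohort means at a missing first
visit; Weibull event times driven by a linear risk score with calibrated
uniform right-censoring. The exact block decomposition of the original 31
clinical features into 70 columns is not public; only the length and the
encoding conventions matter to the protocol, and the schema is
configurable.

Because trained weights are likewise not public, `gen_weights()` draws
Gaussian weights and calibrates a global multiplier by bisection until a
requested fraction of gate pre-activations falls outside the clamp's
pass-through region on a 500-patient reference cohort — guaranteeing that
equivalence results genuinely exercise the clamp path rather than passing
vacuously. What passing tests on such cohorts show is that *encrypted
inference equals plaintext clamped inference* wherever the plaintext model
is well-defined; they do not show clinical validity of any particular
weight draw, nor realistic feature correlations.

## Numerical choices and pinned constants

* Chebyshev nodes of the first kind; the degree-24 interpolant's dense-grid
  (10,001 points) maximum error was measured once at $5.39\times10^{-4}$
  and is pinned in the tests as $\varepsilon_{cheb} = 5.5\times10^{-4}$ so
  regressions fail loudly. The tanh identity doubles this bound.
* Secure-vs-reference cell and end-to-end tolerances are pinned at
  $10^{-4}$ — two orders above the observed $\sim 10^{-6}$ noise floor and
  well below anything the approximation itself could explain away.
* Exact half-integer pre-activations can round differently under different
  mask parities (R's round-half-to-even meets a parity-varying integer
  offset); such points lie inside the clamp band by construction and are a
  measure-zero set for continuous inputs.
* Degenerate inputs: empty vectors, over-length vectors, mixed batch visit
  counts, over-capacity batches, level-0 multiplications, and
  wrong-key decryption all raise classed errors rather than returning
  garbage.
* Problem sizes in the test suite are chosen to make each property
  decisive at desk scale: comparator exhaustiveness is literally exhaustive
  at $k \in \{6, 8\}$; cell equivalence uses 100 seeded trials across six
  weight spreads; the end-to-end equivalence cohort is 200 patients with a
  5% out-of-range pre-activation rate in batched mode.

## Known limitations

* The HE backend is a semantics simulator: bit-level security, rotation-key
  material, and real CKKS noise growth are out of scope by design. The
  interface is the contract a lattice backend must meet.
* The garbling PRF is not a cryptographic hash; malicious security and OT
  extension are not addressed (the threat model is semi-honest).
* Wall-clock and byte benchmarks of a LAN deployment are
  hardware-dependent and are not reproduced; the transcript accounts bytes
  under this package's own serialization model.
* Model training is out of scope; weights are an input.

## A worked call

```{r demo, eval = FALSE}
cfg <- run_config(mode = "batch", seed_crypto = 31L, seed_sim = 32L)
d <- run_demo(cfg, n_patients = 20L, out_dir = "demo-out")
d$report[c("max_abs_diff_a_vs_clamped", "cindex_secure",
           "cindex_plain_clamped", "cells", "refreshes")]
```

The report shows the maximum deviation between encrypted and
clamped-reference dense outputs (encoding-noise scale), the two concordance
indices (equal), and the structural counters (84 cells for 20 patients with
42 total visits; several refreshes per cell, as the depth arithmetic above
predicts).
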