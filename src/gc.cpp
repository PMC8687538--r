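// Yao garbled-circuit engine: free-XOR, point-and-permute, SplitMix64-keyed PRF.
//
// The PRF here is a structural keyed mixer, good enough to make garbled tables
// opaque for protocol-correctness work; it is not a vetted cryptographic hash
// (no such primitive is required for the simulator-backed protocol tests).
//
// Gate kinds: 0 = XOR (free), 1 = AND (4-row table), 2 = NOT (label passthrough,
// garbler swaps the wire's label pair via the global delta).

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline uint64_t rotl64(uint64_t x, int r) {
  return (x << r) | (x >> (64 - r));
}

// gate-tweaked PRF over two labels
static inline uint64_t prf2(uint64_t a, uint64_t b, uint64_t gid) {
  return splitmix64(a ^ rotl64(b, 29) ^ (gid * 0xd1342543de82ef95ULL) ^
                    0xcafebabe1234f00dULL);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(splitmix64(seed ^ 0x5851f42d4c957f2dULL)) {}
  uint64_t next() {
    s += 0x9e3779b97f4a7c15ULL;
    return splitmix64(s);
  }
};

static std::string to_hex(uint64_t x) {
  static const char* d = "0123456789abcdef";
  std::string out(16, '0');
  for (int i = 15; i >= 0; --i) {
    out[i] = d[x & 0xf];
    x >>= 4;
  }
  return out;
}

static uint64_t from_hex(const std::string& s) {
  if (s.size() != 16) stop("label must be a 16-hex-character string");
  uint64_t x = 0;
  for (char c : s) {
    x <<= 4;
    if (c >= '0' && c <= '9') x |= (uint64_t)(c - '0');
    else if (c >= 'a' && c <= 'f') x |= (uint64_t)(c - 'a' + 10);
    else if (c >= 'A' && c <= 'F') x |= (uint64_t)(c - 'A' + 10);
    else stop("invalid hex character in label");
  }
  return x;
}

struct Garbled {
  uint64_t delta;
  std::vector<uint64_t> label0;       // zero-label per wire (garbler secret)
  std::vector<uint64_t> tables;       // 4 rows per AND gate, row-major
  std::vector<int> and_pos;           // per gate: index into tables/4, or -1
  int n_and;
};

// Core garbling. kinds/in1/in2/outw are 0-based wire ids here.
static Garbled garble_core(const IntegerVector& kinds, const IntegerVector& in1,
                           const IntegerVector& in2, const IntegerVector& outw,
                           int n_wires, uint64_t seed) {
  int ng = kinds.size();
  Garbled g;
  Rng rng(seed);
  g.delta = rng.next() | 1ULL;  // lsb(delta)=1 so select bits differ per pair
  g.label0.assign(n_wires, 0);
  std::vector<bool> assigned(n_wires, false), produced(n_wires, false);
  for (int i = 0; i < ng; ++i) produced[outw[i]] = true;
  // circuit inputs: wires referenced but never produced
  for (int i = 0; i < ng; ++i) {
    int a = in1[i];
    if (!produced[a] && !assigned[a]) { g.label0[a] = rng.next(); assigned[a] = true; }
    if (kinds[i] != 2) {
      int b = in2[i];
      if (!produced[b] && !assigned[b]) { g.label0[b] = rng.next(); assigned[b] = true; }
    }
  }
  g.and_pos.assign(ng, -1);
  g.n_and = 0;
  for (int i = 0; i < ng; ++i) if (kinds[i] == 1) g.n_and++;
  g.tables.assign((size_t)g.n_and * 4, 0);
  int ai = 0;
  for (int i = 0; i < ng; ++i) {
    int k = kinds[i], o = outw[i];
    uint64_t la0 = g.label0[in1[i]];
    if (k == 0) {                       // XOR: free
      g.label0[o] = la0 ^ g.label0[in2[i]];
    } else if (k == 2) {                // NOT: swap the pair
      g.label0[o] = la0 ^ g.delta;
    } else {                            // AND
      uint64_t lb0 = g.label0[in2[i]];
      uint64_t lo0 = rng.next();
      g.label0[o] = lo0;
      int pa = (int)(la0 & 1), pb = (int)(lb0 & 1);
      for (int ra = 0; ra < 2; ++ra) {
        for (int rb = 0; rb < 2; ++rb) {
          int va = ra ^ pa, vb = rb ^ pb;      // plain values behind select bits
          uint64_t la = (va == 0) ? la0 : (la0 ^ g.delta);
          uint64_t lb = (vb == 0) ? lb0 : (lb0 ^ g.delta);
          uint64_t lo = ((va & vb) == 0) ? lo0 : (lo0 ^ g.delta);
          g.tables[(size_t)ai * 4 + ra * 2 + rb] = prf2(la, lb, (uint64_t)i) ^ lo;
        }
      }
      g.and_pos[i] = ai++;
    }
  }
  return g;
}

// Evaluate one instance given labels for every circuit-input wire.
static void eval_core(const IntegerVector& kinds, const IntegerVector& in1,
                      const IntegerVector& in2, const IntegerVector& outw,
                      const std::vector<int>& and_pos,
                      const std::vector<uint64_t>& tables,
                      std::vector<uint64_t>& wlab) {
  int ng = kinds.size();
  for (int i = 0; i < ng; ++i) {
    int k = kinds[i], o = outw[i];
    uint64_t la = wlab[in1[i]];
    if (k == 0) {
      wlab[o] = la ^ wlab[in2[i]];
    } else if (k == 2) {
      wlab[o] = la;                      // NOT is a passthrough for the evaluator
    } else {
      uint64_t lb = wlab[in2[i]];
      int row = (int)(la & 1) * 2 + (int)(lb & 1);
      wlab[o] = tables[(size_t)and_pos[i] * 4 + row] ^ prf2(la, lb, (uint64_t)i);
    }
  }
}

// [[Rcpp::export]]
List cpp_garble(IntegerVector kinds, IntegerVector in1, IntegerVector in2,
                IntegerVector outw, int n_wires, double seed) {
  IntegerVector i1 = clone(in1), i2 = clone(in2), ow = clone(outw);
  for (int i = 0; i < i1.size(); ++i) {
    i1[i] -= 1; ow[i] -= 1;
    if (kinds[i] != 2) i2[i] -= 1; else i2[i] = 0;
  }
  Garbled g = garble_core(kinds, i1, i2, ow, n_wires, (uint64_t)seed);
  CharacterVector lab0(n_wires);
  for (int w = 0; w < n_wires; ++w) lab0[w] = to_hex(g.label0[w]);
  CharacterVector tab(g.n_and * 4);
  for (int i = 0; i < g.n_and * 4; ++i) tab[i] = to_hex(g.tables[i]);
  IntegerVector ap(kinds.size());
  for (int i = 0; i < kinds.size(); ++i) ap[i] = g.and_pos[i];
  return List::create(_["label0"] = lab0, _["delta"] = to_hex(g.delta),
                      _["tables"] = tab, _["and_pos"] = ap,
                      _["n_and"] = g.n_and);
}

// [[Rcpp::export]]
CharacterVector cpp_gc_eval(IntegerVector kinds, IntegerVector in1,
                            IntegerVector in2, IntegerVector outw, int n_wires,
                            IntegerVector and_pos, CharacterVector tables,
                            IntegerVector input_wires,
                            CharacterVector input_labels,
                            IntegerVector output_wires) {
  if (input_wires.size() != input_labels.size())
    stop("one label per input wire is required");
  std::vector<uint64_t> tabs(tables.size());
  for (int i = 0; i < tables.size(); ++i) tabs[i] = from_hex(as<std::string>(tables[i]));
  std::vector<int> ap(and_pos.begin(), and_pos.end());
  std::vector<uint64_t> wlab(n_wires, 0);
  for (int i = 0; i < input_wires.size(); ++i)
    wlab[input_wires[i] - 1] = from_hex(as<std::string>(input_labels[i]));
  IntegerVector i1 = clone(in1), i2 = clone(in2), ow = clone(outw);
  for (int i = 0; i < i1.size(); ++i) {
    i1[i] -= 1; ow[i] -= 1;
    if (kinds[i] != 2) i2[i] -= 1; else i2[i] = 0;
  }
  eval_core(kinds, i1, i2, ow, ap, tabs, wlab);
  CharacterVector out(output_wires.size());
  for (int i = 0; i < output_wires.size(); ++i)
    out[i] = to_hex(wlab[output_wires[i] - 1]);
  return out;
}

// Garbler-assisted batch evaluation: selects input labels from (label0, delta)
// per case, evaluates, decodes, and verifies each output label is one of the
// wire's two valid labels. Rows of input_bits are cases.
// [[Rcpp::export]]
IntegerMatrix cpp_eval_batch(IntegerVector kinds, IntegerVector in1,
                             IntegerVector in2, IntegerVector outw, int n_wires,
                             IntegerVector and_pos, CharacterVector tables,
                             CharacterVector label0, std::string delta,
                             IntegerVector input_wires, IntegerMatrix input_bits,
                             IntegerVector output_wires) {
  int ng = kinds.size(), ncase = input_bits.nrow(), nin = input_wires.size(),
      nout = output_wires.size();
  if (input_bits.ncol() != nin) stop("input bit matrix width must match input wires");
  std::vector<uint64_t> tabs(tables.size());
  for (int i = 0; i < tables.size(); ++i) tabs[i] = from_hex(as<std::string>(tables[i]));
  std::vector<uint64_t> l0(n_wires);
  for (int w = 0; w < n_wires; ++w) l0[w] = from_hex(as<std::string>(label0[w]));
  uint64_t dlt = from_hex(delta);
  std::vector<int> ap(and_pos.begin(), and_pos.end());
  std::vector<int> i1(ng), i2(ng), ow(ng);
  for (int i = 0; i < ng; ++i) {
    i1[i] = in1[i] - 1; ow[i] = outw[i] - 1;
    i2[i] = (kinds[i] != 2) ? in2[i] - 1 : 0;
  }
  IntegerMatrix res(ncase, nout);
  std::vector<uint64_t> wlab(n_wires);
  for (int c = 0; c < ncase; ++c) {
    for (int j = 0; j < nin; ++j) {
      int w = input_wires[j] - 1;
      wlab[w] = input_bits(c, j) ? (l0[w] ^ dlt) : l0[w];
    }
    for (int i = 0; i < ng; ++i) {
      int k = kinds[i], o = ow[i];
      uint64_t la = wlab[i1[i]];
      if (k == 0) wlab[o] = la ^ wlab[i2[i]];
      else if (k == 2) wlab[o] = la;
      else {
        uint64_t lb = wlab[i2[i]];
        int row = (int)(la & 1) * 2 + (int)(lb & 1);
        wlab[o] = tabs[(size_t)ap[i] * 4 + row] ^ prf2(la, lb, (uint64_t)i);
      }
    }
    for (int j = 0; j < nout; ++j) {
      int w = output_wires[j] - 1;
      uint64_t l = wlab[w];
      if (l == l0[w]) res(c, j) = 0;
      else if (l == (l0[w] ^ dlt)) res(c, j) = 1;
      else stop("garbled evaluation produced an invalid output label");
    }
  }
  return res;
}

// Fused garble + ideal-OT label selection + evaluate + decode. One garbling of
// the (possibly slot-concatenated) circuit serves all rows of input_bits; this
// is the engine behind the protocol's batched comparison step.
// [[Rcpp::export]]
List cpp_compare_run(IntegerVector kinds, IntegerVector in1, IntegerVector in2,
                     IntegerVector outw, int n_wires, IntegerVector input_wires,
                     IntegerMatrix input_bits, IntegerVector output_wires,
                     double seed) {
  int ng = kinds.size();
  IntegerVector i1 = clone(in1), i2 = clone(in2), ow = clone(outw);
  for (int i = 0; i < ng; ++i) {
    i1[i] -= 1; ow[i] -= 1;
    if (kinds[i] != 2) i2[i] -= 1; else i2[i] = 0;
  }
  Garbled g = garble_core(kinds, i1, i2, ow, n_wires, (uint64_t)seed);
  int ncase = input_bits.nrow(), nin = input_wires.size(),
      nout = output_wires.size();
  IntegerMatrix res(ncase, nout);
  std::vector<uint64_t> wlab(n_wires);
  std::vector<int> i1v(i1.begin(), i1.end()), i2v(i2.begin(), i2.end()),
      owv(ow.begin(), ow.end());
  for (int c = 0; c < ncase; ++c) {
    for (int j = 0; j < nin; ++j) {
      int w = input_wires[j] - 1;
      wlab[w] = input_bits(c, j) ? (g.label0[w] ^ g.delta) : g.label0[w];
    }
    for (int i = 0; i < ng; ++i) {
      int k = kinds[i], o = owv[i];
      uint64_t la = wlab[i1v[i]];
      if (k == 0) wlab[o] = la ^ wlab[i2v[i]];
      else if (k == 2) wlab[o] = la;
      else {
        uint64_t lb = wlab[i2v[i]];
        int row = (int)(la & 1) * 2 + (int)(lb & 1);
        wlab[o] = g.tables[(size_t)g.and_pos[i] * 4 + row] ^ prf2(la, lb, (uint64_t)i);
      }
    }
    for (int j = 0; j < nout; ++j) {
      int w = output_wires[j] - 1;
      uint64_t l = wlab[w];
      if (l == g.label0[w]) res(c, j) = 0;
      else if (l == (g.label0[w] ^ g.delta)) res(c, j) = 1;
      else stop("garbled evaluation produced an invalid output label");
    }
  }
  return List::create(_["bits"] = res, _["n_and"] = g.n_and);
}

// keyed hash of labels (decode/verification hints published by the garbler)
// [[Rcpp::export]]
CharacterVector cpp_hash_labels(CharacterVector labels, IntegerVector tweaks) {
  if (labels.size() != tweaks.size()) stop("labels/tweaks length mismatch");
  CharacterVector out(labels.size());
  for (int i = 0; i < labels.size(); ++i) {
    uint64_t l = from_hex(as<std::string>(labels[i]));
    out[i] = to_hex(prf2(l, 0x517cc1b727220a95ULL, (uint64_t)tweaks[i]));
  }
  return out;
}

// deterministic 64-bit hash of a string (key ids, params fingerprints)
// [[Rcpp::export]]
std::string cpp_hash_str(std::string s) {
  uint64_t h = 0x6c62272e07bb0142ULL;
  for (unsigned char c : s) h = splitmix64(h ^ (uint64_t)c);
  return to_hex(h);
}
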