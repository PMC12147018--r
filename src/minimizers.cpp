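#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cstdlib>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit nucleotide encoding: A=00 C=01 G=10 T=11 (case-insensitive).
// Anything else (N, IUPAC codes, gaps) is ambiguous.
static inline int nt_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline uint64_t low_mask(int ell) {
  return (ell >= 32) ? ~0ULL : ((1ULL << (2 * ell)) - 1ULL);
}

static uint64_t parse_hex64(const std::string& s) {
  uint64_t v = 0;
  for (char c : s) {
    int d;
    if (c >= '0' && c <= '9') d = c - '0';
    else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
    else break;
    v = (v << 4) | (uint64_t)d;
  }
  return v;
}

static std::string to_hex64(uint64_t v) {
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v);
  return std::string(buf);
}

// Canonical 2-bit encoding of an ell-mer: min(forward, reverse complement)
// as unsigned integers. Returns false if any base is ambiguous.
static bool encode_canonical_one(const char* s, int ell, uint64_t& out) {
  uint64_t fwd = 0, rc = 0;
  for (int i = 0; i < ell; i++) {
    int c = nt_code(s[i]);
    if (c < 0) return false;
    fwd = (fwd << 2) | (uint64_t)c;
    rc |= ((uint64_t)(3 - c)) << (2 * i);
  }
  out = fwd < rc ? fwd : rc;
  return true;
}

// [[Rcpp::export(name = ".encode_canonical_cpp")]]
CharacterVector encode_canonical_cpp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; i++) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    int ell = (int)s.size();
    if (ell < 1 || ell > 32)
      stop("sequence length must be between 1 and 32 for a 64-bit key");
    uint64_t v;
    if (encode_canonical_one(s.c_str(), ell, v)) out[i] = to_hex64(v);
    else out[i] = NA_STRING;
  }
  return out;
}

// [[Rcpp::export(name = ".ordering_value_cpp")]]
CharacterVector ordering_value_cpp(CharacterVector keys, std::string seed_hex,
                                   std::string toggle_hex, int ell) {
  uint64_t m = low_mask(ell);
  uint64_t seed = parse_hex64(seed_hex) & m;
  uint64_t toggle = parse_hex64(toggle_hex) & m;
  int n = keys.size();
  CharacterVector out(n);
  for (int i = 0; i < n; i++) {
    if (CharacterVector::is_na(keys[i])) { out[i] = NA_STRING; continue; }
    uint64_t v = parse_hex64(as<std::string>(keys[i])) & m;
    out[i] = to_hex64((v & ~seed) ^ toggle);
  }
  return out;
}

// Sliding-window minimizer extraction over every maximal unambiguous
// segment of length >= k. For each k-bp window, the minimizer is the
// ell-mer minimizing (canonical_key & ~seed) ^ toggle, leftmost on ties.
// The emitted key is the *masked* canonical encoding (toggle not applied).
// Offsets are 0-based window starts in the original sequence.
// [[Rcpp::export(name = ".minimizers_cpp")]]
List minimizers_cpp(std::string seq, int k, int ell, std::string seed_hex,
                    std::string toggle_hex) {
  if (ell > k) stop("minimizer length ell must not exceed window length k");
  if (ell < 1 || ell > 32) stop("ell must be between 1 and 32");
  uint64_t m = low_mask(ell);
  uint64_t seed = parse_hex64(seed_hex) & m;
  uint64_t toggle = parse_hex64(toggle_hex) & m;
  int n = (int)seq.size();
  std::vector<int> offsets;
  std::vector<std::string> keys;

  int i = 0;
  while (i < n) {
    // find next maximal run of unambiguous bases
    while (i < n && nt_code(seq[i]) < 0) i++;
    int start = i;
    while (i < n && nt_code(seq[i]) >= 0) i++;
    int end = i;  // [start, end) unambiguous
    int len = end - start;
    if (len < k) continue;

    // canonical key per ell-mer position within the segment
    int npos = len - ell + 1;
    std::vector<uint64_t> canon(npos);
    {
      uint64_t fwd = 0, rc = 0;
      for (int p = start; p < end; p++) {
        int c = nt_code(seq[p]);
        fwd = ((fwd << 2) | (uint64_t)c) & m;
        rc = (rc >> 2) | (((uint64_t)(3 - c)) << (2 * (ell - 1)));
        int idx = p - start - ell + 1;
        if (idx >= 0) canon[idx] = fwd < rc ? fwd : rc;
      }
    }

    int span = k - ell;  // candidate ell-mer starts per window: span + 1
    for (int w = 0; w <= len - k; w++) {
      uint64_t best_ord = 0, best_key = 0;
      bool first = true;
      for (int p = w; p <= w + span; p++) {
        uint64_t ord = (canon[p] & ~seed) ^ toggle;
        if (first || ord < best_ord) {
          best_ord = ord;
          best_key = canon[p] & ~seed;
          first = false;
        }
      }
      offsets.push_back(start + w);
      keys.push_back(to_hex64(best_key));
    }
  }

  return List::create(_["offset"] = wrap(offsets), _["key"] = wrap(keys));
}
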