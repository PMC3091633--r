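#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// 4-bit base-set encoding (A=1, C=2, G=4, T=8) built from the IUPAC map
// supplied by R, so the base-set table has a single source of truth.
static void build_base_sets(const CharacterVector &symbols,
                            const CharacterVector &sets,
                            uint8_t code[256]) {
  for (int i = 0; i < 256; ++i) code[i] = 0;
  for (int i = 0; i < symbols.size(); ++i) {
    const char sym = Rcpp::as<std::string>(symbols[i])[0];
    std::string s = Rcpp::as<std::string>(sets[i]);
    uint8_t b = 0;
    for (char c : s) {
      if (c == 'A') b |= 1; else if (c == 'C') b |= 2;
      else if (c == 'G') b |= 4; else if (c == 'T') b |= 8;
    }
    code[(unsigned char)sym] = b;
  }
}

// Wu-Manber bitap with k substitutions and per-position mismatch
// prohibition; patterns up to 63 nt (one 64-bit word per mismatch level).
// protected0: 0-based pattern positions where a mismatch is forbidden.
// Returns a 2-column integer matrix: 0-based window start, mismatch count.
static IntegerMatrix bitap_core(const std::string &pat, const std::string &txt,
                                int k, const std::vector<int> &protected0,
                                const uint8_t code[256]) {
  const int m = (int)pat.size(), n = (int)txt.size();
  uint64_t mask[256];
  for (int c = 0; c < 256; ++c) mask[c] = 0;
  for (int c = 0; c < 256; ++c) {
    if (!code[c]) continue;
    uint64_t w = 0;
    for (int j = 0; j < m; ++j)
      if (code[(unsigned char)pat[j]] & code[c]) w |= (uint64_t)1 << j;
    mask[c] = w;
  }
  uint64_t allow = ~(uint64_t)0;
  if (m < 64) allow = ((uint64_t)1 << m) - 1;
  for (int p : protected0) allow &= ~((uint64_t)1 << p);

  const int kk = std::min(k, m);
  std::vector<uint64_t> R(kk + 1, 0), Rn(kk + 1, 0);
  const uint64_t hit = (uint64_t)1 << (m - 1);
  std::vector<int> starts, mms;
  for (int i = 0; i < n; ++i) {
    const uint64_t mc = mask[(unsigned char)txt[i]];
    Rn[0] = ((R[0] << 1) | 1) & mc;
    for (int d = 1; d <= kk; ++d)
      Rn[d] = (((R[d] << 1) | 1) & mc) | (((R[d - 1] << 1) | 1) & allow);
    std::swap(R, Rn);
    for (int d = 0; d <= kk; ++d) {
      if (R[d] & hit) {
        starts.push_back(i - m + 1);
        mms.push_back(d);
        break;
      }
    }
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t i = 0; i < starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = mms[i];
  }
  return out;
}

// Naive fallback with the identical contract, used for patterns > 63 nt.
static IntegerMatrix naive_core(const std::string &pat, const std::string &txt,
                                int k, const std::vector<int> &protected0,
                                const uint8_t code[256]) {
  const int m = (int)pat.size(), n = (int)txt.size();
  std::vector<bool> prot(m, false);
  for (int p : protected0) prot[p] = true;
  std::vector<int> starts, mms;
  for (int o = 0; o + m <= n; ++o) {
    int mm = 0;
    bool ok = true;
    for (int j = 0; j < m; ++j) {
      if (!(code[(unsigned char)pat[j]] & code[(unsigned char)txt[o + j]])) {
        if (prot[j]) { ok = false; break; }
        if (++mm > k) { ok = false; break; }
      }
    }
    if (ok) { starts.push_back(o); mms.push_back(mm); }
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t i = 0; i < starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = mms[i];
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix bitap_search(std::string pattern, std::string text,
                           int max_mismatches, IntegerVector protected0,
                           CharacterVector iupac_symbols,
                           CharacterVector iupac_sets) {
  uint8_t code[256];
  build_base_sets(iupac_symbols, iupac_sets, code);
  std::vector<int> prot(protected0.begin(), protected0.end());
  if ((int)pattern.size() > (int)text.size() || pattern.empty())
    return IntegerMatrix(0, 2);
  if ((int)pattern.size() <= 63)
    return bitap_core(pattern, text, max_mismatches, prot, code);
  return naive_core(pattern, text, max_mismatches, prot, code);
}
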