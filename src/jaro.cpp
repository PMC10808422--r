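#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Decode a UTF-8 byte string into code points so accented names compare by
// character, not byte. Invalid bytes are kept as-is (latin-1 fallback).
static std::vector<uint32_t> utf8_decode(const char *s) {
  std::vector<uint32_t> out;
  const unsigned char *p = reinterpret_cast<const unsigned char *>(s);
  while (*p) {
    uint32_t cp;
    int extra;
    if (*p < 0x80)            { cp = *p;         extra = 0; }
    else if ((*p >> 5) == 6)  { cp = *p & 0x1F;  extra = 1; }
    else if ((*p >> 4) == 14) { cp = *p & 0x0F;  extra = 2; }
    else if ((*p >> 3) == 30) { cp = *p & 0x07;  extra = 3; }
    else                      { out.push_back(*p++); continue; }
    ++p;
    for (int i = 0; i < extra; ++i) {
      if ((*p & 0xC0) != 0x80) { extra = -1; break; }
      cp = (cp << 6) | (*p & 0x3F);
      ++p;
    }
    if (extra < 0) continue;
    out.push_back(cp);
  }
  return out;
}

static double jaro_one(const std::vector<uint32_t> &a,
                       const std::vector<uint32_t> &b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  const int window = std::max(std::max(la, lb) / 2 - 1, 0);

  std::vector<char> amatch(la, 0), bmatch(lb, 0);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    const int lo = std::max(0, i - window);
    const int hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!bmatch[j] && a[i] == b[j]) {
        amatch[i] = bmatch[j] = 1;
        ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;

  // transpositions: matched characters out of order, halved
  int half_transp = 0, j = 0;
  for (int i = 0; i < la; ++i) {
    if (!amatch[i]) continue;
    while (!bmatch[j]) ++j;
    if (a[i] != b[j]) ++half_transp;
    ++j;
  }
  const double t = half_transp / 2.0;
  return ((double)m / la + (double)m / lb + (m - t) / m) / 3.0;
}

// [[Rcpp::export]]
NumericVector jaro_sim_cpp(CharacterVector s1, CharacterVector s2) {
  const R_xlen_t n = s1.size();
  if (s2.size() != n) stop("s1 and s2 must have equal length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (s1[i] == NA_STRING || s2[i] == NA_STRING) {
      out[i] = NA_REAL;
      continue;
    }
    std::vector<uint32_t> a = utf8_decode(Rf_translateCharUTF8(s1[i]));
    std::vector<uint32_t> b = utf8_decode(Rf_translateCharUTF8(s2[i]));
    out[i] = jaro_one(a, b);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector jaro_winkler_sim_cpp(CharacterVector s1, CharacterVector s2,
                                   double p, int lmax) {
  const R_xlen_t n = s1.size();
  if (s2.size() != n) stop("s1 and s2 must have equal length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (s1[i] == NA_STRING || s2[i] == NA_STRING) {
      out[i] = NA_REAL;
      continue;
    }
    std::vector<uint32_t> a = utf8_decode(Rf_translateCharUTF8(s1[i]));
    std::vector<uint32_t> b = utf8_decode(Rf_translateCharUTF8(s2[i]));
    const double sim = jaro_one(a, b);
    int ell = 0;
    const int cap = std::min<int>(std::min(a.size(), b.size()), lmax);
    while (ell < cap && a[ell] == b[ell]) ++ell;
    out[i] = sim + ell * p * (1.0 - sim);
  }
  return out;
}
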