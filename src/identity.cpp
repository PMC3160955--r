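#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

// Generalized-kinship recursion over a pedigree in topological order.
//
// Individuals are 1..n with sire[i-1], dam[i-1] in 0..n, 0 meaning unknown
// (unknown parents are distinct, unrelated, non-inbred phantom founders).
// Topological order is assumed: parents always have a smaller index than
// their offspring, so for a set of arguments the one with the largest index
// is never an ancestor of the others and can be expanded into its parents.
//
// Quantities (all probabilities of joint identity by descent among
// independent random allele draws):
//   phi2(a,b)      one draw from each of a and b IBD
//   phi3(a,b,c)    three draws, all IBD (arguments may repeat)
//   phi4(a,b,c,d)  four draws, all IBD
//   phi22(a,b|c,d) draw-from-a IBD draw-from-b AND draw-from-c IBD draw-from-d
// Draws from a repeated individual are independent; two draws that land on
// the same side (paternal/paternal) are the same physical allele, which is
// what the boundary formulas below encode.

namespace {

// Compact open-addressing hash map (uint64 key -> double, linear probing).
// The recursion can visit 1e8+ tuples on deep intercross pedigrees, so the
// ~80-byte nodes of std::unordered_map are unaffordable; 16-byte slots keep
// that within a laptop's memory.
struct FlatMap {
  static constexpr uint64_t EMPTY = ~0ull;  // ids are < 65535, never all-ones
  std::vector<uint64_t> keys;
  std::vector<double> vals;
  size_t mask = 0, count = 0;

  FlatMap() { rehash(1 << 12); }

  static uint64_t mix(uint64_t x) {
    x ^= x >> 33;
    x *= 0xff51afd7ed558ccdull;
    x ^= x >> 33;
    x *= 0xc4ceb9fe1a85ec53ull;
    x ^= x >> 33;
    return x;
  }

  void rehash(size_t cap) {
    std::vector<uint64_t> ok = std::move(keys);
    std::vector<double> ov = std::move(vals);
    keys.assign(cap, EMPTY);
    vals.assign(cap, 0.0);
    mask = cap - 1;
    count = 0;
    for (size_t i = 0; i < ok.size(); ++i) {
      if (ok[i] != EMPTY) insert(ok[i], ov[i]);
    }
  }

  // returns pointer to value if present, else nullptr
  const double* find(uint64_t k) const {
    size_t i = mix(k) & mask;
    while (keys[i] != EMPTY) {
      if (keys[i] == k) return &vals[i];
      i = (i + 1) & mask;
    }
    return nullptr;
  }

  void insert(uint64_t k, double v) {
    if ((count + 1) * 5 > (mask + 1) * 3) rehash((mask + 1) << 1);
    size_t i = mix(k) & mask;
    while (keys[i] != EMPTY) {
      if (keys[i] == k) {
        vals[i] = v;
        return;
      }
      i = (i + 1) & mask;
    }
    keys[i] = k;
    vals[i] = v;
    ++count;
  }
};

struct Engine {
  const int* sire;
  const int* dam;
  int n;
  FlatMap m2, m3, m4, m22;

  bool is_founder(int a) const { return sire[a - 1] == 0 && dam[a - 1] == 0; }

  static uint64_t key(int a, int b, int c, int d) {
    return ((uint64_t)a << 48) | ((uint64_t)b << 32) | ((uint64_t)c << 16) |
           (uint64_t)d;
  }

  double phi2(int a, int b) {
    if (a == 0 || b == 0) return 0.0;
    if (a < b) std::swap(a, b);
    uint64_t k = key(0, 0, a, b);
    if (const double* p = m2.find(k)) return *p;
    double v;
    int s = sire[a - 1], d = dam[a - 1];
    if (a == b) {
      v = 0.5 * (1.0 + phi2(s, d));
    } else if (is_founder(a)) {
      v = 0.0;  // b precedes a, hence is not a descendant of a
    } else {
      v = 0.5 * (phi2(s, b) + phi2(d, b));
    }
    m2.insert(k, v);
    return v;
  }

  double phi3(int a, int b, int c) {
    if (a == 0 || b == 0 || c == 0) return 0.0;
    // sort descending so a >= b >= c
    if (a < b) std::swap(a, b);
    if (b < c) std::swap(b, c);
    if (a < b) std::swap(a, b);
    uint64_t k = key(0, a, b, c);
    if (const double* p = m3.find(k)) return *p;
    double v;
    int s = sire[a - 1], d = dam[a - 1];
    bool fdr = is_founder(a);
    if (a == b && b == c) {
      v = fdr ? 0.25 : 0.25 * (1.0 + 3.0 * phi2(s, d));
    } else if (a == b) {  // (a,a,c)
      v = fdr ? 0.0 : 0.5 * phi2(a, c) + 0.5 * phi3(s, d, c);
    } else {
      v = fdr ? 0.0 : 0.5 * (phi3(s, b, c) + phi3(d, b, c));
    }
    m3.insert(k, v);
    return v;
  }

  double phi4(int a, int b, int c, int d4) {
    if (a == 0 || b == 0 || c == 0 || d4 == 0) return 0.0;
    int x[4] = {a, b, c, d4};
    std::sort(x, x + 4, std::greater<int>());
    uint64_t k = key(x[0], x[1], x[2], x[3]);
    if (const double* p = m4.find(k)) return *p;
    double v;
    int top = x[0];
    int s = sire[top - 1], d = dam[top - 1];
    bool fdr = is_founder(top);
    int mult = 1;
    while (mult < 4 && x[mult] == top) ++mult;
    if (mult == 4) {
      v = fdr ? 0.125 : 0.125 * (1.0 + 7.0 * phi2(s, d));
    } else if (mult == 3) {
      v = fdr ? 0.0 : 0.25 * phi2(top, x[3]) + 0.75 * phi3(s, d, x[3]);
    } else if (mult == 2) {
      v = fdr ? 0.0 : 0.5 * phi3(top, x[2], x[3]) + 0.5 * phi4(s, d, x[2], x[3]);
    } else {
      v = fdr ? 0.0 : 0.5 * (phi4(s, x[1], x[2], x[3]) + phi4(d, x[1], x[2], x[3]));
    }
    m4.insert(k, v);
    return v;
  }

  // phi22((a,b),(c,d)); any unknown slot makes the joint event impossible
  double phi22(int a, int b, int c, int d4) {
    if (a == 0 || b == 0 || c == 0 || d4 == 0) return 0.0;
    if (a < b) std::swap(a, b);
    if (c < d4) std::swap(c, d4);
    if (a < c || (a == c && b < d4)) {
      std::swap(a, c);
      std::swap(b, d4);
    }
    uint64_t k = key(a, b, c, d4);
    if (const double* p = m22.find(k)) return *p;
    double v;
    int top = a;  // overall max after canonicalization
    int s = sire[top - 1], d = dam[top - 1];
    bool fdr = is_founder(top);
    if (b == top && c == top && d4 == top) {  // (xx,xx)
      v = fdr ? 0.25 : 0.25 + 0.75 * phi2(s, d);
    } else if (b == top && c == top) {  // (xx,xe)
      v = fdr ? 0.0 : 0.5 * phi2(top, d4) + 0.5 * phi3(s, d, d4);
    } else if (b == top) {  // (xx,cd)
      v = 0.5 * phi2(c, d4) + (fdr ? 0.0 : 0.5 * phi22(s, d, c, d4));
    } else if (c == top) {  // (xb,xe): two independent draws from x
      v = fdr ? 0.0
              : 0.25 * (phi3(s, b, d4) + phi3(d, b, d4)) +
                    0.25 * (phi22(s, b, d, d4) + phi22(d, b, s, d4));
    } else {  // (xb,cd)
      v = fdr ? 0.0 : 0.5 * (phi22(s, b, c, d4) + phi22(d, b, c, d4));
    }
    m22.insert(k, v);
    return v;
  }
};

}  // namespace

// For each requested pair (i,j) return the eight generalized quantities that
// determine Jacquard's condensed identity coefficients:
//   f_i, f_j, phi2(ij), phi3(iij), phi3(ijj), phi4(iijj),
//   phi22(ii|jj), phi22(ij|ij)
// seed_upto > 0 pre-fills the pairwise-kinship cache for all individuals with
// index <= seed_upto in topological (generation) order before answering
// queries: seed_upto = n is a full top-down schedule, 0 is pure bottom-up,
// intermediate values give the hybrid schedule.
// [[Rcpp::export]]
Rcpp::NumericMatrix cic_engine(Rcpp::IntegerVector sire, Rcpp::IntegerVector dam,
                               Rcpp::IntegerMatrix pairs, int seed_upto) {
  int n = sire.size();
  Engine eng{INTEGER(sire), INTEGER(dam), n, {}, {}, {}, {}};
  if (seed_upto > n) seed_upto = n;
  for (int a = 1; a <= seed_upto; ++a) {
    for (int b = 1; b <= a; ++b) eng.phi2(a, b);
    if (a % 256 == 0) Rcpp::checkUserInterrupt();
  }
  int np = pairs.nrow();
  Rcpp::NumericMatrix out(np, 8);
  for (int r = 0; r < np; ++r) {
    int i = pairs(r, 0), j = pairs(r, 1);
    if (i < 1 || i > n || j < 1 || j > n)
      Rcpp::stop("pair index out of range");
    out(r, 0) = 2.0 * eng.phi2(i, i) - 1.0;
    out(r, 1) = 2.0 * eng.phi2(j, j) - 1.0;
    out(r, 2) = eng.phi2(i, j);
    out(r, 3) = eng.phi3(i, i, j);
    out(r, 4) = eng.phi3(i, j, j);
    out(r, 5) = eng.phi4(i, i, j, j);
    out(r, 6) = eng.phi22(i, i, j, j);
    out(r, 7) = eng.phi22(i, j, i, j);
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Dense pairwise kinship for a whole pedigree in topological order;
// used by the tabular kinship/inbreeding path for large pedigrees.
// [[Rcpp::export]]
Rcpp::NumericMatrix kinship_engine(Rcpp::IntegerVector sire,
                                   Rcpp::IntegerVector dam) {
  int n = sire.size();
  Rcpp::NumericMatrix phi(n, n);
  for (int a = 0; a < n; ++a) {
    int s = sire[a] - 1, d = dam[a] - 1;  // -1 when unknown
    for (int b = 0; b < a; ++b) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * phi(s, b);
      if (d >= 0) v += 0.5 * phi(d, b);
      phi(a, b) = v;
      phi(b, a) = v;
    }
    double fsd = (s >= 0 && d >= 0) ? phi(s, d) : 0.0;
    phi(a, a) = 0.5 * (1.0 + fsd);
    if (a % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return phi;
}
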