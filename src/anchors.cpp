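#include <Rcpp.h>
#include <unordered_map>
#include <cstring>
using namespace Rcpp;

static inline int b2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// occurrence record for one canonical k-mer class in one genome
struct Occ {
  int count = 0;
  int pos = -1;
  bool fwd_is_canonical = false;
};

static void scan_kmers(const std::string& seq, int k,
                       const IntegerVector& mask_start,
                       const IntegerVector& mask_end,
                       std::unordered_map<uint64_t, Occ>& out) {
  const int n = (int) seq.size();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = b2(seq[i]);
    if (b < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid < k) continue;
    int pos = i - k + 1;
    bool masked = false;
    for (int m = 0; m < mask_start.size(); ++m)
      if (pos >= mask_start[m] && pos < mask_end[m]) { masked = true; break; }
    if (masked) continue;
    if (fwd == rev) continue;             // palindromic k-mer: ambiguous strand
    uint64_t canon = fwd < rev ? fwd : rev;
    Occ& o = out[canon];
    if (o.count == 0) { o.pos = pos; o.fwd_is_canonical = (fwd < rev); }
    o.count++;
  }
}

// Anchors: k-mers unique in both genomes (strand-equivalence classes).
// orientation +1 when both genomes hold the same strand of the class.
// [[Rcpp::export]]
DataFrame cpp_anchor_map(std::string ref, std::string query, int k,
                         IntegerVector ref_mask_start, IntegerVector ref_mask_end,
                         IntegerVector query_mask_start, IntegerVector query_mask_end) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  std::unordered_map<uint64_t, Occ> tr, tq;
  tr.reserve(ref.size() * 2); tq.reserve(query.size() * 2);
  scan_kmers(ref, k, ref_mask_start, ref_mask_end, tr);
  scan_kmers(query, k, query_mask_start, query_mask_end, tq);

  std::vector<int> rp, qp, orient;
  for (auto& kv : tr) {
    if (kv.second.count != 1) continue;
    auto it = tq.find(kv.first);
    if (it == tq.end() || it->second.count != 1) continue;
    rp.push_back(kv.second.pos);
    qp.push_back(it->second.pos);
    orient.push_back(kv.second.fwd_is_canonical == it->second.fwd_is_canonical ? 1 : -1);
  }
  return DataFrame::create(_["ref_pos0"] = rp, _["query_pos0"] = qp,
                           _["orientation"] = orient);
}

// ---------------------------------------------------------------------------
// Longest pair of disjoint, exactly matching inverted segments: binary search
// over length with rolling hashes; every candidate verified by memcmp.
// ---------------------------------------------------------------------------

static const uint64_t HB = 1000000007ULL;

// find a witness (i in seq, j in rc) of a common substring of length L whose
// mapped seq intervals are disjoint; returns leftmost-i witness or (-1,-1)
static bool witness(const std::string& s, const std::string& rc, int L,
                    int& wi, int& wj) {
  const int n = (int) s.size();
  if (L < 1 || L > n) return false;
  uint64_t powL = 1;
  for (int t = 0; t < L; ++t) powL *= HB;
  std::unordered_map<uint64_t, std::vector<int> > tab;
  tab.reserve(n * 2);
  uint64_t h = 0;
  for (int i = 0; i < n; ++i) {
    h = h * HB + (uint8_t) s[i];
    if (i >= L) h -= powL * (uint8_t) s[i - L];
    if (i >= L - 1) tab[h].push_back(i - L + 1);
  }
  int best_i = -1, best_j = -1;
  h = 0;
  for (int j = 0; j < n; ++j) {
    h = h * HB + (uint8_t) rc[j];
    if (j >= L) h -= powL * (uint8_t) rc[j - L];
    if (j < L - 1) continue;
    int jj = j - L + 1;                       // start in rc coords
    auto it = tab.find(h);
    if (it == tab.end()) continue;
    int m1 = n - jj - L;                      // mapped seq interval [m1, m1+L)
    for (int i : it->second) {
      if (std::memcmp(s.data() + i, rc.data() + jj, L) != 0) continue;
      // disjoint intervals in seq coords
      int a = std::min(i, m1), b = std::max(i, m1);
      if (b < a + L) continue;
      if (best_i < 0 || a < best_i || (a == best_i && b < best_j)) {
        best_i = a; best_j = b;
      }
    }
  }
  if (best_i < 0) return false;
  wi = best_i; wj = best_j;
  return true;
}

// [[Rcpp::export]]
List cpp_longest_inverted_pair(std::string seq, int min_len) {
  const int n = (int) seq.size();
  std::string rc(n, 'N');
  for (int i = 0; i < n; ++i) {
    char c = seq[n - 1 - i];
    switch (c) {
      case 'A': rc[i] = 'T'; break; case 'C': rc[i] = 'G'; break;
      case 'G': rc[i] = 'C'; break; case 'T': rc[i] = 'A'; break;
      default: rc[i] = 'N';
    }
  }
  int lo = min_len, hi = n / 2, bi = -1, bj = -1, bl = -1;
  int wi, wj;
  while (lo <= hi) {
    int mid = lo + (hi - lo) / 2;
    if (witness(seq, rc, mid, wi, wj)) {
      bi = wi; bj = wj; bl = mid; lo = mid + 1;
    } else hi = mid - 1;
  }
  if (bl < 0) return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["start1_0"] = bi,
                      _["start2_0"] = bj, _["length"] = bl);
}
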