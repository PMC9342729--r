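#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstring>
using namespace Rcpp;

// Shared helpers for the repeat scanners. Sequences arrive as uppercase
// A/C/G/T/N strings; N never matches anything (including another N).

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static inline bool bases_match(char a, char b) {
  return a == b && a != 'N';
}

// ---------------------------------------------------------------------------
// MISA-style SSR scan: maximal runs of a primitive 1-6 bp motif.
// ---------------------------------------------------------------------------

static bool motif_primitive(const char* s, int u) {
  // primitive iff no proper divisor of u is a period of the motif
  for (int d = 1; d < u; ++d) {
    if (u % d != 0) continue;
    bool periodic = true;
    for (int i = d; i < u; ++i) {
      if (s[i] != s[i - d]) { periodic = false; break; }
    }
    if (periodic) return false;
  }
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_find_ssrs(std::string seq, IntegerVector min_reps) {
  const char* s = seq.c_str();
  const int n = (int) seq.size();
  std::vector<int> start, unit, nrep;
  std::vector<std::string> motif;

  for (int u = 1; u <= 6; ++u) {
    int need = min_reps[u - 1];
    int i = u;
    while (i < n) {
      if (!bases_match(s[i], s[i - u])) { ++i; continue; }
      int run_start = i;                 // first position matching i-u
      while (i < n && bases_match(s[i], s[i - u])) ++i;
      int a = run_start - u;             // repeat region start
      int len = i - a;                   // total region length (>= u+1)
      int count = len / u;
      if (count >= need) {
        // require all bases of motif unambiguous and motif primitive
        bool ok = true;
        for (int t = 0; t < u; ++t) if (base2bit(s[a + t]) < 0) ok = false;
        if (ok && motif_primitive(s + a, u)) {
          start.push_back(a);
          unit.push_back(u);
          nrep.push_back(count);
          motif.push_back(seq.substr(a, u));
        }
      }
    }
  }
  return DataFrame::create(_["start0"] = start, _["unit"] = unit,
                           _["n_repeats"] = nrep, _["motif"] = motif,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Maximal dispersed repeats (forward / palindromic) with a Hamming budget.
//
// Definition (shared with the R brute-force oracle): on each comparison
// diagonal, a hit is a maximal window with <= h mismatches whose end
// positions are matches; copies must be disjoint; palindromic pairs are
// canonicalized so copy1 precedes copy2.
// ---------------------------------------------------------------------------

static inline bool in_mask(int pos, int len,
                           const IntegerVector& mstart, const IntegerVector& mend) {
  // fully inside any mask interval [mstart, mend) ?
  for (int i = 0; i < mstart.size(); ++i)
    if (pos >= mstart[i] && pos + len <= mend[i]) return true;
  return false;
}

static inline bool pos_masked(int pos, const IntegerVector& mstart,
                              const IntegerVector& mend) {
  for (int i = 0; i < mstart.size(); ++i)
    if (pos >= mstart[i] && pos < mend[i]) return true;
  return false;
}

// [[Rcpp::export]]
DataFrame cpp_find_dispersed(std::string seq, int min_len, int max_h,
                             bool forward, bool palindromic,
                             IntegerVector mask_start, IntegerVector mask_end) {
  const int n = (int) seq.size();
  const char* s = seq.c_str();
  std::string rc(n, 'N');
  for (int i = 0; i < n; ++i) rc[n - 1 - i] = comp_base(s[i]);
  const char* t = rc.c_str();

  // pigeonhole: a window of length min_len with <= max_h mismatches
  // contains an exact run of >= (min_len - max_h) / (max_h + 1)
  int k = (min_len - max_h) / (max_h + 1);
  if (k < 3) k = 3;
  if (k > 12) k = 12;
  std::vector<std::string> kind;
  std::vector<int> s1v, s2v, lenv, mmv;
  std::unordered_set<long long> seen;

  // seed table over seq k-mers (positions, skipping N and masked)
  std::unordered_map<uint64_t, std::vector<int> > tab;
  if (n >= k) {
    uint64_t key = 0; int valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) b) & ((1ULL << (2 * k)) - 1);
      if (++valid >= k) {
        int pos = i - k + 1;
        if (!pos_masked(pos, mask_start, mask_end)) tab[key].push_back(pos);
      }
    }
  }

  // orientation 0 = forward (seq vs seq), 1 = palindromic (seq vs revcomp)
  for (int orient = 0; orient < 2; ++orient) {
    if (orient == 0 && !forward) continue;
    if (orient == 1 && !palindromic) continue;
    const char* other = (orient == 0) ? s : t;

    // collect seed positions per diagonal d = pos_other - pos_seq
    std::unordered_map<int, std::vector<int> > diag_seeds;
    if (n >= k) {
      uint64_t key = 0; int valid = 0;
      for (int i = 0; i < n; ++i) {
        int b = base2bit(other[i]);
        if (b < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t) b) & ((1ULL << (2 * k)) - 1);
        if (++valid >= k) {
          int pos2 = i - k + 1;
          if (orient == 1) {
            // position in rc maps back to seq; skip seeds mapping into mask
            int seq_pos = n - pos2 - k;
            if (pos_masked(seq_pos, mask_start, mask_end)) continue;
          } else {
            if (pos_masked(pos2, mask_start, mask_end)) continue;
          }
          auto it = tab.find(key);
          if (it == tab.end()) continue;
          for (int pos1 : it->second) {
            if (orient == 0 && pos1 == pos2) continue;
            diag_seeds[pos2 - pos1].push_back(pos1);
          }
        }
      }
    }

    for (auto& kv : diag_seeds) {
      int d = kv.first;
      if (orient == 0 && d <= 0) continue;   // forward: scan each pair once
      int lo = std::max(0, -d), hi = std::min(n, n - d);
      if (hi - lo < min_len) continue;
      std::vector<int>& sds = kv.second;
      std::sort(sds.begin(), sds.end());
      sds.erase(std::unique(sds.begin(), sds.end()), sds.end());

      std::vector<std::array<int,3> > wins;   // (start, end incl, mismatches)
      int skip_until = lo - 1;                // seeds inside the same match run
      for (int sp : sds) {
        if (sp + k - 1 <= skip_until) continue;
        // expand: collect up to h+1 mismatch positions on each side
        std::vector<int> mmL, mmR;
        for (int i = sp - 1; i >= lo && (int) mmL.size() <= max_h; --i)
          if (!bases_match(s[i], other[i + d])) mmL.push_back(i);
        for (int i = sp + k; i < hi && (int) mmR.size() <= max_h; ++i)
          if (!bases_match(s[i], other[i + d])) mmR.push_back(i);
        // a later seed inside the same unbroken match run repeats this work
        skip_until = mmR.empty() ? hi : mmR.front() - k;
        // sentinel-bounded sorted mismatch list around the seed
        std::vector<int> full;
        if ((int) mmL.size() <= max_h) full.push_back(lo - 1);
        for (int q = (int) mmL.size() - 1; q >= 0; --q) full.push_back(mmL[q]);
        for (int q = 0; q < (int) mmR.size(); ++q) full.push_back(mmR[q]);
        if ((int) mmR.size() <= max_h) full.push_back(hi);
        const int fs = (int) full.size();
        for (int tt = 0; tt + max_h + 1 < fs; ++tt) {
          int a = full[tt] + 1, b = full[tt + max_h + 1] - 1;
          while (a <= b && !bases_match(s[a], other[a + d])) ++a;
          while (b >= a && !bases_match(s[b], other[b + d])) --b;
          if (b - a + 1 < min_len) continue;
          int x = 0;
          for (int q = 0; q < fs; ++q)
            if (full[q] > a && full[q] < b && full[q] >= lo && full[q] < hi) ++x;
          wins.push_back({a, b, x});
        }
      }
      // dedupe and drop windows contained in another window on this diagonal
      std::sort(wins.begin(), wins.end());
      wins.erase(std::unique(wins.begin(), wins.end()), wins.end());
      for (size_t i = 0; i < wins.size(); ++i) {
        bool contained = false;
        for (size_t j = 0; j < wins.size() && !contained; ++j) {
          if (i == j) continue;
          if (wins[j][0] <= wins[i][0] && wins[i][1] <= wins[j][1] &&
              (wins[j][0] < wins[i][0] || wins[i][1] < wins[j][1]))
            contained = true;
        }
        if (contained) continue;
        const auto& w = wins[i];
        int a = w[0], b = w[1];
        int len = b - a + 1;
        int p1 = a, p2;
        if (orient == 0) {
          p2 = a + d;
        } else {
          p2 = n - (b + d) - 1;
        }
        if (p2 < p1) std::swap(p1, p2);
        if (p2 < p1 + len) continue;        // copies must be disjoint
        if (in_mask(p1, len, mask_start, mask_end) ||
            in_mask(p2, len, mask_start, mask_end)) continue;
        long long hkey = ((long long) orient << 62) |
                         (((long long) p1) << 41) | (((long long) p2) << 20) |
                         (long long) (len & 0xFFFFF);
        if (!seen.insert(hkey).second) continue;
        kind.push_back(orient == 0 ? "forward" : "palindromic");
        s1v.push_back(p1); s2v.push_back(p2);
        lenv.push_back(len); mmv.push_back(w[2]);
      }
    }
  }
  return DataFrame::create(_["kind"] = kind, _["start1_0"] = s1v,
                           _["start2_0"] = s2v, _["length"] = lenv,
                           _["mismatches"] = mmv,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Simplified tandem-repeat detector: diagonal self-matches at period p,
// X-drop extension with match +2 / mismatch -7, no indels.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_find_tandem(std::string seq, int min_period, int max_period,
                          int match, int mismatch, int min_score, int xdrop) {
  const char* s = seq.c_str();
  const int n = (int) seq.size();
  std::vector<int> startv, endv, periodv, scorev, matchesv;

  for (int p = min_period; p <= max_period && p < n; ++p) {
    // mark positions i (i >= p) where s[i] == s[i-p]
    int i = p;
    std::vector<uint8_t> used(n, 0);
    while (i < n) {
      if (!bases_match(s[i], s[i - p]) || used[i]) { ++i; continue; }
      // seed: run of matches; require an exact run >= min(8, p)
      int run_start = i;
      while (i < n && bases_match(s[i], s[i - p])) ++i;
      if (i - run_start < std::min(8, p)) continue;
      // X-drop extension left and right over the diagonal
      int best_l = run_start, best_r = i - 1;
      int sc = (i - run_start) * match, best_sc = sc;
      int cur = sc, r = i;
      while (r < n) {
        cur += bases_match(s[r], s[r - p]) ? match : mismatch;
        if (cur < best_sc - xdrop) break;
        if (cur > best_sc) { best_sc = cur; best_r = r; }
        ++r;
      }
      int l = run_start - 1; cur = best_sc;
      int best_sc2 = best_sc;
      while (l >= p) {
        cur += bases_match(s[l], s[l - p]) ? match : mismatch;
        if (cur < best_sc2 - xdrop) break;
        if (cur > best_sc2) { best_sc2 = cur; best_l = l; }
        --l;
      }
      // window [best_l, best_r] of diagonal positions; trim ends to matches
      int a = best_l, b = best_r;
      while (a <= b && !bases_match(s[a], s[a - p])) ++a;
      while (b >= a && !bases_match(s[b], s[b - p])) --b;
      if (b < a) continue;
      int win = b - a + 1, m = 0;
      for (int q = a; q <= b; ++q) if (bases_match(s[q], s[q - p])) ++m;
      int score = m * match + (win - m) * mismatch;
      if (score < min_score) continue;
      if (win < p) continue;               // need >= 2 full copies
      // skip non-primitive periods: some q | p spans the window too
      bool primitive = true;
      for (int q = 1; q < p && primitive; ++q) {
        if (p % q != 0) continue;
        bool all = true;
        for (int z = a; z <= b; ++z)
          if (!bases_match(s[z], s[z - q])) { all = false; break; }
        if (all) primitive = false;
      }
      if (!primitive) continue;
      for (int q = a; q <= b; ++q) used[q] = 1;
      startv.push_back(a - p);             // tract start (first copy)
      endv.push_back(b + 1);               // half-open tract end
      periodv.push_back(p);
      scorev.push_back(score);
      matchesv.push_back(m);
      i = b + 1;
    }
  }
  return DataFrame::create(_["start0"] = startv, _["end0"] = endv,
                           _["period"] = periodv, _["score"] = scorev,
                           _["matches"] = matchesv,
                           _["stringsAsFactors"] = false);
}
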