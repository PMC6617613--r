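// Exhaustive gapless alignment core for mappability scoring.
//
// Reads are matched to the genome allowing up to m mismatches (Hamming
// distance, no indels) on both strands.  The engine uses a pigeonhole seed
// index (any alignment with <= m mismatches contains an exact match of one of
// m+1 disjoint seeds) but is contractually exhaustive; the naive oracles at
// the bottom recompute every score by a direct full scan with no index and
// serve as the arbiter in tests.
//
// Conventions:
//  * coordinates are 0-based half-open;
//  * target windows containing N never match; focal windows containing N are
//    undefined (NA);
//  * a k-mer count is the number of exact (position, strand) placements
//    genome-wide, so the count table is closed under reverse complement;
//  * method 1 sums closed-table counts over the distinct library k-mers (or
//    fragment k-mers, paired) aligning at the focal start in forward
//    orientation; method 2 counts all placements of the focal read/pair.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N or anything else
  }
}

static inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_char(c);
  return r;
}

static std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.rbegin(), v.rend());
  for (auto& b : r) b = (b > 3) ? 4 : (uint8_t)(3 - b);
  return r;
}

struct GenomeCodes {
  std::vector<std::string> seqs;
  std::vector<std::vector<uint8_t>> codes;
  std::vector<std::vector<int>> ncum;  // prefix counts of non-ACGT, length len+1

  bool clean(int ci, long q, int k) const {
    return ncum[ci][q + k] - ncum[ci][q] == 0;
  }
};

static GenomeCodes encode_genome(const CharacterVector& chroms) {
  GenomeCodes g;
  g.seqs.reserve(chroms.size());
  for (R_xlen_t i = 0; i < chroms.size(); i++) {
    std::string s = as<std::string>(chroms[i]);
    std::vector<uint8_t> c(s.size());
    std::vector<int> n(s.size() + 1, 0);
    for (size_t j = 0; j < s.size(); j++) {
      c[j] = (uint8_t)base_code(s[j]);
      n[j + 1] = n[j] + (c[j] > 3 ? 1 : 0);
    }
    g.seqs.push_back(std::move(s));
    g.codes.push_back(std::move(c));
    g.ncum.push_back(std::move(n));
  }
  return g;
}

// ---------------------------------------------------------------------------
// Seed index: exact-match positions of s-mers, s = min(31, floor(r/(m+1))).
// Seed i sits at offset i*chunk within the read, i = 0..m, so any <=m-mismatch
// alignment leaves at least one seed exact.
// ---------------------------------------------------------------------------

struct SeedIndex {
  int s = 0, chunk = 0, nseeds = 0;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> tab;
};

static SeedIndex build_index(const GenomeCodes& g, int r, int m) {
  SeedIndex idx;
  idx.chunk = r / (m + 1);
  if (idx.chunk < 1) stop("read length must exceed the mismatch allowance");
  idx.s = std::min(31, idx.chunk);
  idx.nseeds = m + 1;
  for (size_t ci = 0; ci < g.codes.size(); ci++) {
    const auto& ch = g.codes[ci];
    long len = (long)ch.size();
    if (len < idx.s) continue;
    for (long q = 0; q + idx.s <= len; q++) {
      if (!g.clean((int)ci, q, idx.s)) continue;
      uint64_t key = 0;
      for (int j = 0; j < idx.s; j++) key = (key << 2) | ch[q + j];
      idx.tab[key].push_back({(int)ci, (int)q});
    }
  }
  return idx;
}

// Forward-strand placements of `read` (codes, N-free) with <= m mismatches.
static void fwd_placements(const GenomeCodes& g, const SeedIndex& idx,
                           const std::vector<uint8_t>& read, int m,
                           std::vector<std::pair<int, int>>& out) {
  const int r = (int)read.size();
  std::unordered_set<uint64_t> seen;
  for (int i = 0; i < idx.nseeds; i++) {
    const int off = i * idx.chunk;
    uint64_t key = 0;
    bool ok = true;
    for (int j = 0; j < idx.s; j++) {
      uint8_t b = read[off + j];
      if (b > 3) { ok = false; break; }
      key = (key << 2) | b;
    }
    if (!ok) continue;
    auto it = idx.tab.find(key);
    if (it == idx.tab.end()) continue;
    for (const auto& pr : it->second) {
      const int ci = pr.first;
      const long q = (long)pr.second - off;
      if (q < 0) continue;
      const auto& ch = g.codes[ci];
      if (q + r > (long)ch.size()) continue;
      uint64_t k2 = ((uint64_t)ci << 40) | (uint64_t)q;
      if (!seen.insert(k2).second) continue;
      int mm = 0;
      bool good = true;
      for (int t = 0; t < r; t++) {
        uint8_t b = ch[q + t];
        if (b > 3) { good = false; break; }
        if (b != read[t] && ++mm > m) { good = false; break; }
      }
      if (good) out.push_back({ci, (int)q});
    }
  }
}

static std::vector<uint8_t> encode_read(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); i++) v[i] = (uint8_t)base_code(s[i]);
  return v;
}

static bool read_has_n(const std::vector<uint8_t>& v) {
  for (uint8_t b : v) if (b > 3) return true;
  return false;
}

// ---------------------------------------------------------------------------
// Exact k-mer counting (two-strand placement counts)
// ---------------------------------------------------------------------------

static std::unordered_map<std::string, double>
fwd_kmer_map(const GenomeCodes& g, int k) {
  std::unordered_map<std::string, double> fwd;
  for (size_t ci = 0; ci < g.codes.size(); ci++) {
    long len = (long)g.codes[ci].size();
    for (long q = 0; q + k <= len; q++) {
      if (!g.clean((int)ci, q, k)) continue;
      fwd[g.seqs[ci].substr(q, k)] += 1.0;
    }
  }
  return fwd;
}

static std::unordered_map<std::string, double>
closed_kmer_map(const GenomeCodes& g, int k) {
  auto fwd = fwd_kmer_map(g, k);
  std::unordered_map<std::string, double> res;
  for (const auto& kv : fwd) {
    res[kv.first] += kv.second;
    res[revcomp_str(kv.first)] += kv.second;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector chroms, int k) {
  GenomeCodes g = encode_genome(chroms);
  auto res = closed_kmer_map(g, k);
  std::vector<std::string> keys;
  keys.reserve(res.size());
  for (const auto& kv : res) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kn(keys.size());
  NumericVector kc(keys.size());
  for (size_t i = 0; i < keys.size(); i++) {
    kn[i] = keys[i];
    kc[i] = res[keys[i]];
  }
  return List::create(_["kmer"] = kn, _["count"] = kc);
}

// ---------------------------------------------------------------------------
// Single-end alignment and tracks
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_align_se(std::string read, CharacterVector chroms, int m) {
  GenomeCodes g = encode_genome(chroms);
  auto rd = encode_read(read);
  if (read_has_n(rd)) stop("read contains non-ACGT characters");
  SeedIndex idx = build_index(g, (int)rd.size(), m);
  std::vector<std::pair<int, int>> plus, minus;
  fwd_placements(g, idx, rd, m, plus);
  auto rc = revcomp_codes(rd);
  fwd_placements(g, idx, rc, m, minus);
  int n = (int)(plus.size() + minus.size());
  IntegerVector ci(n), pos(n);
  CharacterVector strand(n);
  int j = 0;
  for (const auto& p : plus) { ci[j] = p.first; pos[j] = p.second; strand[j] = "+"; j++; }
  for (const auto& p : minus) { ci[j] = p.first; pos[j] = p.second; strand[j] = "-"; j++; }
  return DataFrame::create(_["chrom_idx"] = ci, _["pos"] = pos, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

static std::unordered_map<std::string, double>
map_from_vectors(const CharacterVector& kn, const NumericVector& kv) {
  std::unordered_map<std::string, double> tab;
  tab.reserve(kn.size() * 2);
  for (R_xlen_t i = 0; i < kn.size(); i++) tab[as<std::string>(kn[i])] = kv[i];
  return tab;
}

// [[Rcpp::export]]
List cpp_track_se(CharacterVector chroms, int r, int m, int method,
                  CharacterVector kmer_names, NumericVector kmer_counts) {
  GenomeCodes g = encode_genome(chroms);
  SeedIndex idx = build_index(g, r, m);
  std::unordered_map<std::string, double> counts;
  if (method == 1) counts = map_from_vectors(kmer_names, kmer_counts);

  List out(chroms.size());
  std::vector<std::pair<int, int>> plus, minus;
  for (size_t ci = 0; ci < g.codes.size(); ci++) {
    long len = (long)g.codes[ci].size();
    NumericVector sc(len, NA_REAL);
    std::vector<uint8_t> read(r);
    for (long p = 0; p + r <= len; p++) {
      if (!g.clean((int)ci, p, r)) continue;
      for (int t = 0; t < r; t++) read[t] = g.codes[ci][p + t];
      plus.clear(); minus.clear();
      fwd_placements(g, idx, read, m, plus);
      auto rc = revcomp_codes(read);
      fwd_placements(g, idx, rc, m, minus);
      if (method == 2) {
        sc[p] = 1.0 / (double)(plus.size() + minus.size());
      } else {
        // distinct library k-mers aligning at p in forward orientation; each
        // placement of the focal read exposes one such k-mer
        std::unordered_set<std::string> kset;
        for (const auto& pl : plus) kset.insert(g.seqs[pl.first].substr(pl.second, r));
        for (const auto& pl : minus) kset.insert(revcomp_str(g.seqs[pl.first].substr(pl.second, r)));
        double tot = 0.0;
        for (const auto& w : kset) {
          auto it = counts.find(w);
          if (it == counts.end()) stop("k-mer count table does not cover the genome");
          tot += it->second;
        }
        sc[p] = 1.0 / tot;
      }
    }
    out[ci] = sc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Paired-end alignment and tracks
// ---------------------------------------------------------------------------

// Count / enumerate forward-orientation joins: read1 at s1, mate-forward
// sequence at s2 on the same chromosome with insert_min <= s2+r-s1 <= insert_max.
static void join_pairs(const std::vector<std::pair<int, int>>& A,
                       const std::vector<std::pair<int, int>>& B, int r,
                       int imin, int imax,
                       std::vector<std::pair<int, int>>* out_s1s2, long* count) {
  for (const auto& a : A) {
    for (const auto& b : B) {
      if (a.first != b.first) continue;
      long frag = (long)b.second + r - a.second;
      if (frag < imin || frag > imax) continue;
      if (count) (*count)++;
      if (out_s1s2) out_s1s2->push_back({a.second, b.second});
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_align_pe(std::string read1, std::string read2,
                       CharacterVector chroms, int m, int imin, int imax) {
  GenomeCodes g = encode_genome(chroms);
  auto r1 = encode_read(read1);
  auto r2 = encode_read(read2);
  if (read_has_n(r1) || read_has_n(r2)) stop("reads contain non-ACGT characters");
  if (r1.size() != r2.size()) stop("mates must have equal length");
  int r = (int)r1.size();
  SeedIndex idx = build_index(g, r, m);
  auto mateF = revcomp_codes(r2);  // forward-strand sequence the mate matches
  std::vector<std::pair<int, int>> F1, F2, R1, R2;
  fwd_placements(g, idx, r1, m, F1);
  fwd_placements(g, idx, mateF, m, F2);
  auto r1rc = revcomp_codes(r1);
  fwd_placements(g, idx, r1rc, m, R1);
  fwd_placements(g, idx, r2, m, R2);  // read2 matches forward on the - orientation

  std::vector<int> ci, s1, s2, frag;
  std::vector<std::string> strand;
  for (const auto& a : F1)
    for (const auto& b : F2) {
      if (a.first != b.first) continue;
      long f = (long)b.second + r - a.second;
      if (f < imin || f > imax) continue;
      ci.push_back(a.first); s1.push_back(a.second); s2.push_back(b.second);
      frag.push_back((int)f); strand.push_back("+");
    }
  for (const auto& a : R2)      // leftmost: read2 forward match
    for (const auto& b : R1) {  // mate: rc(read1) match
      if (a.first != b.first) continue;
      long f = (long)b.second + r - a.second;
      if (f < imin || f > imax) continue;
      ci.push_back(a.first); s1.push_back(a.second); s2.push_back(b.second);
      frag.push_back((int)f); strand.push_back("-");
    }
  return DataFrame::create(_["chrom_idx"] = wrap(ci), _["s1"] = wrap(s1),
                           _["s2"] = wrap(s2), _["fragment_len"] = wrap(frag),
                           _["strand"] = wrap(strand), _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_track_pe(CharacterVector chroms, int r, int L, int m, int imin,
                  int imax, int method, CharacterVector kmer_names,
                  NumericVector kmer_counts) {
  GenomeCodes g = encode_genome(chroms);
  SeedIndex idx = build_index(g, r, m);
  List out(chroms.size());

  if (method == 2) {
    std::vector<std::pair<int, int>> F1, F2, R1, R2;
    for (size_t ci = 0; ci < g.codes.size(); ci++) {
      long len = (long)g.codes[ci].size();
      NumericVector sc(len, NA_REAL);
      std::vector<uint8_t> read1(r), mateF(r);
      for (long p = 0; p + L <= len; p++) {
        if (!g.clean((int)ci, p, L)) continue;
        for (int t = 0; t < r; t++) read1[t] = g.codes[ci][p + t];
        for (int t = 0; t < r; t++) mateF[t] = g.codes[ci][p + L - r + t];
        F1.clear(); F2.clear(); R1.clear(); R2.clear();
        fwd_placements(g, idx, read1, m, F1);
        fwd_placements(g, idx, mateF, m, F2);
        auto r1rc = revcomp_codes(read1);
        auto mFrc = revcomp_codes(mateF);
        fwd_placements(g, idx, r1rc, m, R1);
        fwd_placements(g, idx, mFrc, m, R2);
        long n = 0;
        join_pairs(F1, F2, r, imin, imax, nullptr, &n);  // + orientation
        join_pairs(R2, R1, r, imin, imax, nullptr, &n);  // - orientation
        sc[p] = 1.0 / (double)n;
      }
      out[ci] = sc;
    }
    return out;
  }

  // method 1: accumulate fragment-count contributions over forward-orientation
  // alignments of every library pair (the table is rc-closed, so reverse
  // orientation is covered by the reverse-complement fragment's entry)
  std::vector<std::vector<double>> acc(g.codes.size());
  for (size_t ci = 0; ci < g.codes.size(); ci++)
    acc[ci].assign(g.codes[ci].size(), 0.0);
  std::vector<std::pair<int, int>> F1, F2;
  for (R_xlen_t i = 0; i < kmer_names.size(); i++) {
    std::string w = as<std::string>(kmer_names[i]);
    if ((int)w.size() != L) stop("fragment count table k does not match L");
    double c = kmer_counts[i];
    auto read1 = encode_read(w.substr(0, r));
    auto mateF = encode_read(w.substr(L - r, r));
    F1.clear(); F2.clear();
    fwd_placements(g, idx, read1, m, F1);
    if (F1.empty()) continue;
    fwd_placements(g, idx, mateF, m, F2);
    for (const auto& a : F1)
      for (const auto& b : F2) {
        if (a.first != b.first) continue;
        long f = (long)b.second + r - a.second;
        if (f < imin || f > imax) continue;
        acc[a.first][a.second] += c;
      }
  }
  for (size_t ci = 0; ci < g.codes.size(); ci++) {
    long len = (long)g.codes[ci].size();
    NumericVector sc(len, NA_REAL);
    for (long p = 0; p + L <= len; p++) {
      if (!g.clean((int)ci, p, L)) continue;
      if (acc[ci][p] <= 0.0) stop("fragment count table does not cover the genome");
      sc[p] = 1.0 / acc[ci][p];
    }
    out[ci] = sc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Naive oracles: direct full scans, no index, no shortcuts.  Used in tests as
// the independent arbiter of the engine above.
// ---------------------------------------------------------------------------

// mismatches of `pat` against chrom sequence at q, or -1 if the window falls
// off the end or touches a non-ACGT base
static int naive_mismatches(const std::string& chrom, long q,
                            const std::string& pat, int cap) {
  if (q < 0 || q + (long)pat.size() > (long)chrom.size()) return -1;
  int mm = 0;
  for (size_t t = 0; t < pat.size(); t++) {
    char c = chrom[q + t];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return -1;
    if (c != pat[t] && ++mm > cap) return mm;
  }
  return mm;
}

// [[Rcpp::export]]
double cpp_oracle_se(CharacterVector chroms, int ci, int p, int r, int m,
                     int method) {
  GenomeCodes g = encode_genome(chroms);
  if (p < 0 || p + r > (long)g.codes[ci].size() || !g.clean(ci, p, r))
    return NA_REAL;
  std::string focal = g.seqs[ci].substr(p, r);
  if (method == 2) {
    std::string focal_rc = revcomp_str(focal);
    long n = 0;
    for (size_t cj = 0; cj < g.seqs.size(); cj++) {
      long len = (long)g.seqs[cj].size();
      for (long q = 0; q + r <= len; q++) {
        int a = naive_mismatches(g.seqs[cj], q, focal, m);
        if (a >= 0 && a <= m) n++;
        int b = naive_mismatches(g.seqs[cj], q, focal_rc, m);
        if (b >= 0 && b <= m) n++;  // (q,-): revcomp(focal) matches forward
      }
    }
    return 1.0 / (double)n;
  }
  // method 1: scan the whole closed k-mer library for members of the
  // mismatch neighborhood of the focal k-mer; sum their exact counts
  auto lib = closed_kmer_map(g, r);
  double tot = 0.0;
  for (const auto& kv : lib) {
    int mm = 0;
    bool ok = true;
    for (int t = 0; t < r; t++)
      if (kv.first[t] != focal[t] && ++mm > m) { ok = false; break; }
    if (ok) tot += kv.second;
  }
  return 1.0 / tot;
}

// [[Rcpp::export]]
double cpp_oracle_pe(CharacterVector chroms, int ci, int p, int r, int L,
                     int m, int imin, int imax, int method) {
  GenomeCodes g = encode_genome(chroms);
  if (p < 0 || p + L > (long)g.codes[ci].size() || !g.clean(ci, p, L))
    return NA_REAL;
  std::string read1 = g.seqs[ci].substr(p, r);
  std::string mateF = g.seqs[ci].substr(p + L - r, r);
  if (method == 2) {
    std::string r1rc = revcomp_str(read1);
    std::string mFrc = revcomp_str(mateF);
    long n = 0;
    for (size_t cj = 0; cj < g.seqs.size(); cj++) {
      long len = (long)g.seqs[cj].size();
      for (long s1 = 0; s1 + r <= len; s1++) {
        int a = naive_mismatches(g.seqs[cj], s1, read1, m);
        if (a >= 0 && a <= m) {  // + orientation anchored at s1
          for (int f = imin; f <= imax; f++) {
            long s2 = s1 + f - r;
            int b = naive_mismatches(g.seqs[cj], s2, mateF, m);
            if (b >= 0 && b <= m) n++;
          }
        }
        int c = naive_mismatches(g.seqs[cj], s1, mFrc, m);
        if (c >= 0 && c <= m) {  // - orientation, leftmost = read2 match
          for (int f = imin; f <= imax; f++) {
            long t1 = s1 + f - r;
            int d = naive_mismatches(g.seqs[cj], t1, r1rc, m);
            if (d >= 0 && d <= m) n++;
          }
        }
      }
    }
    return 1.0 / (double)n;
  }
  // method 1: every library fragment, forward-orientation alignments with
  // leftmost start exactly at (ci, p)
  auto lib = closed_kmer_map(g, L);
  double tot = 0.0;
  for (const auto& kv : lib) {
    const std::string& w = kv.first;
    int mm = 0;
    bool ok = true;
    for (int t = 0; t < r; t++)
      if (w[t] != read1[t] && ++mm > m) { ok = false; break; }
    if (!ok) continue;
    std::string wmate = w.substr(L - r, r);
    for (int f = imin; f <= imax; f++) {
      long s2 = (long)p + f - r;
      int b = naive_mismatches(g.seqs[ci], s2, wmate, m);
      if (b >= 0 && b <= m) tot += kv.second;
    }
  }
  return 1.0 / tot;
}
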