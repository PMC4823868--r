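// Core alignment machinery: exact k-mer seed index over the forward
// genome, contiguous read verification, anchor lookup, breakpoint
// resolution for linear and back-spliced (head-to-tail) junctions, and a
// local-alignment scorer for inverted-repeat detection.
//
// Strand convention: a minus-strand hit for query q at forward position p
// means revcomp(q) occurs at p on the forward sequence. Junction fields
// acceptor_start/donor_end are geometric forward-strand boundaries; a
// junction on '+' requires GT immediately after donor_end and AG
// immediately before acceptor_start, a junction on '-' requires CT and AC
// at the same positions (the reverse complement read through the minus
// strand).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_char(c);
  return r;
}

struct SeedIndex {
  int k;
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  std::unordered_map<uint64_t, std::vector<uint64_t>> table; // kmer -> chrom<<32 | pos
};

// Encode a k-mer; returns false if it contains a non-ACGT base.
static bool encode_kmer(const char* s, int k, uint64_t& code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

static uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ull - (code & 3ull));
    code >>= 2;
  }
  return rc;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  uint64_t mask = (k == 32) ? ~0ull : ((1ull << (2 * k)) - 1ull);
  for (int c = 0; c < seqs.size(); ++c) {
    std::string s = as<std::string>(seqs[c]);
    idx->names.push_back(as<std::string>(names[c]));
    if ((int)s.size() < k) {
      delete idx;
      stop("chromosome shorter than k");
    }
    uint64_t code = 0;
    int run = 0; // length of current valid-base run ending here
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        uint64_t pos = i + 1 - k;
        idx->table[code].push_back(((uint64_t)c << 32) | pos);
      }
    }
    idx->seqs.push_back(std::move(s));
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  IntegerVector lens(idx->seqs.size());
  CharacterVector nm(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) {
    lens[i] = (int)idx->seqs[i].size();
    nm[i] = idx->names[i];
  }
  return List::create(_["k"] = idx->k, _["chrom"] = nm, _["length"] = lens);
}

struct Hit { int chrom; int pos; char strand; };

static void lookup_hits(const SeedIndex& idx, const std::string& q,
                        std::vector<Hit>& out) {
  uint64_t code;
  if ((int)q.size() != idx.k) return;
  if (!encode_kmer(q.c_str(), idx.k, code)) return;
  auto it = idx.table.find(code);
  if (it != idx.table.end()) {
    for (uint64_t v : it->second)
      out.push_back(Hit{(int)(v >> 32), (int)(v & 0xffffffffull), '+'});
  }
  uint64_t rc = revcomp_code(code, idx.k);
  it = idx.table.find(rc);
  if (it != idx.table.end()) {
    for (uint64_t v : it->second)
      out.push_back(Hit{(int)(v >> 32), (int)(v & 0xffffffffull), '-'});
  }
  std::sort(out.begin(), out.end(), [](const Hit& a, const Hit& b) {
    if (a.chrom != b.chrom) return a.chrom < b.chrom;
    if (a.pos != b.pos) return a.pos < b.pos;
    return a.strand < b.strand; // '+' (43) before '-' (45)
  });
}

// [[Rcpp::export]]
DataFrame cpp_map_anchor(SEXP xp, std::string anchor) {
  XPtr<SeedIndex> idx(xp);
  std::vector<Hit> hits;
  lookup_hits(*idx, anchor, hits);
  IntegerVector chrom(hits.size()), pos(hits.size());
  CharacterVector strand(hits.size());
  for (size_t i = 0; i < hits.size(); ++i) {
    chrom[i] = hits[i].chrom + 1; // 1-based chrom index for R
    pos[i] = hits[i].pos;
    strand[i] = std::string(1, hits[i].strand);
  }
  return DataFrame::create(_["chrom_idx"] = chrom, _["pos"] = pos,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Count mismatches of s (whole string) aligned at genome position pos;
// returns max_allow+1 early when exceeded or out of bounds.
static int count_mismatches(const std::string& g, const std::string& s,
                            long pos, int max_allow) {
  if (pos < 0 || pos + (long)s.size() > (long)g.size()) return max_allow + 1;
  int mm = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    if (g[pos + i] != s[i] && ++mm > max_allow) return mm;
  }
  return mm;
}

struct ContigHit { int chrom; int pos; char strand; int mm; };

static bool contig_better(const ContigHit& a, const ContigHit& b) {
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.chrom != b.chrom) return a.chrom < b.chrom;
  if (a.pos != b.pos) return a.pos < b.pos;
  return a.strand < b.strand;
}

// Contiguous placement of one read: seed with the first k-mer (last k-mer
// as fallback), on both strands; full-length verification with at most
// max_mismatch substitutions; deterministic best-hit selection.
static bool map_contig_one(const SeedIndex& idx, const std::string& read,
                           int max_mismatch, ContigHit& best) {
  int k = idx.k;
  int L = (int)read.size();
  if (L < k) return false;
  std::string rc = revcomp_str(read);
  bool found = false;
  const std::string* oriented[2] = {&read, &rc};
  const char strands[2] = {'+', '-'};
  for (int si = 0; si < 2; ++si) {
    const std::string& o = *oriented[si];
    for (int seed = 0; seed < 2; ++seed) {
      long off = (seed == 0) ? 0 : (long)(L - k);
      std::vector<Hit> hits;
      lookup_hits(idx, o.substr(off, k), hits);
      for (const Hit& h : hits) {
        if (h.strand != '+') continue; // oriented string vs forward genome
        long pos = (long)h.pos - off;
        int mm = count_mismatches(idx.seqs[h.chrom], o, pos, max_mismatch);
        if (mm <= max_mismatch) {
          ContigHit cand{h.chrom, (int)pos, strands[si], mm};
          if (!found || contig_better(cand, best)) { best = cand; found = true; }
        }
      }
    }
  }
  return found;
}

// [[Rcpp::export]]
DataFrame cpp_map_contiguous(SEXP xp, CharacterVector reads, int max_mismatch) {
  XPtr<SeedIndex> idx(xp);
  int n = reads.size();
  IntegerVector chrom(n, NA_INTEGER), pos(n, NA_INTEGER), mm(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING);
  for (int i = 0; i < n; ++i) {
    ContigHit best;
    if (map_contig_one(*idx, as<std::string>(reads[i]), max_mismatch, best)) {
      chrom[i] = best.chrom + 1;
      pos[i] = best.pos;
      strand[i] = std::string(1, best.strand);
      mm[i] = best.mm;
    }
  }
  return DataFrame::create(_["chrom_idx"] = chrom, _["pos"] = pos,
                           _["strand"] = strand, _["n_mismatches"] = mm,
                           _["stringsAsFactors"] = false);
}

// A resolved split of one read across a junction.
struct SplitCall {
  int mm;        // total mismatches of the two placements
  int jtype;     // 1 linear, 2 backsplice
  int centr;     // |2s - L|, distance of split from read midpoint
  int acceptor;  // acceptor_start (geometric)
  int donor;     // donor_end (geometric, exclusive)
  int chrom;
  char strand;
  int split;
};

static bool split_better(const SplitCall& a, const SplitCall& b) {
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.jtype != b.jtype) return a.jtype < b.jtype; // linear preferred on tie
  if (a.centr != b.centr) return a.centr < b.centr;
  if (a.acceptor != b.acceptor) return a.acceptor < b.acceptor;
  if (a.donor != b.donor) return a.donor < b.donor;
  if (a.chrom != b.chrom) return a.chrom < b.chrom;
  return a.strand < b.strand;
}

static inline bool splice_ok(const std::string& g, long donor_end,
                             long acceptor_start, char strand) {
  if (donor_end + 2 > (long)g.size() || acceptor_start - 2 < 0) return false;
  if (strand == '+') {
    return g[donor_end] == 'G' && g[donor_end + 1] == 'T' &&
           g[acceptor_start - 2] == 'A' && g[acceptor_start - 1] == 'G';
  }
  return g[donor_end] == 'C' && g[donor_end + 1] == 'T' &&
         g[acceptor_start - 2] == 'A' && g[acceptor_start - 1] == 'C';
}

static const int MIN_INTRON = 4; // room for GT..AG

// Enumerate split positions for one oriented read whose first anchor sits
// at p_left and whose last anchor sits at p_right on chromosome chrom.
// The junction's strand is decided by which splice motif flanks the
// breakpoints (GT..AG forward -> '+', CT..AC forward -> '-'); the read's
// own orientation only selects which of read/revcomp(read) aligns
// forward, since the library contains both orientations.
static void resolve_pair(const SeedIndex& idx, const std::string& oriented,
                         int chrom, long p_left, long p_right,
                         int anchor_len, int max_mismatch,
                         std::vector<SplitCall>& out) {
  const std::string& g = idx.seqs[chrom];
  int L = (int)oriented.size();
  if (L < 2 * anchor_len) return;

  // Cumulative mismatches of the left extension beyond its anchor.
  // pref_mm[s] = mismatches of oriented[0:s] at p_left (anchor exact).
  std::vector<int> pref_mm(L + 1, 0);
  for (int i = anchor_len; i < L; ++i) {
    long gp = p_left + i;
    int add = (gp >= (long)g.size() || g[gp] != oriented[i]) ? 1 : 0;
    pref_mm[i + 1] = pref_mm[i] + add;
  }
  // suff_mm[s] = mismatches of oriented[s:L] ending at p_right + anchor_len.
  std::vector<int> suff_mm(L + 1, 0);
  long suff_end = p_right + anchor_len; // exclusive genome end of suffix
  for (int i = L - anchor_len - 1; i >= 0; --i) {
    long gp = suff_end - (L - i);
    int add = (gp < 0 || gp >= (long)g.size() || g[gp] != oriented[i]) ? 1 : 0;
    suff_mm[i] = suff_mm[i + 1] + add;
  }
  for (int s = anchor_len; s <= L - anchor_len; ++s) {
    long b1 = p_left + s;              // prefix end (donor_end)
    long b2 = suff_end - (L - s);      // suffix start (acceptor_start)
    if (b1 > (long)g.size() || b2 < 0) continue;
    int mm = pref_mm[s] + suff_mm[s];
    if (mm > max_mismatch) continue;
    int jtype;
    if (b2 - b1 >= MIN_INTRON) jtype = 1;        // forward order: linear
    else if (b1 - b2 >= 1) jtype = 2;            // head-to-tail: backsplice
    else continue;                               // contiguous/degenerate
    char strand;
    if (splice_ok(g, b1, b2, '+')) strand = '+';
    else if (splice_ok(g, b1, b2, '-')) strand = '-';
    else continue;
    out.push_back(SplitCall{mm, jtype, std::abs(2 * s - L), (int)b2, (int)b1,
                            chrom, strand, s});
  }
}

// [[Rcpp::export]]
DataFrame cpp_resolve_breakpoint(SEXP xp, std::string read,
                                 int left_chrom, int left_pos,
                                 int right_chrom, int right_pos,
                                 std::string strand,
                                 int anchor_len, int max_mismatch,
                                 bool all_candidates) {
  XPtr<SeedIndex> idx(xp);
  std::vector<SplitCall> cands;
  char st = strand[0];
  if (left_chrom == right_chrom) {
    if (st == '+') {
      resolve_pair(*idx, read, left_chrom - 1, left_pos, right_pos,
                   anchor_len, max_mismatch, cands);
    } else {
      // minus-strand hits: orient the read by reverse complement; the
      // original right anchor becomes the leading anchor.
      resolve_pair(*idx, revcomp_str(read), left_chrom - 1, right_pos,
                   left_pos, anchor_len, max_mismatch, cands);
    }
  }
  std::sort(cands.begin(), cands.end(), split_better);
  if (!all_candidates && cands.size() > 1) cands.resize(1);
  int n = (int)cands.size();
  IntegerVector chrom(n), acc(n), don(n), mm(n), split(n);
  CharacterVector str(n), jt(n);
  for (int i = 0; i < n; ++i) {
    chrom[i] = cands[i].chrom + 1;
    acc[i] = cands[i].acceptor;
    don[i] = cands[i].donor;
    mm[i] = cands[i].mm;
    split[i] = cands[i].split;
    str[i] = std::string(1, cands[i].strand);
    jt[i] = cands[i].jtype == 1 ? "linear" : "backsplice";
  }
  return DataFrame::create(_["chrom_idx"] = chrom, _["strand"] = str,
                           _["acceptor_start"] = acc, _["donor_end"] = don,
                           _["jtype"] = jt, _["n_mismatches"] = mm,
                           _["split"] = split,
                           _["stringsAsFactors"] = false);
}

// Full per-read pipeline over a read set. Status codes:
// 0 contiguous, 1 linear junction, 2 backsplice junction, 3 unmapped,
// 4 skipped (short read or anchor with too many hits).
// [[Rcpp::export]]
List cpp_call_reads(SEXP xp, CharacterVector reads, int anchor_len,
                    int max_mismatch, double max_span, int max_anchor_hits) {
  XPtr<SeedIndex> idx(xp);
  int n = reads.size();
  IntegerVector status(n), chrom(n, NA_INTEGER), acc(n, NA_INTEGER),
      don(n, NA_INTEGER), mm(n, NA_INTEGER), pos(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING), jtype(n, NA_STRING);

  for (int i = 0; i < n; ++i) {
    std::string read = as<std::string>(reads[i]);
    int L = (int)read.size();
    ContigHit ch;
    if (map_contig_one(*idx, read, max_mismatch, ch)) {
      status[i] = 0;
      chrom[i] = ch.chrom + 1;
      pos[i] = ch.pos;
      strand[i] = std::string(1, ch.strand);
      mm[i] = ch.mm;
      continue;
    }
    if (L < 2 * anchor_len) { status[i] = 4; continue; }
    std::vector<Hit> hl, hr;
    lookup_hits(*idx, read.substr(0, anchor_len), hl);
    lookup_hits(*idx, read.substr(L - anchor_len, anchor_len), hr);
    if ((int)hl.size() > max_anchor_hits || (int)hr.size() > max_anchor_hits) {
      status[i] = 4;
      continue;
    }
    std::vector<SplitCall> cands;
    std::string oriented_rc; // computed lazily
    for (const Hit& a : hl) {
      for (const Hit& b : hr) {
        if (a.chrom != b.chrom || a.strand != b.strand) continue;
        if (std::abs((double)a.pos - (double)b.pos) > max_span) continue;
        if (a.strand == '+') {
          resolve_pair(*idx, read, a.chrom, a.pos, b.pos,
                       anchor_len, max_mismatch, cands);
        } else {
          if (oriented_rc.empty()) oriented_rc = revcomp_str(read);
          // oriented read leads with revcomp of the original right anchor
          resolve_pair(*idx, oriented_rc, a.chrom, b.pos, a.pos,
                       anchor_len, max_mismatch, cands);
        }
      }
    }
    if (cands.empty()) { status[i] = 3; continue; }
    const SplitCall& best = *std::min_element(cands.begin(), cands.end(),
                                              split_better);
    status[i] = best.jtype; // 1 linear, 2 backsplice
    chrom[i] = best.chrom + 1;
    acc[i] = best.acceptor;
    don[i] = best.donor;
    mm[i] = best.mm;
    strand[i] = std::string(1, best.strand);
    jtype[i] = best.jtype == 1 ? "linear" : "backsplice";
  }
  return List::create(_["status"] = status, _["chrom_idx"] = chrom,
                      _["strand"] = strand, _["acceptor_start"] = acc,
                      _["donor_end"] = don, _["n_mismatches"] = mm,
                      _["pos"] = pos, _["jtype"] = jtype);
}

// Smith-Waterman local alignment with linear gap penalty and full
// traceback. Tie-break among equal maximal scores: the alignment whose
// pattern start is smallest, then whose subject start is smallest
// (resolved by tracing back from every maximal cell; maximal cells are
// rare at these scores). Returns 0-based half-open segment coordinates.
// [[Rcpp::export]]
List cpp_smith_waterman(std::string a, std::string b, double match,
                        double mismatch, double gap) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0); // 0 stop,1 diag,2 up,3 left
  double best = 0.0;
  std::vector<std::pair<int,int>> best_cells;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + ((a[i - 1] == b[j - 1]) ? match : mismatch);
      double sup = prev[j] + gap;
      double sleft = cur[j - 1] + gap;
      double v = sdiag; unsigned char d = 1;
      if (sup > v) { v = sup; d = 2; }
      if (sleft > v) { v = sleft; d = 3; }
      if (v <= 0.0) { v = 0.0; d = 0; }
      cur[j] = v;
      tb[(size_t)i * (m + 1) + j] = d;
      if (v > best + 1e-9) {
        best = v;
        best_cells.clear();
        best_cells.push_back({i, j});
      } else if (v > 0.0 && std::abs(v - best) <= 1e-9 &&
                 best_cells.size() < 64) {
        best_cells.push_back({i, j});
      }
    }
    std::swap(prev, cur);
  }
  if (best <= 0.0 || best_cells.empty()) {
    return List::create(_["score"] = 0.0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["length"] = 0L,
                        _["n_matches"] = 0L, _["identity"] = NA_REAL,
                        _["a_aligned"] = "", _["b_aligned"] = "");
  }
  // trace back each maximal cell; keep the spec's preferred start.
  int bi = -1, bj = -1, bsi = -1, bsj = -1, bcols = 0, bmatch = 0;
  std::string ba, bb;
  for (auto& cell : best_cells) {
    int i = cell.first, j = cell.second;
    int cols = 0, nmatch = 0;
    std::string aa, ab;
    int ci = i, cj = j;
    while (ci > 0 && cj > 0) {
      unsigned char d = tb[(size_t)ci * (m + 1) + cj];
      if (d == 0) break;
      if (d == 1) {
        aa.push_back(a[ci - 1]); ab.push_back(b[cj - 1]);
        if (a[ci - 1] == b[cj - 1]) ++nmatch;
        --ci; --cj;
      } else if (d == 2) {
        aa.push_back(a[ci - 1]); ab.push_back('-'); --ci;
      } else {
        aa.push_back('-'); ab.push_back(b[cj - 1]); --cj;
      }
      ++cols;
    }
    bool take = (bi < 0) || (ci < bsi) || (ci == bsi && cj < bsj);
    if (take) {
      bi = i; bj = j; bsi = ci; bsj = cj; bcols = cols; bmatch = nmatch;
      std::reverse(aa.begin(), aa.end());
      std::reverse(ab.begin(), ab.end());
      ba = aa; bb = ab;
    }
  }
  return List::create(_["score"] = best, _["a_start"] = bsi, _["a_end"] = bi,
                      _["b_start"] = bsj, _["b_end"] = bj,
                      _["length"] = bcols, _["n_matches"] = bmatch,
                      _["identity"] = (double)bmatch / (double)bcols,
                      _["a_aligned"] = ba, _["b_aligned"] = bb);
}
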