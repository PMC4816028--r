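#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <cmath>
#include <cfenv>
#include <string>
#include <vector>

using namespace Rcpp;

// Concatenated-genome conventions shared with the R layer:
//  - chromosomes are joined with a single sentinel '$' after each one;
//  - '$' (ASCII 36) sorts below every nucleotide, so the byte order of
//    suffixes is $ < A < C < G < N < T;
//  - all coordinates on this side are 0-based, half-open. The R wrappers
//    convert to 1-based inclusive coordinates.
static const char SENT = '$';

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline int bcode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  default:  return 3;
  }
}

static inline char rc_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = rc_base(r[i]);
  return r;
}

// ---------------------------------------------------------------- suffix array

// [[Rcpp::export]]
IntegerVector cpp_build_sa(const std::string& seq) {
  const int n = (int) seq.size();
  std::vector<int> pos;
  pos.reserve(n);
  for (int i = 0; i < n; ++i)
    if (seq[i] != SENT) pos.push_back(i);
  const char* s = seq.c_str();
  // comparator relies on the NUL terminator: a proper-prefix suffix sorts
  // first, matching the sentinel-smallest convention
  std::sort(pos.begin(), pos.end(), [s](int a, int b) {
    return std::strcmp(s + a, s + b) < 0;
  });
  return IntegerVector(pos.begin(), pos.end());
}

// ---------------------------------------------------------------- prefix table

static bool encode_kmer(const std::string& s, size_t from, int k, double& out) {
  long long code = 0;
  if (from + (size_t) k > s.size()) return false;
  for (int j = 0; j < k; ++j) {
    char c = s[from + j];
    if (!is_base(c)) return false;
    code = (code << 2) | bcode(c);
  }
  out = (double) code;
  return true;
}

// Rank intervals are contiguous per k-mer because suffixes sharing their
// first k bases are lexicographic neighbours; suffixes that are shorter
// than k or contain N/sentinel in the first k bases fall between blocks.
// [[Rcpp::export]]
List cpp_build_ptable(const std::string& seq, IntegerVector sa, int k) {
  if (k < 1) stop("prefix length k must be >= 1");
  if (k > 26) stop("prefix length k must be <= 26");
  std::vector<double> keys;
  std::vector<int> lo, hi;
  const int n = sa.size();
  double cur = -1.0;
  bool have = false;
  for (int r = 0; r < n; ++r) {
    double code;
    if (!encode_kmer(seq, (size_t) sa[r], k, code)) { have = false; continue; }
    if (have && code == cur) {
      hi.back() = r + 1;
    } else {
      keys.push_back(code);
      lo.push_back(r);
      hi.push_back(r + 1);
      cur = code;
      have = true;
    }
  }
  return List::create(_["keys"] = NumericVector(keys.begin(), keys.end()),
                      _["lo"]   = IntegerVector(lo.begin(), lo.end()),
                      _["hi"]   = IntegerVector(hi.begin(), hi.end()));
}

// ---------------------------------------------------------------- SA search

// -1: suffix < pattern, 0: pattern is a prefix of suffix, 1: suffix > pattern.
// Both are known equal on [0, from).
static int suf_cmp(const std::string& seq, int pos, const std::string& pat,
                   int from) {
  const int n = (int) seq.size(), m = (int) pat.size();
  int i = pos + from, j = from;
  while (j < m) {
    if (i >= n) return -1;
    char a = seq[i], b = pat[j];
    if (a != b) return a < b ? -1 : 1;
    ++i; ++j;
  }
  return 0;
}

static void sa_bounds(const std::string& seq, const int* sa, int lo, int hi,
                      const std::string& pat, int from, int& out_lo,
                      int& out_hi) {
  int l = lo, h = hi;
  while (l < h) {
    int mid = l + (h - l) / 2;
    if (suf_cmp(seq, sa[mid], pat, from) < 0) l = mid + 1; else h = mid;
  }
  out_lo = l;
  h = hi;
  while (l < h) {
    int mid = l + (h - l) / 2;
    if (suf_cmp(seq, sa[mid], pat, from) <= 0) l = mid + 1; else h = mid;
  }
  out_hi = l;
}

struct IndexView {
  const std::string* seq;
  const int* sa;
  int n;
  const double* keys;
  const int* plo;
  const int* phi;
  int nkeys;
  int k;
};

// fills [lo, hi) of SA ranks whose suffixes start with pat; returns false
// when pat contains a non-ACGT character
static bool search_bounds(const IndexView& ix, const std::string& pat,
                          int& lo, int& hi) {
  lo = hi = 0;
  for (size_t i = 0; i < pat.size(); ++i)
    if (!is_base(pat[i])) return false;
  if (pat.empty()) return false;
  if ((int) pat.size() >= ix.k && ix.nkeys > 0) {
    double code = 0;
    long long c = 0;
    for (int j = 0; j < ix.k; ++j) c = (c << 2) | bcode(pat[j]);
    code = (double) c;
    const double* p = std::lower_bound(ix.keys, ix.keys + ix.nkeys, code);
    if (p == ix.keys + ix.nkeys || *p != code) return true; // no hits
    int e = (int) (p - ix.keys);
    if ((int) pat.size() == ix.k) { lo = ix.plo[e]; hi = ix.phi[e]; }
    else sa_bounds(*ix.seq, ix.sa, ix.plo[e], ix.phi[e], pat, ix.k, lo, hi);
  } else {
    sa_bounds(*ix.seq, ix.sa, 0, ix.n, pat, 0, lo, hi);
  }
  return true;
}

// [[Rcpp::export]]
IntegerVector cpp_sa_search(const std::string& seq, IntegerVector sa,
                            NumericVector keys, IntegerVector plo,
                            IntegerVector phi, int k,
                            const std::string& pattern, int max_hits) {
  IndexView ix = { &seq, sa.size() ? INTEGER(sa) : NULL, sa.size(),
                   keys.size() ? REAL(keys) : NULL,
                   plo.size() ? INTEGER(plo) : NULL,
                   phi.size() ? INTEGER(phi) : NULL,
                   keys.size(), k };
  int lo, hi;
  if (!search_bounds(ix, pattern, lo, hi)) return IntegerVector(0);
  int cnt = hi - lo;
  if (cnt <= 0) return IntegerVector(0);
  if (max_hits > 0 && cnt > max_hits) return IntegerVector(0);
  std::vector<int> out(cnt);
  for (int i = 0; i < cnt; ++i) out[i] = ix.sa[lo + i];
  std::sort(out.begin(), out.end());
  return IntegerVector(out.begin(), out.end());
}

// ---------------------------------------------------------------- seeds

static std::vector<int> seed_starts(int L, int s, int n) {
  std::vector<int> st;
  if (L <= s || n <= 1) { st.push_back(0); return st; }
  for (int i = 0; i < n; ++i) {
    double x = (double) i * (double) (L - s) / (double) (n - 1);
    st.push_back((int) std::nearbyint(x)); // round-half-to-even
  }
  st.erase(std::unique(st.begin(), st.end()), st.end());
  return st;
}

// [[Rcpp::export]]
IntegerMatrix cpp_generate_seeds(int read_len, int seed_len, int num_seeds) {
  int s = std::min(seed_len, read_len);
  std::vector<int> st = seed_starts(read_len, s, num_seeds);
  IntegerMatrix out((int) st.size(), 2);
  for (size_t i = 0; i < st.size(); ++i) {
    out(i, 0) = st[i];
    out(i, 1) = s;
  }
  return out;
}

// ---------------------------------------------------------------- extension

struct Ext {
  int rs, re, gs, ge, mm;   // half-open read span, half-open genome span
  int strand;               // 0 forward, 1 reverse
  int chrom;                // 0-based chromosome index
};

// Greedy bidirectional extension: alternately try one base left then one
// base right (left first), skipping exhausted directions. A direction is
// exhausted at a read/chromosome boundary or when accepting the next
// mismatching base would exceed the shared budget. N compares as mismatch.
static Ext extend_hit(const std::string& seq, const std::string& read,
                      int roff, int slen, int gpos, int cstart, int cend,
                      int max_mm) {
  Ext e;
  e.rs = roff; e.re = roff + slen;
  e.gs = gpos; e.ge = gpos + slen;
  e.mm = 0; e.strand = 0; e.chrom = 0;
  const int L = (int) read.size();
  bool left_open = true, right_open = true;
  while (left_open || right_open) {
    if (left_open) {
      if (e.rs == 0 || e.gs == cstart) {
        left_open = false;
      } else {
        char a = read[e.rs - 1], b = seq[e.gs - 1];
        bool mis = (a != b) || !is_base(a) || !is_base(b);
        if (mis && e.mm + 1 > max_mm) left_open = false;
        else { --e.rs; --e.gs; if (mis) ++e.mm; }
      }
    }
    if (right_open) {
      if (e.re == L || e.ge == cend) {
        right_open = false;
      } else {
        char a = read[e.re], b = seq[e.ge];
        bool mis = (a != b) || !is_base(a) || !is_base(b);
        if (mis && e.mm + 1 > max_mm) right_open = false;
        else { ++e.re; ++e.ge; if (mis) ++e.mm; }
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
IntegerVector cpp_extend_seed(const std::string& seq, const std::string& read,
                              int read_off0, int seed_len, int gpos0,
                              int chrom_start0, int chrom_end0, int max_mm) {
  Ext e = extend_hit(seq, read, read_off0, seed_len, gpos0, chrom_start0,
                     chrom_end0, max_mm);
  return IntegerVector::create(e.rs, e.re, e.gs, e.ge, e.mm);
}

// ---------------------------------------------------------------- clustering

struct Cal {
  int chrom, strand;
  int gs, ge;                 // envelope, half-open
  std::vector<int> members;   // indices into the extension vector
  int coverage;               // read bases covered by the union of members
  int mm_total;
};

static int union_coverage(const std::vector<Ext>& exts,
                          const std::vector<int>& idx) {
  std::vector<std::pair<int, int> > sp;
  sp.reserve(idx.size());
  for (size_t i = 0; i < idx.size(); ++i)
    sp.push_back(std::make_pair(exts[idx[i]].rs, exts[idx[i]].re));
  std::sort(sp.begin(), sp.end());
  int cov = 0, cs = -1, ce = -1;
  for (size_t i = 0; i < sp.size(); ++i) {
    if (cs < 0 || sp[i].first > ce) {
      if (cs >= 0) cov += ce - cs;
      cs = sp[i].first; ce = sp[i].second;
    } else if (sp[i].second > ce) {
      ce = sp[i].second;
    }
  }
  if (cs >= 0) cov += ce - cs;
  return cov;
}

// Extensions must already belong to one (chromosome, strand) group and be
// listed in the order they should be chained. Two consecutive extensions
// join the same CAL when the genomic distance between them is <= max_gap
// and their diagonals differ by <= max_gap.
static void cluster_group(const std::vector<Ext>& exts,
                          std::vector<int>& idx, int chrom, int strand,
                          int max_gap, int min_cal_len,
                          std::vector<Cal>& out) {
  std::sort(idx.begin(), idx.end(), [&exts](int a, int b) {
    if (exts[a].gs != exts[b].gs) return exts[a].gs < exts[b].gs;
    if (exts[a].rs != exts[b].rs) return exts[a].rs < exts[b].rs;
    return exts[a].ge < exts[b].ge;
  });
  std::vector<std::vector<int> > groups;
  for (size_t i = 0; i < idx.size(); ++i) {
    const Ext& e = exts[idx[i]];
    bool fresh = groups.empty();
    if (!fresh) {
      const Ext& p = exts[groups.back().back()];
      long dist = (long) e.gs - (long) p.ge;
      long ddia = std::labs(((long) e.gs - e.rs) - ((long) p.gs - p.rs));
      fresh = dist > max_gap || ddia > max_gap;
    }
    if (fresh) groups.push_back(std::vector<int>());
    groups.back().push_back(idx[i]);
  }
  for (size_t g = 0; g < groups.size(); ++g) {
    Cal c;
    c.chrom = chrom; c.strand = strand;
    c.gs = exts[groups[g][0]].gs;
    c.ge = 0;
    c.mm_total = 0;
    for (size_t i = 0; i < groups[g].size(); ++i) {
      const Ext& e = exts[groups[g][i]];
      c.gs = std::min(c.gs, e.gs);
      c.ge = std::max(c.ge, e.ge);
      c.mm_total += e.mm;
    }
    if (c.ge - c.gs < min_cal_len) continue;
    c.members = groups[g];
    c.coverage = union_coverage(exts, c.members);
    out.push_back(c);
  }
}

// Exported wrapper over the same clustering used by the batch mapper.
// ext matrix columns: rs, re, gs, ge, mm, strand (all 0-based half-open).
// [[Rcpp::export]]
List cpp_cluster_extensions(IntegerMatrix ext, IntegerVector chrom_starts0,
                            IntegerVector chrom_ends0, int max_gap,
                            int min_cal_len) {
  const int n = ext.nrow();
  std::vector<Ext> exts((size_t) n);
  const int nc = chrom_starts0.size();
  for (int i = 0; i < n; ++i) {
    Ext& e = exts[i];
    e.rs = ext(i, 0); e.re = ext(i, 1);
    e.gs = ext(i, 2); e.ge = ext(i, 3);
    e.mm = ext(i, 4); e.strand = ext(i, 5);
    e.chrom = 0;
    for (int c = nc - 1; c >= 0; --c)
      if (e.gs >= chrom_starts0[c]) { e.chrom = c; break; }
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&exts](int a, int b) {
    if (exts[a].strand != exts[b].strand) return exts[a].strand < exts[b].strand;
    return exts[a].chrom < exts[b].chrom;
  });
  std::vector<Cal> cals;
  size_t i = 0;
  while (i < order.size()) {
    size_t j = i;
    int ch = exts[order[i]].chrom, st = exts[order[i]].strand;
    while (j < order.size() && exts[order[j]].chrom == ch &&
           exts[order[j]].strand == st) ++j;
    std::vector<int> grp(order.begin() + i, order.begin() + j);
    cluster_group(exts, grp, ch, st, max_gap, min_cal_len, cals);
    i = j;
  }
  const int m = (int) cals.size();
  IntegerVector chrom(m), strand(m), gs(m), ge(m), cov(m), mm(m);
  List members(m);
  IntegerVector assign(n, 0);
  for (int c = 0; c < m; ++c) {
    chrom[c] = cals[c].chrom;
    strand[c] = cals[c].strand;
    gs[c] = cals[c].gs;
    ge[c] = cals[c].ge;
    cov[c] = cals[c].coverage;
    mm[c] = cals[c].mm_total;
    IntegerVector mb(cals[c].members.size());
    for (size_t t = 0; t < cals[c].members.size(); ++t) {
      mb[t] = cals[c].members[t] + 1; // 1-based row index for R
      assign[cals[c].members[t]] = c + 1;
    }
    members[c] = mb;
  }
  return List::create(_["chrom"] = chrom, _["strand"] = strand,
                      _["genome_start"] = gs, _["genome_end"] = ge,
                      _["coverage"] = cov, _["mismatches"] = mm,
                      _["members"] = members, _["assignment"] = assign);
}

// ---------------------------------------------------------------- affine DP

struct AlnRes {
  double score;
  std::vector<std::pair<char, int> > ops; // M/I/D over the segment
  int qbeg, qend, tbeg, tend;             // half-open aligned spans
};

static void push_op(std::vector<std::pair<char, int> >& ops, char op, int len) {
  if (len <= 0) return;
  if (!ops.empty() && ops.back().first == op) ops.back().second += len;
  else ops.push_back(std::make_pair(op, len));
}

static const double NEG = -1e18;

// mode 0: local (free start, free end)
// mode 1: global (both ends fixed)
// mode 2: extension (start fixed at (0,0), free end)
// Gap of length l costs gap_open + l * gap_extend.
// Traceback ties prefer diagonal, then deletion (D), then insertion (I);
// the end cell for free-end modes is the maximal cell with largest i,
// then largest j.
static AlnRes align_dp(const std::string& q, const std::string& t, int mode,
                       double ma, double mi, double go, double ge) {
  const int m = (int) q.size(), n = (int) t.size();
  const size_t W = (size_t) n + 1;
  std::vector<double> H((size_t) (m + 1) * W), E((size_t) (m + 1) * W),
      F((size_t) (m + 1) * W);
  const bool local = (mode == 0);
  H[0] = 0.0; E[0] = NEG; F[0] = NEG;
  for (int j = 1; j <= n; ++j) {
    size_t c = (size_t) j;
    if (local) { H[c] = 0.0; E[c] = NEG; }
    else { E[c] = -(go + ge * j); H[c] = E[c]; }
    F[c] = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    size_t r = (size_t) i * W;
    if (local) { H[r] = 0.0; F[r] = NEG; }
    else { F[r] = -(go + ge * i); H[r] = F[r]; }
    E[r] = NEG;
    for (int j = 1; j <= n; ++j) {
      size_t c = r + j, up = c - W, left = c - 1, diag = up - 1;
      double e = std::max(H[left] - go - ge, E[left] - ge);
      double f = std::max(H[up] - go - ge, F[up] - ge);
      char qa = q[i - 1], tb = t[j - 1];
      bool match = (qa == tb) && is_base(qa) && is_base(tb);
      double d = H[diag] + (match ? ma : -mi);
      double h = std::max(d, std::max(e, f));
      if (local && h < 0.0) h = 0.0;
      E[c] = e; F[c] = f; H[c] = h;
    }
  }
  // end cell
  int bi = m, bj = n;
  if (mode != 1) {
    double best = local ? 0.0 : NEG;
    bi = 0; bj = 0;
    if (!local) best = H[0], bi = 0, bj = 0;
    for (int i = 0; i <= m; ++i) {
      size_t r = (size_t) i * W;
      for (int j = 0; j <= n; ++j) {
        double v = H[r + j];
        if (v > best || (v == best && (i > bi || (i == bi && j > bj)))) {
          best = v; bi = i; bj = j;
        }
      }
    }
  }
  AlnRes res;
  res.score = H[(size_t) bi * W + bj];
  // traceback
  std::vector<std::pair<char, int> > rev;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E (D-run), 2 = F (I-run)
  while (true) {
    size_t c = (size_t) i * W + j;
    if (state == 0) {
      if (local && H[c] == 0.0) break;
      if (i == 0 && j == 0) break;
      bool done = false;
      if (i > 0 && j > 0) {
        char qa = q[i - 1], tb = t[j - 1];
        bool match = (qa == tb) && is_base(qa) && is_base(tb);
        double d = H[c - W - 1] + (match ? ma : -mi);
        if (H[c] == d) {
          push_op(rev, 'M', 1);
          --i; --j;
          done = true;
        }
      }
      if (!done) {
        if (j > 0 && H[c] == E[c]) state = 1;
        else if (i > 0 && H[c] == F[c]) state = 2;
        else break; // defensive; unreachable for consistent matrices
      }
    } else if (state == 1) {
      size_t c2 = (size_t) i * W + j;
      push_op(rev, 'D', 1);
      double prevH = H[c2 - 1] - go - ge;
      --j;
      if (E[c2] == prevH) state = 0;
      if (j == 0 && state == 1) state = 0;
    } else {
      size_t c2 = (size_t) i * W + j;
      push_op(rev, 'I', 1);
      double prevH = H[c2 - W] - go - ge;
      --i;
      if (F[c2] == prevH) state = 0;
      if (i == 0 && state == 2) state = 0;
    }
  }
  res.qbeg = i; res.tbeg = j; res.qend = bi; res.tend = bj;
  res.ops.reserve(rev.size());
  for (int r = (int) rev.size() - 1; r >= 0; --r)
    push_op(res.ops, rev[r].first, rev[r].second);
  return res;
}

static std::string ops_to_cigar(const std::vector<std::pair<char, int> >& ops) {
  std::string out;
  char buf[32];
  for (size_t i = 0; i < ops.size(); ++i) {
    std::snprintf(buf, sizeof(buf), "%d%c", ops[i].second, ops[i].first);
    out += buf;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_align(const std::string& query, const std::string& target, int mode,
               double match, double mismatch, double gap_open,
               double gap_extend) {
  if (query.empty() || target.empty())
    stop("alignment requires nonempty sequences");
  AlnRes r = align_dp(query, target, mode, match, mismatch, gap_open,
                      gap_extend);
  return List::create(_["score"] = r.score,
                      _["cigar"] = ops_to_cigar(r.ops),
                      _["query_begin"] = r.qbeg, _["query_end"] = r.qend,
                      _["target_begin"] = r.tbeg, _["target_end"] = r.tend);
}

// ---------------------------------------------------------------- gap fill

struct Aln {
  bool ok;
  int chrom, strand;
  int pos;        // 0-based leftmost aligned genome offset (global)
  std::string cigar;
  double score;
  int nmatch, nmis, gapruns, gapbases, mbases;
  double frac;    // aligned (M) read fraction
  int nm;
};

// anchors: chain gap-free member extensions left to right, merging
// overlapping spans on the same diagonal and dropping conflicting ones
static std::vector<Ext> chain_members(std::vector<Ext> mem) {
  std::sort(mem.begin(), mem.end(), [](const Ext& a, const Ext& b) {
    if (a.rs != b.rs) return a.rs < b.rs;
    if (a.gs != b.gs) return a.gs < b.gs;
    return a.re > b.re;
  });
  std::vector<Ext> out;
  for (size_t i = 0; i < mem.size(); ++i) {
    const Ext& e = mem[i];
    if (out.empty()) { out.push_back(e); continue; }
    Ext& a = out.back();
    if (e.rs >= a.re && e.gs >= a.ge) {
      out.push_back(e);
    } else if ((long) e.gs - e.rs == (long) a.gs - a.rs &&
               e.rs <= a.re && e.gs <= a.ge) {
      a.re = std::max(a.re, e.re);
      a.ge = std::max(a.ge, e.ge);
    }
    // otherwise: conflicting overlap, drop (SW over the gap will recover)
  }
  return out;
}

static Aln fill_cal(const std::string& seq, const std::string& rread,
                    const std::vector<Ext>& members, int cstart, int cend,
                    double ma, double mi, double go, double gex) {
  Aln out;
  out.ok = false;
  out.score = NEG;
  const int L = (int) rread.size();
  std::vector<Ext> anchors = chain_members(members);
  if (anchors.empty()) return out;
  std::vector<std::pair<char, int> > ops;
  int pos = anchors[0].gs;

  // left end: extension alignment on reversed segments, anchored at the
  // first anchor's start; unaligned read prefix becomes a soft clip
  if (anchors[0].rs > 0) {
    int r0 = anchors[0].rs;
    int refend = anchors[0].gs;
    int refstart = std::max(cstart, refend - (r0 + 10));
    std::string qseg(rread.begin(), rread.begin() + r0);
    std::reverse(qseg.begin(), qseg.end());
    std::string tseg(seq.begin() + refstart, seq.begin() + refend);
    std::reverse(tseg.begin(), tseg.end());
    if (tseg.empty()) {
      push_op(ops, 'S', r0);
    } else {
      AlnRes r = align_dp(qseg, tseg, 2, ma, mi, go, gex);
      push_op(ops, 'S', r0 - r.qend);
      for (int i = (int) r.ops.size() - 1; i >= 0; --i)
        push_op(ops, r.ops[i].first, r.ops[i].second);
      pos = refend - r.tend;
    }
  }

  for (size_t a = 0; a < anchors.size(); ++a) {
    push_op(ops, 'M', anchors[a].re - anchors[a].rs);
    if (a + 1 == anchors.size()) break;
    int qlen = anchors[a + 1].rs - anchors[a].re;
    int tlen = anchors[a + 1].gs - anchors[a].ge;
    if (qlen == 0 && tlen == 0) continue;
    if (qlen == 0) { push_op(ops, 'D', tlen); continue; }
    if (tlen == 0) { push_op(ops, 'I', qlen); continue; }
    std::string qseg(rread.begin() + anchors[a].re,
                     rread.begin() + anchors[a + 1].rs);
    std::string tseg(seq.begin() + anchors[a].ge,
                     seq.begin() + anchors[a + 1].gs);
    AlnRes r = align_dp(qseg, tseg, 1, ma, mi, go, gex);
    for (size_t i = 0; i < r.ops.size(); ++i)
      push_op(ops, r.ops[i].first, r.ops[i].second);
  }

  // right end
  const Ext& last = anchors.back();
  if (last.re < L) {
    int rl = L - last.re;
    int tstart = last.ge;
    int tend = std::min(cend, tstart + rl + 10);
    if (tend <= tstart) {
      push_op(ops, 'S', rl);
    } else {
      std::string qseg(rread.begin() + last.re, rread.end());
      std::string tseg(seq.begin() + tstart, seq.begin() + tend);
      AlnRes r = align_dp(qseg, tseg, 2, ma, mi, go, gex);
      for (size_t i = 0; i < r.ops.size(); ++i)
        push_op(ops, r.ops[i].first, r.ops[i].second);
      push_op(ops, 'S', rl - r.qend);
    }
  }

  // normalize boundaries: no I/D may sit between a soft clip (or the
  // record edge) and the first/last M
  while (true) {
    size_t first = 0;
    while (first < ops.size() && ops[first].first == 'S') ++first;
    if (first < ops.size() && ops[first].first == 'D') {
      pos += ops[first].second;
      ops.erase(ops.begin() + first);
      continue;
    }
    if (first < ops.size() && ops[first].first == 'I') {
      int len = ops[first].second;
      ops.erase(ops.begin() + first);
      if (first > 0) ops[first - 1].second += len;
      else ops.insert(ops.begin(), std::make_pair('S', len));
      continue;
    }
    break;
  }
  while (true) {
    int lastop = (int) ops.size() - 1;
    while (lastop >= 0 && ops[lastop].first == 'S') --lastop;
    if (lastop >= 0 && ops[lastop].first == 'D') {
      ops.erase(ops.begin() + lastop);
      continue;
    }
    if (lastop >= 0 && ops[lastop].first == 'I') {
      int len = ops[lastop].second;
      ops.erase(ops.begin() + lastop);
      if (lastop < (int) ops.size()) ops[lastop].second += len;
      else ops.push_back(std::make_pair('S', len));
      continue;
    }
    break;
  }
  // merge adjacent equal ops that normalization may have created
  std::vector<std::pair<char, int> > merged;
  for (size_t i = 0; i < ops.size(); ++i)
    push_op(merged, ops[i].first, ops[i].second);
  ops.swap(merged);

  // score and consistency from the final operation string
  int ri = 0, gi = pos;
  int nmatch = 0, nmis = 0, gapruns = 0, gapbases = 0, mbases = 0;
  for (size_t i = 0; i < ops.size(); ++i) {
    char op = ops[i].first;
    int len = ops[i].second;
    if (op == 'M') {
      for (int x = 0; x < len; ++x) {
        char a = rread[ri + x], b = seq[gi + x];
        if (a == b && is_base(a)) ++nmatch; else ++nmis;
      }
      ri += len; gi += len; mbases += len;
    } else if (op == 'I') {
      ++gapruns; gapbases += len; ri += len;
    } else if (op == 'D') {
      ++gapruns; gapbases += len; gi += len;
    } else { // S
      ri += len;
    }
  }
  if (ri != L || mbases == 0) return out;
  out.ok = true;
  out.pos = pos;
  out.cigar = ops_to_cigar(ops);
  out.nmatch = nmatch; out.nmis = nmis;
  out.gapruns = gapruns; out.gapbases = gapbases;
  out.mbases = mbases;
  out.score = ma * nmatch - mi * nmis - go * gapruns - gex * gapbases;
  out.frac = (double) mbases / (double) L;
  out.nm = nmis + gapbases;
  out.chrom = 0; out.strand = 0;
  return out;
}

// member matrix columns: rs, re, gs, ge (0-based half-open, strand-oriented)
// [[Rcpp::export]]
List cpp_fill_cal(const std::string& seq, const std::string& oriented_read,
                  IntegerMatrix members, int chrom_start0, int chrom_end0,
                  double match, double mismatch, double gap_open,
                  double gap_extend) {
  std::vector<Ext> mem((size_t) members.nrow());
  for (int i = 0; i < members.nrow(); ++i) {
    mem[i].rs = members(i, 0); mem[i].re = members(i, 1);
    mem[i].gs = members(i, 2); mem[i].ge = members(i, 3);
    mem[i].mm = 0; mem[i].strand = 0; mem[i].chrom = 0;
  }
  Aln a = fill_cal(seq, oriented_read, mem, chrom_start0, chrom_end0, match,
                   mismatch, gap_open, gap_extend);
  return List::create(_["ok"] = a.ok, _["pos"] = a.ok ? a.pos : NA_INTEGER,
                      _["cigar"] = a.ok ? a.cigar : "",
                      _["score"] = a.ok ? a.score : NA_REAL,
                      _["matches"] = a.ok ? a.nmatch : NA_INTEGER,
                      _["mismatches"] = a.ok ? a.nmis : NA_INTEGER,
                      _["gap_runs"] = a.ok ? a.gapruns : NA_INTEGER,
                      _["gap_bases"] = a.ok ? a.gapbases : NA_INTEGER,
                      _["aligned_fraction"] = a.ok ? a.frac : NA_REAL,
                      _["nm"] = a.ok ? a.nm : NA_INTEGER);
}

// ---------------------------------------------------------------- finalize

static int compute_mapq(const std::vector<double>& scores, int best_i) {
  if (scores.size() == 1) return 60;
  double best = scores[best_i], second = NEG;
  for (size_t i = 0; i < scores.size(); ++i)
    if ((int) i != best_i && scores[i] > second) second = scores[i];
  if (best <= 0.0) return 0;
  if (second >= best) return 0;
  if (second <= 0.0) second = 0.0;
  double q = (best - second) / best * 60.0;
  int m = (int) std::llround(q);
  if (m > 60) m = 60;
  if (m < 0) m = 0;
  return m;
}

// ---------------------------------------------------------------- batch map

// Full per-read pipeline over the shared statics. Parameters with value
// <= 0 select the length-scaled defaults described in the R documentation.
// [[Rcpp::export]]
List cpp_map_batch(const std::string& seq, IntegerVector chrom_starts0,
                   IntegerVector chrom_lens, IntegerVector sa,
                   NumericVector keys, IntegerVector plo, IntegerVector phi,
                   int k, CharacterVector reads, int seed_len, int num_seeds,
                   int max_hits, int max_mismatches, double mismatch_frac,
                   int max_gap_abs, double gap_mult, int min_cal_abs,
                   double min_cal_frac, int max_cals, double match,
                   double mismatch, double gap_open, double gap_extend) {
  IndexView ix = { &seq, sa.size() ? INTEGER(sa) : NULL, sa.size(),
                   keys.size() ? REAL(keys) : NULL,
                   plo.size() ? INTEGER(plo) : NULL,
                   phi.size() ? INTEGER(phi) : NULL,
                   keys.size(), k };
  const int nc = chrom_starts0.size();
  const int nr = reads.size();
  LogicalVector out_mapped(nr);
  IntegerVector out_chrom(nr), out_pos(nr), out_strand(nr), out_mapq(nr),
      out_nm(nr), out_ncals(nr);
  NumericVector out_score(nr), out_frac(nr);
  CharacterVector out_cigar(nr);

  for (int rix = 0; rix < nr; ++rix) {
    std::string rd = as<std::string>(reads[rix]);
    const int L = (int) rd.size();
    out_mapped[rix] = false;
    out_chrom[rix] = NA_INTEGER; out_pos[rix] = NA_INTEGER;
    out_strand[rix] = NA_INTEGER; out_mapq[rix] = 0;
    out_score[rix] = NA_REAL; out_frac[rix] = NA_REAL;
    out_nm[rix] = NA_INTEGER; out_cigar[rix] = NA_STRING;
    out_ncals[rix] = 0;
    if (L < 1) continue;

    const int s = std::min(seed_len, L);
    const int n_seeds = num_seeds > 0 ? num_seeds
                                      : std::max(5, L / seed_len);
    const int mm_budget = max_mismatches >= 0
        ? max_mismatches
        : (int) std::ceil(mismatch_frac * L);
    const int max_gap = max_gap_abs > 0 ? max_gap_abs
                                        : (int) std::lround(gap_mult * L);
    const int min_cal = min_cal_abs >= 0
        ? min_cal_abs
        : (int) std::lround(min_cal_frac * L);
    std::vector<int> starts = seed_starts(L, s, n_seeds);

    std::string fwd = rd, rev = cpp_revcomp(rd);
    std::vector<Ext> exts;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& oread = strand == 0 ? fwd : rev;
      for (size_t si = 0; si < starts.size(); ++si) {
        int roff = starts[si];
        std::string pat = oread.substr((size_t) roff, (size_t) s);
        int lo, hi;
        if (!search_bounds(ix, pat, lo, hi)) continue; // seed contains N
        int cnt = hi - lo;
        if (cnt <= 0 || (max_hits > 0 && cnt > max_hits)) continue;
        for (int h = lo; h < hi; ++h) {
          int gpos = ix.sa[h];
          int ch = 0;
          for (int c = nc - 1; c >= 0; --c)
            if (gpos >= chrom_starts0[c]) { ch = c; break; }
          int cstart = chrom_starts0[ch];
          int cend = cstart + chrom_lens[ch];
          Ext e = extend_hit(seq, oread, roff, s, gpos, cstart, cend,
                             mm_budget);
          e.strand = strand;
          e.chrom = ch;
          exts.push_back(e);
        }
      }
    }
    if (exts.empty()) continue;
    // deduplicate identical extensions produced by overlapping seeds
    std::sort(exts.begin(), exts.end(), [](const Ext& a, const Ext& b) {
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.gs != b.gs) return a.gs < b.gs;
      if (a.rs != b.rs) return a.rs < b.rs;
      if (a.ge != b.ge) return a.ge < b.ge;
      return a.re < b.re;
    });
    exts.erase(std::unique(exts.begin(), exts.end(),
                           [](const Ext& a, const Ext& b) {
                             return a.strand == b.strand && a.rs == b.rs &&
                                    a.re == b.re && a.gs == b.gs &&
                                    a.ge == b.ge;
                           }),
               exts.end());

    std::vector<Cal> cals;
    size_t i = 0;
    while (i < exts.size()) {
      size_t j = i;
      int ch = exts[i].chrom, st = exts[i].strand;
      while (j < exts.size() && exts[j].chrom == ch && exts[j].strand == st)
        ++j;
      std::vector<int> grp;
      for (size_t t = i; t < j; ++t) grp.push_back((int) t);
      cluster_group(exts, grp, ch, st, max_gap, min_cal, cals);
      i = j;
    }
    if (cals.empty()) continue;

    // rank: coverage desc, total mismatches asc, leftmost genome
    // coordinate, forward strand first
    std::vector<int> order((int) cals.size());
    for (size_t t = 0; t < order.size(); ++t) order[t] = (int) t;
    std::sort(order.begin(), order.end(), [&cals](int a, int b) {
      if (cals[a].coverage != cals[b].coverage)
        return cals[a].coverage > cals[b].coverage;
      if (cals[a].mm_total != cals[b].mm_total)
        return cals[a].mm_total < cals[b].mm_total;
      if (cals[a].gs != cals[b].gs) return cals[a].gs < cals[b].gs;
      return cals[a].strand < cals[b].strand;
    });
    if ((int) order.size() > max_cals) order.resize(max_cals);
    out_ncals[rix] = (int) order.size();

    std::vector<Aln> alns;
    for (size_t t = 0; t < order.size(); ++t) {
      const Cal& c = cals[order[t]];
      std::vector<Ext> mem;
      for (size_t u = 0; u < c.members.size(); ++u)
        mem.push_back(exts[c.members[u]]);
      int cstart = chrom_starts0[c.chrom];
      int cend = cstart + chrom_lens[c.chrom];
      const std::string& oread = c.strand == 0 ? fwd : rev;
      Aln a = fill_cal(seq, oread, mem, cstart, cend, match, mismatch,
                       gap_open, gap_extend);
      if (!a.ok) continue;
      a.chrom = c.chrom;
      a.strand = c.strand;
      alns.push_back(a);
    }
    if (alns.empty()) continue;

    std::vector<double> scores(alns.size());
    for (size_t t = 0; t < alns.size(); ++t) scores[t] = alns[t].score;
    int best = 0;
    for (size_t t = 1; t < alns.size(); ++t) {
      const Aln& a = alns[t], &b = alns[best];
      bool better = a.score > b.score;
      if (a.score == b.score) {
        if (a.chrom != b.chrom) better = a.chrom < b.chrom;
        else if (a.pos != b.pos) better = a.pos < b.pos;
        else better = a.strand < b.strand;
      }
      if (better) best = (int) t;
    }
    const Aln& a = alns[best];
    out_mapped[rix] = true;
    out_chrom[rix] = a.chrom + 1;
    out_pos[rix] = a.pos - chrom_starts0[a.chrom] + 1; // 1-based local
    out_strand[rix] = a.strand;
    out_mapq[rix] = compute_mapq(scores, best);
    out_score[rix] = a.score;
    out_frac[rix] = a.frac;
    out_nm[rix] = a.nm;
    out_cigar[rix] = a.cigar;
  }
  return List::create(_["mapped"] = out_mapped, _["chrom"] = out_chrom,
                      _["pos"] = out_pos, _["strand"] = out_strand,
                      _["mapq"] = out_mapq, _["cigar"] = out_cigar,
                      _["score"] = out_score, _["aligned_frac"] = out_frac,
                      _["nm"] = out_nm, _["n_cals"] = out_ncals);
}
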