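#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Ungapped, one-gap read matcher and pileup engine.
//
// The reference is held as a single padded string (contigs joined by runs of
// '#', which match nothing), with per-contig offsets used to report local
// coordinates and to reject placements that straddle a boundary. Candidate
// placements come from exact k-mer seeds taken at non-overlapping offsets of
// the read; with k <= len/(max_mm + 2) every placement with at most max_mm
// mismatches plus one gap retains an exact seed, so enumeration is complete.

static const int PAD = 12; // > max gap length + max mismatches

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// 2-bit encode a k-mer; returns false if any non-ACGT base present
static bool kmer_code(const char* s, int k, uint64_t& code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b;
    switch (s[i]) {
    case 'A': b = 0; break; case 'C': b = 1; break;
    case 'G': b = 2; break; case 'T': b = 3; break;
    default: return false;
    }
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

struct Placement {
  long pos;      // 0-based start in padded reference
  bool fwd;
  int mm;        // mismatches (gap bases not counted)
  int gap_pos;   // 0-based padded ref position of first gap base (del) or of
                 // the base following the insertion point; -1 if ungapped
  int gap_len;   // >0 insertion in read, <0 deletion from reference, 0 none
  int max_run;   // longest contiguous exact match
};

// evaluate ungapped placement; returns true if mm <= max_mm
static bool eval_ungapped(const std::string& ref, const std::string& rd,
                          long s, int max_mm, Placement& out) {
  int len = (int)rd.size();
  if (s < 0 || s + len > (long)ref.size()) return false;
  int mm = 0, run = 0, max_run = 0;
  for (int i = 0; i < len; ++i) {
    if (ref[s + i] == rd[i] && rd[i] != 'N') {
      if (++run > max_run) max_run = run;
    } else {
      run = 0;
      if (++mm > max_mm) return false;
    }
  }
  out.pos = s; out.mm = mm; out.gap_pos = -1; out.gap_len = 0;
  out.max_run = max_run;
  return true;
}

// best single-gap placement left-anchored at s; gap sizes 1..max_gap both
// directions; O(len * max_gap) via cumulative prefix/suffix arrays
static bool eval_gapped(const std::string& ref, const std::string& rd,
                        long s, int max_mm, int max_gap, Placement& out) {
  int len = (int)rd.size();
  long L = (long)ref.size();
  if (s < 0 || s + len + max_gap > L) return false;
  // prefix arrays vs ref[s..]: cumulative mismatches and max exact run
  std::vector<int> pre(len + 1, 0), prerun(len + 1, 0);
  {
    int run = 0, mx = 0;
    for (int i = 0; i < len; ++i) {
      bool m = (ref[s + i] == rd[i] && rd[i] != 'N');
      pre[i + 1] = pre[i] + (m ? 0 : 1);
      run = m ? run + 1 : 0;
      if (run > mx) mx = run;
      prerun[i + 1] = mx;
    }
  }
  bool found = false;
  Placement best;
  best.mm = 0; best.gap_len = 0; best.pos = s; best.fwd = true;
  best.gap_pos = -1; best.max_run = 0;
  std::vector<int> sufmm(len + 1), sufrun(len + 1), streak(len + 1);
  for (int dir = 0; dir < 2; ++dir) {      // 0 = deletion, 1 = insertion
    for (int g = 1; g <= max_gap; ++g) {
      // suffix arrays for this gap size:
      //   deletion:  rd[i] vs ref[s + i + g]  (i in [b, len))
      //   insertion: rd[i] vs ref[s + i - g]  (i in [b + g, len))
      int lo = (dir == 0) ? 0 : g;
      sufmm[len] = 0; sufrun[len] = 0; streak[len] = 0;
      for (int i = len - 1; i >= lo; --i) {
        long p = (dir == 0) ? s + i + g : s + i - g;
        bool m = (p >= 0 && p < L && ref[p] == rd[i] && rd[i] != 'N');
        sufmm[i] = sufmm[i + 1] + (m ? 0 : 1);
        streak[i] = m ? streak[i + 1] + 1 : 0;
        sufrun[i] = std::max(sufrun[i + 1], streak[i]);
      }
      int bmax = (dir == 0) ? len - 1 : len - g - 1;
      for (int b = 1; b <= bmax; ++b) {
        if (pre[b] > max_mm) break;
        int si = (dir == 0) ? b : b + g;
        int mm = pre[b] + sufmm[si];
        if (mm > max_mm) continue;
        int score = mm + g;
        int best_score = best.mm + std::abs(best.gap_len);
        if (!found || score < best_score ||
            (score == best_score && s + b < (long)best.gap_pos)) {
          best.pos = s; best.mm = mm;
          best.gap_pos = (int)(s + b);
          best.gap_len = (dir == 0) ? -g : g;
          best.max_run = std::max(prerun[b], sufrun[si]);
          found = true;
        }
      }
    }
  }
  if (found) out = best;
  return found;
}

static bool accept(const Placement& p, int read_len, double min_ident,
                   int min_exact) {
  int aligned = read_len - std::max(0, p.gap_len); // read bases aligned to ref
  double ident = 100.0 * (double)(aligned - p.mm) / (double)aligned;
  return ident > min_ident && p.max_run >= min_exact;
}

// [[Rcpp::export]]
List cpp_align(CharacterVector contigs, CharacterVector contig_names,
               CharacterVector reads, int k = 16, int max_mm = 2,
               double min_ident = 95.0, int min_exact = 35,
               int max_hits = 100, int max_gap = 9) {
  // build padded reference
  std::string ref;
  std::vector<long> offs;     // start offset of each contig in padded string
  std::vector<long> clens;
  for (int c = 0; c < contigs.size(); ++c) {
    if (c > 0) ref.append(PAD, '#');
    offs.push_back((long)ref.size());
    std::string s = as<std::string>(contigs[c]);
    clens.push_back((long)s.size());
    ref += s;
  }
  ref.append(PAD, '#'); // tail padding so one-gap evaluation works at contig ends
  long L = (long)ref.size();
  // k-mer index of reference
  std::unordered_map<uint64_t, std::vector<long> > idx;
  idx.reserve((size_t)(L * 1.3));
  {
    uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    uint64_t code = 0; int valid = 0;
    for (long i = 0; i < L; ++i) {
      int b = -1;
      switch (ref[i]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      }
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) idx[code].push_back(i - k + 1);
    }
  }

  int n = reads.size();
  IntegerVector status(n);       // 0 unmapped, 1 mapped, 2 multi
  IntegerVector contig_i(n, NA_INTEGER);
  IntegerVector start(n, NA_INTEGER);   // 1-based local
  CharacterVector strand(n, NA_STRING);
  IntegerVector nm(n, NA_INTEGER);
  IntegerVector gpos(n, NA_INTEGER);    // 1-based local pos of gap (first del
                                        // base, or base following insertion)
  IntegerVector glen(n, 0);
  LogicalVector perfect(n);
  IntegerVector mult(n, 0);

  std::vector<long> cand;
  for (int r = 0; r < n; ++r) {
    std::string fseq = as<std::string>(reads[r]);
    int len = (int)fseq.size();
    if (len < min_exact) { status[r] = 0; continue; }
    std::string rseq = revcomp(fseq);
    std::vector<Placement> hits;
    bool over_cap = false;
    for (int st = 0; st < 2 && !over_cap; ++st) {
      const std::string& rd = (st == 0) ? fseq : rseq;
      cand.clear();
      for (int o = 0; o + k <= len; o += k) {
        uint64_t code;
        if (!kmer_code(rd.c_str() + o, k, code)) continue;
        std::unordered_map<uint64_t, std::vector<long> >::const_iterator it =
          idx.find(code);
        if (it == idx.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j)
          cand.push_back(it->second[j] - o);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      // phase 1: ungapped
      bool any_ungapped = false;
      for (size_t j = 0; j < cand.size(); ++j) {
        Placement p;
        if (eval_ungapped(ref, rd, cand[j], max_mm, p) &&
            accept(p, len, min_ident, min_exact)) {
          p.fwd = (st == 0);
          hits.push_back(p);
          any_ungapped = true;
          if ((int)hits.size() > max_hits) { over_cap = true; break; }
        }
      }
      if (over_cap) break;
      if (!any_ungapped) {
        // phase 2: single-gap placements around each candidate
        std::vector<long> ecand;
        for (size_t j = 0; j < cand.size(); ++j)
          for (int d = -max_gap; d <= max_gap; ++d) ecand.push_back(cand[j] + d);
        std::sort(ecand.begin(), ecand.end());
        ecand.erase(std::unique(ecand.begin(), ecand.end()), ecand.end());
        for (size_t j = 0; j < ecand.size(); ++j) {
          Placement p;
          if (eval_gapped(ref, rd, ecand[j], max_mm, max_gap, p) &&
              accept(p, len, min_ident, min_exact)) {
            p.fwd = (st == 0);
            hits.push_back(p);
            if ((int)hits.size() > max_hits) { over_cap = true; break; }
          }
        }
      }
    }
    if (over_cap) { status[r] = 2; mult[r] = max_hits + 1; continue; }
    if (hits.empty()) { status[r] = 0; continue; }
    // dedupe by (pos, strand); keep best (lowest edit, then leftmost, then fwd)
    std::sort(hits.begin(), hits.end(),
              [](const Placement& a, const Placement& b) {
                int ea = a.mm + std::abs(a.gap_len), eb = b.mm + std::abs(b.gap_len);
                if (ea != eb) return ea < eb;
                if (a.pos != b.pos) return a.pos < b.pos;
                return a.fwd && !b.fwd;
              });
    std::vector<std::pair<long, bool> > seen;
    std::vector<Placement> uniq;
    for (size_t j = 0; j < hits.size(); ++j) {
      std::pair<long, bool> key(hits[j].pos, hits[j].fwd);
      bool dup = false;
      for (size_t q = 0; q < seen.size(); ++q)
        if (seen[q] == key) { dup = true; break; }
      if (!dup) { seen.push_back(key); uniq.push_back(hits[j]); }
    }
    if ((int)uniq.size() > max_hits) { status[r] = 2; mult[r] = (int)uniq.size(); continue; }
    const Placement& p = uniq[0];
    // map to contig
    int ci = 0;
    for (size_t c2 = 0; c2 < offs.size(); ++c2)
      if (p.pos >= offs[c2] && p.pos < offs[c2] + clens[c2]) ci = (int)c2;
    if (p.pos < offs[ci] || p.pos + len + std::max(0, -p.gap_len) >
        offs[ci] + clens[ci]) { status[r] = 0; continue; }
    status[r] = 1;
    contig_i[r] = ci + 1;
    start[r] = (int)(p.pos - offs[ci]) + 1;
    strand[r] = p.fwd ? "+" : "-";
    nm[r] = p.mm + std::abs(p.gap_len);
    perfect[r] = (p.mm == 0 && p.gap_len == 0);
    mult[r] = (int)uniq.size();
    if (p.gap_len != 0) {
      gpos[r] = (int)(p.gap_pos - offs[ci]) + 1;
      glen[r] = p.gap_len;
    } else gpos[r] = 0;
  }
  return List::create(_["status"] = status, _["contig"] = contig_i,
                      _["start"] = start, _["strand"] = strand,
                      _["nm"] = nm, _["gap_pos"] = gpos, _["gap_len"] = glen,
                      _["perfect"] = perfect, _["multiplicity"] = mult);
}

// [[Rcpp::export]]
List cpp_pileup(std::string refseq, CharacterVector reads,
                IntegerVector start, CharacterVector strand,
                IntegerVector gap_pos, IntegerVector gap_len) {
  long L = (long)refseq.size();
  // base counts: 8 x L (A,C,G,T forward then A,C,G,T reverse)
  IntegerMatrix counts(8, (int)L);
  IntegerVector del_depth((int)L);
  std::map<std::pair<long, int>, std::pair<int, int> > dels; // (pos0,len)->(fwd,rev)
  std::map<std::pair<long, std::string>, std::pair<int, int> > inss;
  int n = reads.size();
  for (int r = 0; r < n; ++r) {
    // read sequences arrive already oriented to the forward reference strand
    std::string rd = as<std::string>(reads[r]);
    if (strand[r] == NA_STRING) continue;
    bool fwd = (as<std::string>(strand[r]) == "+");
    long s = start[r] - 1;
    int len = (int)rd.size();
    int gp = gap_pos[r], gl = gap_len[r];
    if (gl == 0) {
      for (int i = 0; i < len; ++i) {
        long p = s + i;
        if (p < 0 || p >= L) continue;
        int b;
        switch (rd[i]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
        }
        if (b >= 0) counts(fwd ? b : b + 4, (int)p)++;
      }
    } else if (gl < 0) { // deletion of -gl ref bases starting at ref pos gp (1-based)
      long dstart = gp - 1;
      int g = -gl;
      int b0 = (int)(dstart - s);     // read bases before the gap
      for (int i = 0; i < len; ++i) {
        long p = (i < b0) ? s + i : s + i + g;
        if (p < 0 || p >= L) continue;
        int b;
        switch (rd[i]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
        }
        if (b >= 0) counts(fwd ? b : b + 4, (int)p)++;
      }
      for (long p = dstart; p < dstart + g && p < L; ++p) del_depth[(int)p]++;
      std::pair<long, int> key(dstart, g);
      if (fwd) dels[key].first++; else dels[key].second++;
    } else { // insertion of gl read bases before ref pos gp (1-based)
      long ipos = gp - 1;
      int b0 = (int)(ipos - s);
      for (int i = 0; i < len; ++i) {
        if (i >= b0 && i < b0 + gl) continue; // inserted bases
        long p = (i < b0) ? s + i : s + i - gl;
        if (p < 0 || p >= L) continue;
        int b;
        switch (rd[i]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
        }
        if (b >= 0) counts(fwd ? b : b + 4, (int)p)++;
      }
      std::string iseq = rd.substr(b0, gl);
      std::pair<long, std::string> key(ipos, iseq);
      if (fwd) inss[key].first++; else inss[key].second++;
    }
  }
  // flatten indel maps
  int nd = (int)dels.size(), ni = (int)inss.size();
  IntegerVector dpos(nd), dlen(nd), dfwd(nd), drev(nd);
  {
    int i = 0;
    for (std::map<std::pair<long, int>, std::pair<int, int> >::iterator it =
           dels.begin(); it != dels.end(); ++it, ++i) {
      dpos[i] = (int)it->first.first + 1; dlen[i] = it->first.second;
      dfwd[i] = it->second.first; drev[i] = it->second.second;
    }
  }
  IntegerVector ipos(ni), ifwd(ni), irev(ni);
  CharacterVector iseq(ni);
  {
    int i = 0;
    for (std::map<std::pair<long, std::string>, std::pair<int, int> >::iterator
           it = inss.begin(); it != inss.end(); ++it, ++i) {
      ipos[i] = (int)it->first.first + 1; iseq[i] = it->first.second;
      ifwd[i] = it->second.first; irev[i] = it->second.second;
    }
  }
  return List::create(_["counts"] = counts, _["del_depth"] = del_depth,
                      _["del"] = DataFrame::create(_["pos"] = dpos, _["len"] = dlen,
                                                   _["fwd"] = dfwd, _["rev"] = drev),
                      _["ins"] = DataFrame::create(_["pos"] = ipos, _["seq"] = iseq,
                                                   _["fwd"] = ifwd, _["rev"] = irev,
                                                   _["stringsAsFactors"] = false));
}
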