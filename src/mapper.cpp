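#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}
static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerMap;

// index k-mers of `ref` (forward strand only; reads are searched in both
// orientations instead). k-mers containing non-ACGT are skipped.
static KmerMap build_kmer_map(const std::string& ref, int k) {
  KmerMap m;
  int n = (int)ref.size();
  if (n < k) return m;
  uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(ref[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) m[key].push_back(i - k + 1);
  }
  return m;
}

static inline bool pack_kmer(const std::string& s, int pos, int k, uint64_t& key) {
  key = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    key = (key << 2) | (uint64_t)c;
  }
  return true;
}

// mismatches of seq against ref_ext at offset, early exit beyond `cap`
static int count_mm(const std::string& ref, int offset, const std::string& seq,
                    int cap) {
  int mm = 0, L = (int)seq.size();
  for (int j = 0; j < L; ++j) {
    char a = ref[offset + j], b = seq[j];
    if (a != b || base_code(a) < 0) {  // N/N never matches anything
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List cpp_kmer_positions(std::string ref, std::string kmer) {
  int k = (int)kmer.size();
  KmerMap m = build_kmer_map(ref, k);
  uint64_t key;
  std::vector<int> fwd, rev;
  if (pack_kmer(kmer, 0, k, key)) {
    KmerMap::iterator it = m.find(key);
    if (it != m.end()) fwd = it->second;
  }
  std::string rc = revcomp(kmer);
  if (pack_kmer(rc, 0, k, key)) {
    KmerMap::iterator it = m.find(key);
    if (it != m.end()) rev = it->second;
  }
  return List::create(_["fwd"] = wrap(fwd), _["rev"] = wrap(rev));
}

struct Candidate { int offset; int strand; };

// Map reads onto one reference with an ungapped mismatch budget.
// Guaranteed equivalent to exhaustive scan: seeds partition the read into
// (budget+1) blocks (pigeonhole), shrinking k when needed and falling back
// to a full scan when even k = 4 cannot fit.
// [[Rcpp::export]]
DataFrame cpp_map_reads(std::string ref, CharacterVector reads,
                        int k, double max_mm_frac, bool circular) {
  int n_reads = reads.size();
  int L_ref = (int)ref.size();
  int max_L = 0;
  for (int i = 0; i < n_reads; ++i)
    max_L = std::max(max_L, (int)LENGTH(STRING_ELT(reads, i)));
  int wrap = circular ? std::min(L_ref - 1, std::max(0, max_L - 1)) : 0;
  std::string ref_ext = ref + ref.substr(0, wrap);
  int L_ext = (int)ref_ext.size();

  std::unordered_map<int, KmerMap> indexes;  // by effective k

  IntegerVector out_start(n_reads), out_end(n_reads), out_mm(n_reads),
      out_mapq(n_reads);
  CharacterVector out_strand(n_reads);
  LogicalVector out_mapped(n_reads);

  for (int i = 0; i < n_reads; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int L = (int)fwd.size();
    out_mapped[i] = false;
    if (L == 0 || L > L_ref) continue;
    int budget = (int)std::floor(max_mm_frac * L);
    int max_off = circular ? (L_ref - 1) : (L_ref - L);
    if (max_off < 0) continue;

    std::string rev = revcomp(fwd);
    const std::string* seqs[2] = { &fwd, &rev };
    const char strands[2] = { '+', '-' };

    // gather candidate (offset, strand) pairs
    std::vector<Candidate> cands;
    int s = budget + 1;
    int k_eff = k;
    if ((int64_t)s * k_eff > L) k_eff = L / s;
    bool full_scan = (k_eff < 4);

    if (full_scan) {
      for (int st = 0; st < 2; ++st)
        for (int off = 0; off <= max_off; ++off)
          cands.push_back(Candidate{ off, st });
    } else {
      if (indexes.find(k_eff) == indexes.end())
        indexes[k_eff] = build_kmer_map(ref_ext, k_eff);
      KmerMap& idx = indexes[k_eff];
      std::vector<std::pair<int,int> > seen;  // (offset, strand)
      for (int st = 0; st < 2; ++st) {
        const std::string& q = *seqs[st];
        for (int b = 0; b < s; ++b) {
          int pos = (int)(((int64_t)b * L) / s);
          if (pos + k_eff > L) pos = L - k_eff;
          uint64_t key;
          if (!pack_kmer(q, pos, k_eff, key)) continue;
          KmerMap::iterator it = idx.find(key);
          if (it == idx.end()) continue;
          for (size_t h = 0; h < it->second.size(); ++h) {
            int off = it->second[h] - pos;
            if (circular) {
              if (off < 0) off += L_ref;
              if (off < 0 || off > max_off) continue;
            } else {
              if (off < 0 || off > max_off) continue;
            }
            seen.push_back(std::make_pair(off, st));
          }
        }
      }
      std::sort(seen.begin(), seen.end());
      seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
      for (size_t h = 0; h < seen.size(); ++h)
        cands.push_back(Candidate{ seen[h].first, seen[h].second });
    }

    // evaluate candidates; deterministic preference: fewer mismatches, then
    // + strand, then smaller offset (candidate order below encodes this)
    std::sort(cands.begin(), cands.end(), [](const Candidate& a, const Candidate& b) {
      if (a.strand != b.strand) return a.strand < b.strand;
      return a.offset < b.offset;
    });
    int best_mm = budget + 1, second_mm = budget + 1;
    int best_off = -1, best_strand = 0;
    bool have_best = false, have_second = false;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      int off = cands[ci].offset, st = cands[ci].strand;
      if (circular && off + L > L_ext) continue;  // cannot happen by wrap size
      int mm = count_mm(ref_ext, off, *seqs[st], budget);
      if (mm > budget) continue;
      if (!have_best) {
        have_best = true; best_mm = mm; best_off = off; best_strand = st;
      } else if (mm < best_mm) {
        second_mm = best_mm; have_second = true;
        best_mm = mm; best_off = off; best_strand = st;
      } else if (mm < second_mm || !have_second) {
        second_mm = mm; have_second = true;
      }
    }
    if (!have_best) continue;
    int mapq = 60;
    if (have_second) mapq = std::min(60, 30 * (second_mm - best_mm));
    out_mapped[i] = true;
    out_start[i] = best_off;
    out_end[i] = best_off + L;
    out_strand[i] = std::string(1, strands[best_strand]);
    out_mm[i] = best_mm;
    out_mapq[i] = mapq;
  }
  return DataFrame::create(
    _["mapped"] = out_mapped, _["start"] = out_start, _["end"] = out_end,
    _["strand"] = out_strand, _["n_mismatch"] = out_mm, _["mapq"] = out_mapq,
    _["stringsAsFactors"] = false);
}

// Column base counts over a reference from ungapped alignments.
// Non-ACGT read bases are not counted (depth is the sum of A/C/G/T counts).
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int ref_len, IntegerVector starts,
                         CharacterVector strands, CharacterVector bases,
                         bool circular) {
  IntegerMatrix counts(4, ref_len);
  int n = starts.size();
  for (int i = 0; i < n; ++i) {
    std::string b = as<std::string>(bases[i]);
    if (as<std::string>(strands[i]) == "-") b = revcomp(b);
    int L = (int)b.size();
    int start = starts[i];
    if (start < 0 || (!circular && start + L > ref_len) || start >= ref_len)
      stop("alignment out of reference bounds (read %d)", i + 1);
    for (int j = 0; j < L; ++j) {
      int pos = start + j;
      if (pos >= ref_len) {
        if (!circular) stop("alignment out of reference bounds (read %d)", i + 1);
        pos -= ref_len;
      }
      int c = base_code(b[j]);
      if (c >= 0) counts(c, pos)++;
    }
  }
  return counts;
}
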