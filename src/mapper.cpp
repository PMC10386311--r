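#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode A/C/G/T; returns 4 for anything else.
static inline int base2(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return 4;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KmerIndex;

// Index all k-mers of the (extension-included) target sequences.
// Packed hit = (target << 40) | 0-based position in the extended sequence.
static void index_target(KmerIndex &idx, const std::string &seq,
                         uint64_t t, int k) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2(seq[i]);
    if (b > 3) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      uint64_t pos = i + 1 - k;
      idx[h].push_back((t << 40) | pos);
    }
  }
}

// Mismatch count with early exit; start is 0-based in ext.
static int count_mm(const std::string &ext, size_t start,
                    const std::string &read, int max_mm) {
  if (start + read.size() > ext.size()) return max_mm + 1;
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    if (ext[start + i] != read[i] && ++mm > max_mm) return mm;
  }
  return mm;
}

struct Hit {
  int target;      // 0-based
  long start;      // 0-based in extended sequence
  int strand;      // 0 = +, 1 = -
  int mm;
};

// Map reads to targets by exact k-mer seeding plus full-length verification
// allowing up to max_mm substitutions. Circular targets are extended by
// wrap bases so placements may run over the end (the caller interprets
// start modulo the target length). Seeds are tried at offsets 0, k, 2k, ...;
// the first seed yielding a verified placement decides the candidate set.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector target_seqs, LogicalVector circular,
                   CharacterVector reads, int k, int max_mm, int wrap) {
  int nt = target_seqs.size();
  std::vector<std::string> ext(nt);
  std::vector<long> tlen(nt);
  KmerIndex idx;
  for (int t = 0; t < nt; ++t) {
    std::string s = as<std::string>(target_seqs[t]);
    tlen[t] = (long)s.size();
    if (circular[t] && (long)s.size() > wrap)
      s += s.substr(0, wrap);
    ext[t] = s;
    index_target(idx, ext[t], (uint64_t)t, k);
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  int n = reads.size();
  IntegerVector out_target(n, NA_INTEGER), out_start(n, NA_INTEGER),
    out_mm(n, NA_INTEGER), out_nbest(n, NA_INTEGER);
  CharacterVector out_strand(n, NA_STRING);

  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rc = revcomp(fwd);
    int L = (int)fwd.size();
    std::vector<Hit> best;
    int best_mm = max_mm + 1;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &rd = strand ? rc : fwd;
      if (L < k) continue;
      for (int off = 0; off + k <= L; off += k) {
        // encode seed
        uint64_t h = 0;
        bool ok = true;
        for (int i = 0; i < k; ++i) {
          int b = base2(rd[off + i]);
          if (b > 3) { ok = false; break; }
          h = ((h << 2) | (uint64_t)b) & mask;
        }
        if (!ok) continue;
        KmerIndex::const_iterator it = idx.find(h);
        if (it == idx.end()) continue;
        bool verified_any = false;
        for (size_t j = 0; j < it->second.size(); ++j) {
          int t = (int)(it->second[j] >> 40);
          long pos = (long)(it->second[j] & ((1ULL << 40) - 1));
          long start = pos - off;
          if (start < 0) {
            if (circular[t]) start += tlen[t]; else continue;
          }
          if (circular[t] && start >= tlen[t]) start -= tlen[t];
          int mm = count_mm(ext[t], (size_t)start, rd, max_mm);
          if (mm > max_mm) continue;
          verified_any = true;
          Hit hmm = {t, start, strand, mm};
          if (mm < best_mm) {
            best_mm = mm;
            best.clear();
            best.push_back(hmm);
          } else if (mm == best_mm) {
            bool dupe = false;
            for (size_t b2 = 0; b2 < best.size(); ++b2)
              if (best[b2].target == t && best[b2].start == start &&
                  best[b2].strand == strand) { dupe = true; break; }
            if (!dupe) best.push_back(hmm);
          }
        }
        if (verified_any) break;  // first productive seed decides
      }
    }
    if (!best.empty()) {
      // leftmost placement among equally good ones
      Hit chosen = best[0];
      for (size_t j = 1; j < best.size(); ++j) {
        if (best[j].target < chosen.target ||
            (best[j].target == chosen.target && best[j].start < chosen.start))
          chosen = best[j];
      }
      out_target[r] = chosen.target + 1;
      out_start[r] = (int)chosen.start + 1;
      out_strand[r] = chosen.strand ? "-" : "+";
      out_mm[r] = chosen.mm;
      out_nbest[r] = (int)best.size();
    }
  }
  return List::create(_["target"] = out_target, _["start"] = out_start,
                      _["strand"] = out_strand, _["nmm"] = out_mm,
                      _["n_best"] = out_nbest);
}

// Per-position base counts (A, C, G, T rows) over one target from
// substitution-only placements. Oriented read sequences are given; starts
// are 1-based and may run over the end of a circular target (positions
// wrap modulo target length).
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(std::string target_seq, IntegerVector starts,
                         CharacterVector oriented, bool circ) {
  long len = (long)target_seq.size();
  IntegerMatrix counts(4, len);
  for (int i = 0; i < starts.size(); ++i) {
    std::string rd = as<std::string>(oriented[i]);
    long s = starts[i] - 1;
    for (size_t j = 0; j < rd.size(); ++j) {
      long p = s + (long)j;
      if (p >= len) {
        if (circ) p -= len; else break;
      }
      int b = base2(rd[j]);
      if (b <= 3) counts(b, p)++;
    }
  }
  return counts;
}
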