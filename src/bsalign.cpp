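// Aligner and pileup kernels.
//
// Alignment contract: report EVERY position on every supplied (converted)
// reference where the query matches with at most `max_mm` substitutions
// (no indels).  Candidate generation uses max_mm + 1 disjoint exact seeds
// (pigeonhole: <= max_mm substitutions leave at least one seed intact), so
// the hit set is provably identical to a naive all-offsets Hamming scan.
// Queries too short to host the seeds fall back to the naive scan itself.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N or anything else: never matches
  }
}

// Hamming distance capped at max_mm + 1 (early exit). Any non-ACGT byte on
// either side counts as a mismatch, including N vs N.
static inline int capped_mm(const char* ref, const char* qry, int len, int cap) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    char r = ref[i], q = qry[i];
    if (r != q || base2bits(r) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector refs, CharacterVector reads,
                          int max_mm, int seed_len) {
  const int nref = refs.size();
  std::vector<const char*> rptr(nref);
  std::vector<int> rlen(nref);
  for (int j = 0; j < nref; ++j) {
    rptr[j] = CHAR(STRING_ELT(refs, j));
    rlen[j] = LENGTH(STRING_ELT(refs, j));
  }

  // k-mer index over all references; value packs (ref << 32) | pos0
  std::unordered_map<uint64_t, std::vector<uint64_t>> index;
  const uint64_t mask =
      (seed_len >= 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * seed_len)) - 1);
  for (int j = 0; j < nref; ++j) {
    const char* s = rptr[j];
    const int L = rlen[j];
    uint64_t key = 0;
    int run = 0; // valid bases accumulated
    for (int i = 0; i < L; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | uint64_t(b)) & mask;
      if (++run >= seed_len) {
        int pos0 = i - seed_len + 1;
        index[key].push_back((uint64_t(j) << 32) | uint64_t(pos0));
      }
    }
  }

  std::vector<int> out_read, out_ref, out_pos, out_mm;
  const int nseeds = max_mm + 1;
  std::vector<uint64_t> cand;

  for (int q = 0; q < reads.size(); ++q) {
    const char* rd = CHAR(STRING_ELT(reads, q));
    const int L = LENGTH(STRING_ELT(reads, q));
    if (L < seed_len) continue; // unmappable by contract (caller pre-filters)

    int stride = L / nseeds;
    bool seeds_ok = stride >= seed_len;
    cand.clear();

    if (seeds_ok) {
      for (int si = 0; si < nseeds && seeds_ok; ++si) {
        int off = si * stride;
        uint64_t key = 0;
        for (int i = 0; i < seed_len; ++i) {
          int b = base2bits(rd[off + i]);
          if (b < 0) { seeds_ok = false; break; }
          key = (key << 2) | uint64_t(b);
        }
        if (!seeds_ok) break;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (uint64_t packed : it->second) {
          int j = int(packed >> 32);
          int64_t start = int64_t(packed & 0xffffffffu) - off;
          if (start < 0 || start + L > rlen[j]) continue;
          cand.push_back((uint64_t(j) << 32) | uint64_t(start));
        }
      }
    }

    if (seeds_ok) {
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (uint64_t packed : cand) {
        int j = int(packed >> 32);
        int pos0 = int(packed & 0xffffffffu);
        int mm = capped_mm(rptr[j] + pos0, rd, L, max_mm);
        if (mm <= max_mm) {
          out_read.push_back(q + 1);
          out_ref.push_back(j + 1);
          out_pos.push_back(pos0 + 1);
          out_mm.push_back(mm);
        }
      }
    } else {
      // short/ambiguous query: exhaustive scan keeps the contract exact
      for (int j = 0; j < nref; ++j) {
        const int last = rlen[j] - L;
        for (int pos0 = 0; pos0 <= last; ++pos0) {
          int mm = capped_mm(rptr[j] + pos0, rd, L, max_mm);
          if (mm <= max_mm) {
            out_read.push_back(q + 1);
            out_ref.push_back(j + 1);
            out_pos.push_back(pos0 + 1);
            out_mm.push_back(mm);
          }
        }
      }
    }
  }

  return DataFrame::create(_["read"] = out_read, _["ref"] = out_ref,
                           _["pos"] = out_pos, _["mm"] = out_mm);
}

// Per-cytosine C/T pileup on strand-oriented coordinates.
//
// `refs` are the strand reference sequences (Watson forward, Crick =
// reverse complement of Watson), one entry per (chromosome, strand).
// Each record supplies its reference id, 1-based start on that strand's
// own coordinates, strand-oriented bases/quals, a fragment id and a mate
// number.  Within one fragment, positions covered by both mates count
// once, taking the mate whose base quality is higher (ties -> mate 1).
// Only reference-C positions are tallied, and only read bases C or T.
// [[Rcpp::export]]
List cpp_pileup(CharacterVector refs, IntegerVector ref_id,
                IntegerVector start, CharacterVector bases,
                CharacterVector quals, IntegerVector frag_id,
                IntegerVector mate) {
  const int nref = refs.size();
  std::vector<const char*> rptr(nref);
  std::vector<int> rlen(nref);
  std::vector<std::vector<int>> cc(nref), tc(nref);
  for (int j = 0; j < nref; ++j) {
    rptr[j] = CHAR(STRING_ELT(refs, j));
    rlen[j] = LENGTH(STRING_ELT(refs, j));
  }
  const int n = ref_id.size();

  // order records by fragment, mate 1 first, so a fragment is contiguous
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (frag_id[a] != frag_id[b]) return frag_id[a] < frag_id[b];
    return mate[a] < mate[b];
  });

  auto ensure = [&](int j) {
    if ((int)cc[j].size() == 0) {
      cc[j].assign(rlen[j], 0);
      tc[j].assign(rlen[j], 0);
    }
  };

  int i = 0;
  while (i < n) {
    int a = ord[i];
    int b = -1;
    if (i + 1 < n && frag_id[ord[i + 1]] == frag_id[a]) b = ord[i + 1];

    int ja = ref_id[a] - 1;
    if (ja < 0 || ja >= nref) stop("reference id out of range");
    const char* sa = CHAR(STRING_ELT(bases, a));
    const char* qa = CHAR(STRING_ELT(quals, a));
    int La = LENGTH(STRING_ELT(bases, a));
    int s0a = start[a] - 1;
    if (s0a < 0 || s0a + La > rlen[ja])
      stop("alignment record extends past chromosome end");
    ensure(ja);

    if (b < 0 || ref_id[b] != ref_id[a]) {
      // unpaired (or discordant refs, which the aligner never emits)
      for (int p = 0; p < La; ++p) {
        if (rptr[ja][s0a + p] != 'C') continue;
        char x = sa[p];
        if (x == 'C') cc[ja][s0a + p]++;
        else if (x == 'T') tc[ja][s0a + p]++;
      }
      if (b >= 0) {
        int jb = ref_id[b] - 1;
        const char* sb = CHAR(STRING_ELT(bases, b));
        int Lb = LENGTH(STRING_ELT(bases, b));
        int s0b = start[b] - 1;
        if (s0b < 0 || s0b + Lb > rlen[jb])
          stop("alignment record extends past chromosome end");
        ensure(jb);
        for (int p = 0; p < Lb; ++p) {
          if (rptr[jb][s0b + p] != 'C') continue;
          char x = sb[p];
          if (x == 'C') cc[jb][s0b + p]++;
          else if (x == 'T') tc[jb][s0b + p]++;
        }
        i += 2;
        continue;
      }
      i += 1;
      continue;
    }

    // proper pair on one strand reference: overlap-aware
    const char* sb = CHAR(STRING_ELT(bases, b));
    const char* qb = CHAR(STRING_ELT(quals, b));
    int Lb = LENGTH(STRING_ELT(bases, b));
    int s0b = start[b] - 1;
    if (s0b < 0 || s0b + Lb > rlen[ja])
      stop("alignment record extends past chromosome end");

    int lo = std::min(s0a, s0b);
    int hi = std::max(s0a + La, s0b + Lb); // exclusive
    for (int g = lo; g < hi; ++g) {
      if (rptr[ja][g] != 'C') continue;
      bool ina = g >= s0a && g < s0a + La;
      bool inb = g >= s0b && g < s0b + Lb;
      char x;
      if (ina && inb) {
        // higher base quality wins; tie -> mate 1 (record a)
        x = (qb[g - s0b] > qa[g - s0a]) ? sb[g - s0b] : sa[g - s0a];
      } else if (ina) {
        x = sa[g - s0a];
      } else if (inb) {
        x = sb[g - s0b];
      } else {
        continue;
      }
      if (x == 'C') cc[ja][g]++;
      else if (x == 'T') tc[ja][g]++;
    }
    i += 2;
  }

  // emit covered positions only
  std::vector<int> o_ref, o_pos, o_c, o_t;
  for (int j = 0; j < nref; ++j) {
    if ((int)cc[j].size() == 0) continue;
    for (int p = 0; p < rlen[j]; ++p) {
      int c = cc[j][p], t = tc[j][p];
      if (c + t > 0) {
        o_ref.push_back(j + 1);
        o_pos.push_back(p + 1);
        o_c.push_back(c);
        o_t.push_back(t);
      }
    }
  }
  return List::create(_["ref"] = o_ref, _["pos"] = o_pos,
                      _["c_count"] = o_c, _["t_count"] = o_t);
}
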