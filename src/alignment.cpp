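#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <set>
#include <cstdint>

using namespace Rcpp;

// 2-bit nucleotide code; -1 for anything that is not A/C/G/T.
static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// k-mer index: key -> flat positions encoded as ref_idx * stride + pos
typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KmerIndex;

static void index_refs(const std::vector<std::string>& refs, int k,
                       KmerIndex& idx, uint64_t stride) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string& s = refs[r];
    if ((int)s.size() < k) continue;
    uint64_t key = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2(s[i]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        idx[key].push_back((uint64_t)r * stride + (i - k + 1));
      }
    }
  }
}

// Encode a k-mer starting at pos; returns false if it contains non-ACGT.
static bool kmer_at(const std::string& s, size_t pos, int k, uint64_t& key) {
  if (pos + k > s.size()) return false;
  key = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2(s[pos + i]);
    if (b < 0) return false;
    key = (key << 2) | (uint64_t)b;
  }
  return true;
}

static inline int hamming_le(const std::string& a, const std::string& b,
                             size_t boff, int max_mm) {
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    char x = a[i], y = b[boff + i];
    if (x >= 'a') x -= 32;
    if (y >= 'a') y -= 32;
    if (x != y && ++mm > max_mm) return -1;
  }
  return mm;
}

// Non-overlapping pigeonhole seed offsets for a read of length L.
static std::vector<size_t> seed_offsets(size_t L, int k, int max_mm) {
  std::vector<size_t> off;
  int nchunk = max_mm + 1;
  size_t chunk = L / nchunk;
  if (chunk < (size_t)k) {
    // guarantee lost; fall back to a dense tiling of seeds
    for (size_t p = 0; p + k <= L; p += 1) off.push_back(p);
    return off;
  }
  for (int i = 0; i < nchunk; ++i) off.push_back((size_t)i * chunk);
  return off;
}

// All end-to-end (full read span) alignments of each read against each
// reference, either strand, with at most max_mm substitutions.
// Returns 0-based ref offsets; strand +1/-1; the minus-strand offset refers
// to the forward reference coordinate of the alignment's left end.
// [[Rcpp::export]]
DataFrame cpp_align_end_to_end(CharacterVector reads, CharacterVector refs,
                               int max_mm, int kmer) {
  std::vector<std::string> R(reads.size()), S(refs.size());
  uint64_t stride = 1;
  for (int i = 0; i < refs.size(); ++i) {
    S[i] = as<std::string>(refs[i]);
    if (S[i].size() + 1 > stride) stride = S[i].size() + 1;
  }
  for (int i = 0; i < reads.size(); ++i) R[i] = as<std::string>(reads[i]);

  KmerIndex idx;
  index_refs(S, kmer, idx, stride);

  std::vector<int> o_read, o_ref, o_pos, o_strand, o_mm;
  for (int ri = 0; ri < (int)R.size(); ++ri) {
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? R[ri] : revcomp(R[ri]);
      size_t L = q.size();
      if (L < (size_t)kmer) continue;
      std::set<std::pair<int, int> > seen;
      std::vector<size_t> offs = seed_offsets(L, kmer, max_mm);
      for (size_t oi = 0; oi < offs.size(); ++oi) {
        uint64_t key;
        if (!kmer_at(q, offs[oi], kmer, key)) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        const std::vector<uint64_t>& hits = it->second;
        for (size_t h = 0; h < hits.size(); ++h) {
          int refi = (int)(hits[h] / stride);
          long pos = (long)(hits[h] % stride) - (long)offs[oi];
          if (pos < 0 || (size_t)pos + L > S[refi].size()) continue;
          if (!seen.insert(std::make_pair(refi, (int)pos)).second) continue;
          int mm = hamming_le(q, S[refi], (size_t)pos, max_mm);
          if (mm < 0) continue;
          o_read.push_back(ri + 1);
          o_ref.push_back(refi + 1);
          o_pos.push_back((int)pos);
          o_strand.push_back(strand == 0 ? 1 : -1);
          o_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["read"] = o_read, _["ref"] = o_ref,
                           _["pos"] = o_pos, _["strand"] = o_strand,
                           _["mismatches"] = o_mm);
}

// TRUE for every read with at least one end-to-end alignment (either strand,
// <= max_mm substitutions) against any reference. Early-exit per read.
// [[Rcpp::export]]
LogicalVector cpp_match_any(CharacterVector reads, CharacterVector refs,
                            int max_mm, int kmer) {
  std::vector<std::string> R(reads.size()), S(refs.size());
  uint64_t stride = 1;
  for (int i = 0; i < refs.size(); ++i) {
    S[i] = as<std::string>(refs[i]);
    if (S[i].size() + 1 > stride) stride = S[i].size() + 1;
  }
  for (int i = 0; i < reads.size(); ++i) R[i] = as<std::string>(reads[i]);

  KmerIndex idx;
  index_refs(S, kmer, idx, stride);

  LogicalVector out(reads.size(), false);
  for (int ri = 0; ri < (int)R.size(); ++ri) {
    bool found = false;
    for (int strand = 0; strand < 2 && !found; ++strand) {
      std::string q = strand == 0 ? R[ri] : revcomp(R[ri]);
      size_t L = q.size();
      if (L < (size_t)kmer) continue;
      std::vector<size_t> offs = seed_offsets(L, kmer, max_mm);
      std::set<std::pair<int, int> > seen;
      for (size_t oi = 0; oi < offs.size() && !found; ++oi) {
        uint64_t key;
        if (!kmer_at(q, offs[oi], kmer, key)) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        const std::vector<uint64_t>& hits = it->second;
        for (size_t h = 0; h < hits.size() && !found; ++h) {
          int refi = (int)(hits[h] / stride);
          long pos = (long)(hits[h] % stride) - (long)offs[oi];
          if (pos < 0 || (size_t)pos + L > S[refi].size()) continue;
          if (!seen.insert(std::make_pair(refi, (int)pos)).second) continue;
          if (hamming_le(q, S[refi], (size_t)pos, max_mm) >= 0) found = true;
        }
      }
    }
    out[ri] = found;
  }
  return out;
}

// Exact-word seeding followed by greedy ungapped extension in both
// directions; a base is appended only while cumulative identity stays at or
// above min_identity. One hit (the best-scoring, score = matches -
// mismatches) per (read, reference) pair. Positions are 0-based.
// [[Rcpp::export]]
DataFrame cpp_seed_extend(CharacterVector reads, CharacterVector refs,
                          int word, double min_identity, int min_len) {
  std::vector<std::string> R(reads.size()), S(refs.size());
  uint64_t stride = 1;
  for (int i = 0; i < refs.size(); ++i) {
    S[i] = as<std::string>(refs[i]);
    if (S[i].size() + 1 > stride) stride = S[i].size() + 1;
  }
  for (int i = 0; i < reads.size(); ++i) R[i] = as<std::string>(reads[i]);

  KmerIndex idx;
  index_refs(S, word, idx, stride);

  std::vector<int> o_read, o_ref, o_strand, o_seed, o_len;
  std::vector<double> o_ident, o_score;

  for (int ri = 0; ri < (int)R.size(); ++ri) {
    // best per ref: score, then fields
    std::unordered_map<int, std::vector<double> > best;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? R[ri] : revcomp(R[ri]);
      size_t L = q.size();
      if (L < (size_t)word) continue;
      std::set<std::pair<int, long> > diag_seen; // (ref, diagonal)
      for (size_t p = 0; p + word <= L; ++p) {
        uint64_t key;
        if (!kmer_at(q, p, word, key)) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        const std::vector<uint64_t>& hits = it->second;
        for (size_t h = 0; h < hits.size(); ++h) {
          int refi = (int)(hits[h] / stride);
          long rp = (long)(hits[h] % stride);
          long diag = rp - (long)p;
          long dkey = strand == 0 ? diag : -diag - 1000000000L;
          if (!diag_seen.insert(std::make_pair(refi, dkey)).second) continue;
          const std::string& s = S[refi];
          // extend: current block [qlo,qhi) on read, matching s at diag+q
          long qlo = (long)p, qhi = (long)p + word;
          long matches = word, len = word;
          // left
          while (qlo > 0 && diag + qlo > 0) {
            char x = q[qlo - 1], y = s[diag + qlo - 1];
            if (x >= 'a') x -= 32;
            if (y >= 'a') y -= 32;
            long m2 = matches + (x == y && x != 'N' ? 1 : 0);
            if ((double)m2 / (double)(len + 1) < min_identity) break;
            --qlo; ++len; matches = m2;
          }
          // right
          while (qhi < (long)L && diag + qhi < (long)s.size()) {
            char x = q[qhi], y = s[diag + qhi];
            if (x >= 'a') x -= 32;
            if (y >= 'a') y -= 32;
            long m2 = matches + (x == y && x != 'N' ? 1 : 0);
            if ((double)m2 / (double)(len + 1) < min_identity) break;
            ++qhi; ++len; matches = m2;
          }
          if (len < min_len) continue;
          double ident = (double)matches / (double)len;
          double score = (double)matches - (double)(len - matches);
          std::vector<double>& b = best[refi];
          if (b.empty() || score > b[0]) {
            b.assign(6, 0.0);
            b[0] = score;
            b[1] = strand == 0 ? 1.0 : -1.0;
            b[2] = (double)(diag + p); // seed position on reference
            b[3] = (double)len;
            b[4] = ident;
          }
        }
      }
    }
    for (std::unordered_map<int, std::vector<double> >::iterator it =
             best.begin();
         it != best.end(); ++it) {
      o_read.push_back(ri + 1);
      o_ref.push_back(it->first + 1);
      o_score.push_back(it->second[0]);
      o_strand.push_back((int)it->second[1]);
      o_seed.push_back((int)it->second[2]);
      o_len.push_back((int)it->second[3]);
      o_ident.push_back(it->second[4]);
    }
  }
  return DataFrame::create(_["read"] = o_read, _["ref"] = o_ref,
                           _["strand"] = o_strand, _["seed_pos"] = o_seed,
                           _["length"] = o_len, _["identity"] = o_ident,
                           _["score"] = o_score);
}
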