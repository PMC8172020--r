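#include "circbin.h"

using namespace Rcpp;

typedef unsigned __int128 u128;

static inline int b2(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

struct Key128 {
  uint64_t hi, lo;
  bool operator==(const Key128 &o) const { return hi == o.hi && lo == o.lo; }
};
struct Key128Hash {
  size_t operator()(const Key128 &k) const {
    return (size_t)(k.hi * 0x9E3779B97F4A7C15ULL ^
                    (k.lo + 0x9E3779B97F4A7C15ULL + (k.hi << 6)));
  }
};

typedef std::unordered_set<Key128, Key128Hash> KmerSet;

static inline Key128 to_key(u128 v) {
  Key128 k;
  k.hi = (uint64_t)(v >> 64);
  k.lo = (uint64_t)v;
  return k;
}

// enumerate canonical k-mers of s, calling fn(canonical) for each clean window
template <typename F>
static void each_canonical(const std::string &s, int k, F fn) {
  int n = (int)s.size();
  if (n < k) return;
  u128 mask = (k == 64) ? ~(u128)0 : (((u128)1 << (2 * k)) - 1);
  u128 fwd = 0, rc = 0;
  int valid = 0; // clean bases accumulated
  for (int i = 0; i < n; ++i) {
    int b = b2(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (u128)b) & mask;
    rc = (rc >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) fn(fwd < rc ? fwd : rc);
  }
}

static std::string unpack(u128 v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = "ACGT"[(int)(v & 3)];
    v >>= 2;
  }
  return s;
}

static u128 pack_str(const std::string &s) {
  u128 v = 0;
  for (size_t i = 0; i < s.size(); ++i) v = (v << 2) | (u128)b2(s[i]);
  return v;
}

// [[Rcpp::export]]
CharacterVector build_kmer_index_cpp(CharacterVector seqs, int k) {
  KmerSet set;
  std::vector<u128> raw;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    each_canonical(s, k, [&](u128 v) {
      Key128 key = to_key(v);
      if (set.insert(key).second) raw.push_back(v);
    });
  }
  std::sort(raw.begin(), raw.end());
  CharacterVector out(raw.size());
  for (size_t i = 0; i < raw.size(); ++i) out[i] = unpack(raw[i], k);
  return out;
}

static KmerSet set_from_chr(const CharacterVector &kmers) {
  KmerSet set;
  set.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    set.insert(to_key(pack_str(as<std::string>(kmers[i]))));
  return set;
}

static int count_hits(const std::string &s, int k, const KmerSet &set,
                      int cap) {
  int n = 0;
  each_canonical(s, k, [&](u128 v) {
    if (n >= cap) return;
    if (set.count(to_key(v))) ++n;
  });
  return n;
}

// [[Rcpp::export]]
LogicalVector bait_cpp(CharacterVector seq1, CharacterVector seq2,
                       CharacterVector kmers, int k, int min_hits) {
  KmerSet set = set_from_chr(kmers);
  R_xlen_t n = seq1.size();
  LogicalVector keep(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string m1 = as<std::string>(seq1[i]);
    bool hit = count_hits(m1, k, set, min_hits) >= min_hits;
    if (!hit) {
      std::string m2 = as<std::string>(seq2[i]);
      hit = count_hits(m2, k, set, min_hits) >= min_hits;
    }
    keep[i] = hit;
  }
  return keep;
}

// assign each read to the contig sharing most sampled canonical k-mers
// (coverage estimation); returns 0-based contig index or -1
// [[Rcpp::export]]
IntegerVector assign_reads_cpp(CharacterVector reads, CharacterVector contigs,
                               int k, int step) {
  std::unordered_map<Key128, int, Key128Hash> owner;
  for (R_xlen_t c = 0; c < contigs.size(); ++c) {
    std::string s = as<std::string>(contigs[c]);
    each_canonical(s, k, [&](u128 v) {
      Key128 key = to_key(v);
      auto it = owner.find(key);
      if (it == owner.end()) owner[key] = (int)c;
      else if (it->second != (int)c) it->second = -2; // shared: uninformative
    });
  }
  IntegerVector out(reads.size());
  std::vector<int> tally(contigs.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::fill(tally.begin(), tally.end(), 0);
    std::string s = as<std::string>(reads[i]);
    int pos = 0;
    each_canonical(s, k, [&](u128 v) {
      if ((pos++ % step) != 0) return;
      auto it = owner.find(to_key(v));
      if (it != owner.end() && it->second >= 0) ++tally[it->second];
    });
    int best = -1, bc = 0;
    for (size_t c = 0; c < tally.size(); ++c)
      if (tally[c] > bc) { bc = tally[c]; best = (int)c; }
    out[i] = best;
  }
  return out;
}
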