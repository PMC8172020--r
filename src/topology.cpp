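#include "circbin.h"

using namespace Rcpp;

// Exact-substring mapping of mates against a genome.  A mate maps if it is a
// verbatim substring of the genome (position found through a 31-mer anchor
// at the read start, so any sequencing error prevents mapping -- intended:
// only perfect reads provide positional evidence).  Returns 1-based start
// positions and strands (+1/-1), NA when unmapped.

static const int AK = 31;

static inline int b2t(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static bool pack64(const std::string &s, int pos, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = b2t(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

typedef std::unordered_map<uint64_t, std::vector<int>> PosMap;

static PosMap index_genome(const std::string &g) {
  PosMap pm;
  if ((int)g.size() < AK) return pm;
  pm.reserve(g.size() * 2);
  uint64_t mask = (1ULL << (2 * AK)) - 1;
  uint64_t v = 0;
  int valid = 0;
  for (int i = 0; i < (int)g.size(); ++i) {
    int b = b2t(g[i]);
    if (b < 0) { valid = 0; v = 0; continue; }
    v = ((v << 2) | (uint64_t)b) & mask;
    if (++valid >= AK) pm[v].push_back(i - AK + 1);
  }
  return pm;
}

static bool locate(const std::string &g, const PosMap &pm,
                   const std::string &read, int &pos, int &strand) {
  if ((int)read.size() < AK) return false;
  for (int o = 0; o < 2; ++o) {
    std::string r = (o == 0) ? read : cb_revcomp(read);
    uint64_t key;
    if (!pack64(r, 0, AK, key)) return false;
    auto it = pm.find(key);
    if (it != pm.end()) {
      for (size_t c = 0; c < it->second.size(); ++c) {
        int p = it->second[c];
        if (p + (int)r.size() <= (int)g.size() &&
            g.compare(p, r.size(), r) == 0) {
          pos = p + 1;
          strand = (o == 0) ? 1 : -1;
          return true;
        }
      }
    }
  }
  return false;
}

// [[Rcpp::export]]
List map_mates_cpp(std::string genome, CharacterVector seq1,
                   CharacterVector seq2) {
  PosMap pm = index_genome(genome);
  R_xlen_t n = seq1.size();
  IntegerVector p1(n, NA_INTEGER), p2(n, NA_INTEGER);
  IntegerVector s1(n, NA_INTEGER), s2(n, NA_INTEGER);
  IntegerVector l1(n, NA_INTEGER), l2(n, NA_INTEGER);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(seq1[i]);
    std::string b = as<std::string>(seq2[i]);
    int pos, strand;
    if (locate(genome, pm, a, pos, strand)) {
      p1[i] = pos; s1[i] = strand; l1[i] = (int)a.size();
    }
    if (locate(genome, pm, b, pos, strand)) {
      p2[i] = pos; s2[i] = strand; l2[i] = (int)b.size();
    }
  }
  return List::create(_["pos1"] = p1, _["strand1"] = s1, _["len1"] = l1,
                      _["pos2"] = p2, _["strand2"] = s2, _["len2"] = l2);
}
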