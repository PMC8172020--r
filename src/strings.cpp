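#include "circbin.h"

using namespace Rcpp;

char cb_comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'N': return 'N';
  default: return 0;
  }
}

std::string cb_revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = cb_comp(s[s.size() - 1 - i]);
    if (c == 0)
      stop("invalid character '%c' in sequence (alphabet is A,C,G,T,N)",
           s[s.size() - 1 - i]);
    out[i] = c;
  }
  return out;
}

// longest proper prefix that is also a suffix (KMP failure of last position)
int cb_border(const std::string &s) {
  int n = (int)s.size();
  if (n <= 1) return 0;
  std::vector<int> pi(n, 0);
  for (int i = 1; i < n; ++i) {
    int j = pi[i - 1];
    while (j > 0 && s[i] != s[j]) j = pi[j - 1];
    if (s[i] == s[j]) ++j;
    pi[i] = j;
  }
  return pi[n - 1];
}

std::vector<int> cb_zarray(const std::string &s) {
  int n = (int)s.size();
  std::vector<int> z(n, 0);
  if (n == 0) return z;
  z[0] = n;
  int l = 0, r = 0;
  for (int i = 1; i < n; ++i) {
    if (i < r) z[i] = std::min(r - i, z[i - l]);
    while (i + z[i] < n && s[z[i]] == s[i + z[i]]) ++z[i];
    if (i + z[i] > r) { l = i; r = i + z[i]; }
  }
  return z;
}

// longest suffix of a equal to a prefix of b (<= min(|a|,|b|))
int cb_suffix_prefix_overlap(const std::string &a, const std::string &b) {
  if (a.empty() || b.empty()) return 0;
  std::string s = b + '\x01' + a;
  std::vector<int> z = cb_zarray(s);
  int n = (int)s.size(), best = 0;
  int amax = (int)std::min(a.size(), b.size());
  for (int i = (int)b.size() + 1; i < n; ++i) {
    if (i + z[i] == n) {
      int len = n - i;
      if (len <= amax && len > best) best = len;
    }
  }
  return best;
}

bool cb_contains(const std::string &hay, const std::string &needle) {
  return hay.find(needle) != std::string::npos;
}

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

bool cb_pack(const std::string &s, size_t pos, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bit(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

uint64_t cb_pack_rc(uint64_t key, int k) {
  uint64_t out = 0;
  for (int i = 0; i < k; ++i) {
    out = (out << 2) | (3 - (key & 3));
    key >>= 2;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector rc_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    out[i] = cb_revcomp(as<std::string>(seqs[i]));
  }
  out.attr("names") = seqs.attr("names");
  return out;
}

// [[Rcpp::export]]
int border_cpp(std::string seq) { return cb_border(seq); }

// [[Rcpp::export]]
int suffix_prefix_overlap_cpp(std::string a, std::string b) {
  return cb_suffix_prefix_overlap(a, b);
}

// ---------------------------------------------------------------------------
// Exact longest repeat, both strands, excluding the designated terminal pair.
//
// A repeat is a pair of distinct intervals of the sequence whose contents
// match directly or as reverse complements.  Windows containing N never
// match.  Excluded pairs: direct matches at offset exactly L - t (the
// terminal-copy correspondence of a candidate circular contig) and a
// palindromic window matching its own reverse complement at the identical
// interval.  Strategy: seed-and-extend on duplicated 32-mers for answers
// >= 32, otherwise an exact descending scan over window lengths 31..1.
// ---------------------------------------------------------------------------

struct Occ { int pos; int flag; }; // flag 0 = fwd, 1 = rc, 2 = palindromic

static int longest_repeat_seeded(const std::string &s, int t) {
  const int K = 32;
  int L = (int)s.size();
  if (L < K) return 0;
  std::unordered_map<uint64_t, std::vector<Occ>> groups;
  groups.reserve((size_t)L * 2);
  for (int i = 0; i + K <= L; ++i) {
    uint64_t kf;
    if (!cb_pack(s, i, K, kf)) continue;
    uint64_t kr = cb_pack_rc(kf, K);
    if (kf == kr) groups[kf].push_back({i, 2});
    else if (kf < kr) groups[kf].push_back({i, 0});
    else groups[kr].push_back({i, 1});
  }
  long long excl_off = (long long)L - t;
  int best = 0;
  for (auto &kv : groups) {
    std::vector<Occ> &occ = kv.second;
    if (occ.size() < 2) continue;
    for (size_t a = 0; a < occ.size(); ++a) {
      for (size_t b = a + 1; b < occ.size(); ++b) {
        int i = occ[a].pos, j = occ[b].pos; // i < j by construction order
        int fa = occ[a].flag, fb = occ[b].flag;
        bool direct = (fa == fb) || fa == 2 || fb == 2;
        bool inverted = (fa != fb) || fa == 2 || fb == 2;
        if (direct && s.compare(i, K, s, j, K) == 0) {
          // left-maximal dedup: a longer match covering this seed was (or
          // will be) reached from the seed one position to the left
          if (!(i > 0 && j > 0 && s[i - 1] == s[j - 1] &&
                base2bit(s[i - 1]) >= 0)) {
            int ext_l = 0, ext_r = 0;
            while (i - ext_l - 1 >= 0 &&
                   s[i - ext_l - 1] == s[j - ext_l - 1] &&
                   base2bit(s[i - ext_l - 1]) >= 0)
              ++ext_l;
            while (j + K + ext_r < L &&
                   s[i + K + ext_r] == s[j + K + ext_r] &&
                   base2bit(s[i + K + ext_r]) >= 0)
              ++ext_r;
            int M = K + ext_l + ext_r;
            if ((long long)(j - i) != excl_off && M > best) best = M;
          }
        }
        if (inverted) {
          // inverted match: s[i..i+K) == revcomp(s[j..j+K)) ?
          bool ok = true;
          for (int x = 0; x < K; ++x) {
            if (s[i + x] != cb_comp(s[j + K - 1 - x])) { ok = false; break; }
          }
          if (ok) {
            // left-maximal in i direction pairs with right of j
            if (!(i > 0 && j + K < L && base2bit(s[i - 1]) >= 0 &&
                  s[i - 1] == cb_comp(s[j + K]))) {
              int ea = 0, eb = 0;
              while (i - ea - 1 >= 0 && j + K + ea < L &&
                     base2bit(s[i - ea - 1]) >= 0 &&
                     s[i - ea - 1] == cb_comp(s[j + K + ea]))
                ++ea;
              while (i + K + eb < L && j - eb - 1 >= 0 &&
                     base2bit(s[i + K + eb]) >= 0 &&
                     s[i + K + eb] == cb_comp(s[j - eb - 1]))
                ++eb;
              int M = K + ea + eb;
              int I = i - ea, J = j - eb;
              if (!(I == J)) { // identical interval = self-mirror palindrome
                if (M > best) best = M;
              }
            }
          }
        }
      }
    }
  }
  return best >= K ? best : 0;
}

// exact check for small lengths 31..1 (used when no repeat >= 32 exists)
static int longest_repeat_small(const std::string &s, int t) {
  int L = (int)s.size();
  long long excl_off = (long long)L - t;
  for (int k = std::min(31, L - 1); k >= 1; --k) {
    std::unordered_map<uint64_t, std::vector<Occ>> groups;
    for (int i = 0; i + k <= L; ++i) {
      uint64_t kf;
      if (!cb_pack(s, i, k, kf)) continue;
      uint64_t kr = cb_pack_rc(kf, k);
      if (kf == kr) groups[kf].push_back({i, 2});
      else if (kf < kr) groups[kf].push_back({i, 0});
      else groups[kr].push_back({i, 1});
    }
    for (auto &kv : groups) {
      std::vector<Occ> &occ = kv.second;
      if (occ.size() == 1) continue; // lone palindrome excluded (self-mirror)
      if (occ.size() >= 3) return k; // some pair is always admissible
      int i = occ[0].pos, j = occ[1].pos;
      bool mixed = (occ[0].flag != occ[1].flag) || occ[0].flag == 2 ||
                   occ[1].flag == 2;
      if (mixed) return k;               // inverted pair, distinct intervals
      if ((long long)(j - i) != excl_off) return k; // direct, non-terminal
    }
  }
  return 0;
}

// [[Rcpp::export]]
int longest_repeat_cpp(std::string seq, int t) {
  int big = longest_repeat_seeded(seq, t);
  if (big > 0) return big;
  return longest_repeat_small(seq, t);
}

// count occurrences of `pat` in `seq` on both strands (overlapping allowed).
// A palindromic pattern's forward and reverse occurrences at the same
// interval are counted once.
// [[Rcpp::export]]
int count_occurrences_cpp(std::string seq, std::string pat) {
  if (pat.empty() || pat.size() > seq.size()) return 0;
  std::string rc = cb_revcomp(pat);
  int n = 0;
  for (size_t pos = seq.find(pat); pos != std::string::npos;
       pos = seq.find(pat, pos + 1))
    ++n;
  if (rc != pat) {
    for (size_t pos = seq.find(rc); pos != std::string::npos;
         pos = seq.find(rc, pos + 1))
      ++n;
  }
  return n;
}
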