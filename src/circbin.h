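#ifndef CIRCBIN_H
#define CIRCBIN_H

#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>

// shared low-level helpers (defined in strings.cpp)
char cb_comp(char c);
std::string cb_revcomp(const std::string &s);
int cb_border(const std::string &s);
std::vector<int> cb_zarray(const std::string &s);
int cb_suffix_prefix_overlap(const std::string &a, const std::string &b);
bool cb_contains(const std::string &hay, const std::string &needle);

// 2-bit packing; returns false if any non-ACGT char in window
bool cb_pack(const std::string &s, size_t pos, int k, uint64_t &out);
uint64_t cb_pack_rc(uint64_t key, int k);

#endif
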