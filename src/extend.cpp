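#include "circbin.h"
#include <climits>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Read-coherent consensus extension.
//
// The 3' end of a contig grows base by base.  A read votes while its exact
// alignment against the trailing `min_overlap` window of the growing
// sequence holds (a mismatching vote suspends the read until the mismatch
// leaves the window).  Reads join when one of their anchor windows (taken at
// offsets 0, mo, 2*mo, ... within the read, either orientation) equals the
// current terminal window.  Extension halts on low support, on a tie, on a
// balanced conflict (runner-up base supported by >= min_support reads and by
// more than a quarter of the winner's support), or at max_step.
// ---------------------------------------------------------------------------

static inline uint64_t fnv64(const char *p, int n) {
  uint64_t h = 1469598103934665603ULL;
  for (int i = 0; i < n; ++i) {
    h ^= (unsigned char)p[i];
    h *= 1099511628211ULL;
  }
  return h;
}

static inline int base2bit_e(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

struct AnchorEntry { int read; int orient; int offset; };

struct AnchorMap {
  int mo;
  std::unordered_map<uint64_t, std::vector<AnchorEntry>> map;
};

static bool window_clean(const char *p, int n) {
  return memchr(p, 'N', (size_t)n) == NULL;
}

static void build_anchor_map(AnchorMap &am,
                             const std::vector<std::string> &fwd,
                             const std::vector<std::string> &rcv, int mo) {
  am.mo = mo;
  am.map.reserve(fwd.size() * 4);
  for (int o = 0; o < 2; ++o) {
    const std::vector<std::string> &v = (o == 0) ? fwd : rcv;
    for (size_t r = 0; r < v.size(); ++r) {
      const std::string &s = v[r];
      for (int off = 0; off + mo < (int)s.size(); off += mo) {
        if (!window_clean(s.data() + off, mo)) continue;
        am.map[fnv64(s.data() + off, mo)].push_back(
            {(int)r, o, off});
      }
    }
  }
}

struct Active { int read; int orient; int next; int last_mm; };

static std::string extend_core(const std::string &contig,
                               const std::vector<std::string> &fwd,
                               const std::vector<std::string> &rcv,
                               const AnchorMap &am, int mo, int min_support,
                               int max_step) {
  int clen = (int)contig.size();
  if (clen < mo) return std::string();
  // tail = trailing window of contig + everything appended so far
  std::string tail = contig.substr(clen - mo);
  std::string ext;
  std::vector<Active> act;
  std::vector<std::vector<uint8_t>> joined(2);
  joined[0].assign(fwd.size(), 0);
  joined[1].assign(fwd.size(), 0);

  // seed with reads that already overlap the current end anywhere
  const std::string &w0 = tail;
  if (!window_clean(w0.data(), mo)) return std::string();
  for (int o = 0; o < 2; ++o) {
    const std::vector<std::string> &v = (o == 0) ? fwd : rcv;
    for (size_t r = 0; r < v.size(); ++r) {
      const std::string &s = v[r];
      size_t pos = s.find(w0);
      while (pos != std::string::npos && pos + mo >= s.size())
        pos = s.find(w0, pos + 1);
      if (pos != std::string::npos) {
        act.push_back({(int)r, o, (int)pos + mo, INT_MIN});
        joined[o][r] = 1;
      }
    }
  }

  for (int t = 0; t < max_step; ++t) {
    int counts[4] = {0, 0, 0, 0};
    for (size_t a = 0; a < act.size(); ++a) {
      const Active &A = act[a];
      if (A.last_mm != INT_MIN && t - A.last_mm < mo) continue;
      const std::string &s = (A.orient == 0) ? fwd[A.read] : rcv[A.read];
      int b = base2bit_e(s[A.next]);
      if (b >= 0) ++counts[b];
    }
    int wi = 0;
    for (int b = 1; b < 4; ++b)
      if (counts[b] > counts[wi]) wi = b;
    int c1 = counts[wi], c2 = 0;
    for (int b = 0; b < 4; ++b)
      if (b != wi && counts[b] > c2) c2 = counts[b];
    if (c1 < min_support) break;
    if (c2 == c1) break;                       // consensus tie
    if (c2 >= min_support && 4 * c2 > c1) break; // balanced conflict
    char base = "ACGT"[wi];
    ext.push_back(base);
    tail.push_back(base);
    // advance / suspend / retire voters
    size_t keep = 0;
    for (size_t a = 0; a < act.size(); ++a) {
      Active A = act[a];
      const std::string &s = (A.orient == 0) ? fwd[A.read] : rcv[A.read];
      if (s[A.next] != base) A.last_mm = t;
      ++A.next;
      if (A.next < (int)s.size()) act[keep++] = A;
    }
    act.resize(keep);
    // recruit reads whose anchor matches the new terminal window
    const char *wp = tail.data() + tail.size() - mo;
    if (window_clean(wp, mo)) {
      auto it = am.map.find(fnv64(wp, mo));
      if (it != am.map.end()) {
        for (size_t e = 0; e < it->second.size(); ++e) {
          const AnchorEntry &ae = it->second[e];
          if (joined[ae.orient][ae.read]) continue;
          const std::string &s =
              (ae.orient == 0) ? fwd[ae.read] : rcv[ae.read];
          if (s.compare(ae.offset, mo, wp, mo) != 0) continue;
          act.push_back({ae.read, ae.orient, ae.offset + mo, INT_MIN});
          joined[ae.orient][ae.read] = 1;
        }
      }
    }
  }
  return ext;
}

static std::vector<std::string> orient_reads(const CharacterVector &reads,
                                             std::vector<std::string> &rcv) {
  std::vector<std::string> fwd;
  fwd.reserve(reads.size());
  rcv.reserve(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    fwd.push_back(as<std::string>(reads[i]));
    rcv.push_back(cb_revcomp(fwd.back()));
  }
  return fwd;
}

// [[Rcpp::export]]
std::string extend_end_cpp(std::string contig, CharacterVector reads,
                           int min_overlap, int min_support, int max_step) {
  std::vector<std::string> rcv;
  std::vector<std::string> fwd = orient_reads(reads, rcv);
  AnchorMap am;
  build_anchor_map(am, fwd, rcv, min_overlap);
  return extend_core(contig, fwd, rcv, am, min_overlap, min_support,
                     max_step);
}

// ---------------------------------------------------------------------------
// Contig merging on exact end overlaps.
//
// Ends are merged only when the pairing is unambiguous: both participating
// ends must have exactly one overlap partner of length >= min_overlap
// (a contig's own terminal self-overlap counts towards that degree).  The
// longest eligible overlap is fused first; ties break on contig ids.
// ---------------------------------------------------------------------------

struct Edge {
  int x, y;      // indices, x < y
  int type;      // 0: x.E1-y.E0; 1: y.E1-x.E0; 2: x.E1-y.E1; 3: x.E0-y.E0
  int len;
};

struct Ctg { std::string id; std::string seq; };

static void edge_ends(const Edge &e, int &ax, int &ay) {
  // returns which end of x (0/1) and of y the edge uses
  switch (e.type) {
  case 0: ax = 1; ay = 0; break;
  case 1: ax = 0; ay = 1; break;
  case 2: ax = 1; ay = 1; break;
  default: ax = 0; ay = 0; break;
  }
}

static bool merge_pass(std::vector<Ctg> &ctgs, int mo) {
  bool any = false;
  while (true) {
    int n = (int)ctgs.size();
    if (n < 2) return any;
    std::vector<Edge> edges;
    std::vector<int> deg(2 * n, 0);
    for (int x = 0; x < n; ++x) {
      int self = cb_border(ctgs[x].seq);
      if (self >= mo) { ++deg[2 * x]; ++deg[2 * x + 1]; }
    }
    for (int x = 0; x < n; ++x) {
      for (int y = x + 1; y < n; ++y) {
        std::string rcy = cb_revcomp(ctgs[y].seq);
        int l0 = cb_suffix_prefix_overlap(ctgs[x].seq, ctgs[y].seq);
        int l1 = cb_suffix_prefix_overlap(ctgs[y].seq, ctgs[x].seq);
        int l2 = cb_suffix_prefix_overlap(ctgs[x].seq, rcy);
        int l3 = cb_suffix_prefix_overlap(rcy, ctgs[x].seq);
        int ls[4] = {l0, l1, l2, l3};
        for (int ty = 0; ty < 4; ++ty) {
          if (ls[ty] >= mo) {
            Edge e = {x, y, ty, ls[ty]};
            int ax, ay;
            edge_ends(e, ax, ay);
            ++deg[2 * x + ax];
            ++deg[2 * y + ay];
            edges.push_back(e);
          }
        }
      }
    }
    int best = -1;
    for (size_t i = 0; i < edges.size(); ++i) {
      int ax, ay;
      edge_ends(edges[i], ax, ay);
      if (deg[2 * edges[i].x + ax] != 1 || deg[2 * edges[i].y + ay] != 1)
        continue;
      if (best < 0 || edges[i].len > edges[best].len ||
          (edges[i].len == edges[best].len &&
           (ctgs[edges[i].x].id < ctgs[edges[best].x].id ||
            (ctgs[edges[i].x].id == ctgs[edges[best].x].id &&
             ctgs[edges[i].y].id < ctgs[edges[best].y].id))))
        best = (int)i;
    }
    if (best < 0) return any;
    Edge e = edges[best];
    const std::string &sx = ctgs[e.x].seq;
    const std::string &sy = ctgs[e.y].seq;
    std::string fused;
    switch (e.type) {
    case 0: fused = sx + sy.substr(e.len); break;
    case 1: fused = sy + sx.substr(e.len); break;
    case 2: fused = sx + cb_revcomp(sy).substr(e.len); break;
    default: fused = cb_revcomp(sy) + sx.substr(e.len); break;
    }
    std::string id = std::min(ctgs[e.x].id, ctgs[e.y].id);
    std::vector<Ctg> next;
    for (int i = 0; i < (int)ctgs.size(); ++i)
      if (i != e.x && i != e.y) next.push_back(ctgs[i]);
    next.push_back({id, fused});
    std::sort(next.begin(), next.end(),
              [](const Ctg &a, const Ctg &b) { return a.id < b.id; });
    ctgs.swap(next);
    any = true;
  }
}

// drop contigs that are substrings of another (either orientation)
static bool dedup_pass(std::vector<Ctg> &ctgs) {
  std::vector<int> idx(ctgs.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (ctgs[a].seq.size() != ctgs[b].seq.size())
      return ctgs[a].seq.size() > ctgs[b].seq.size();
    return ctgs[a].id < ctgs[b].id;
  });
  std::vector<Ctg> kept;
  bool dropped = false;
  for (size_t ii = 0; ii < idx.size(); ++ii) {
    const Ctg &c = ctgs[idx[ii]];
    bool contained = false;
    std::string rc;
    for (size_t j = 0; j < kept.size(); ++j) {
      if (cb_contains(kept[j].seq, c.seq)) { contained = true; break; }
      if (rc.empty()) rc = cb_revcomp(c.seq);
      if (cb_contains(kept[j].seq, rc)) { contained = true; break; }
    }
    if (contained) dropped = true;
    else kept.push_back(c);
  }
  std::sort(kept.begin(), kept.end(),
            [](const Ctg &a, const Ctg &b) { return a.id < b.id; });
  ctgs.swap(kept);
  return dropped;
}

static std::vector<Ctg> make_ctgs(const CharacterVector &seqs) {
  CharacterVector nm = seqs.names();
  std::vector<Ctg> ctgs;
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    ctgs.push_back({as<std::string>(nm[i]), as<std::string>(seqs[i])});
  std::sort(ctgs.begin(), ctgs.end(),
            [](const Ctg &a, const Ctg &b) { return a.id < b.id; });
  return ctgs;
}

static CharacterVector ctgs_out(const std::vector<Ctg> &ctgs) {
  CharacterVector out(ctgs.size());
  CharacterVector nm(ctgs.size());
  for (size_t i = 0; i < ctgs.size(); ++i) {
    out[i] = ctgs[i].seq;
    nm[i] = ctgs[i].id;
  }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
CharacterVector merge_contigs_cpp(CharacterVector seqs, int min_overlap) {
  std::vector<Ctg> ctgs = make_ctgs(seqs);
  merge_pass(ctgs, min_overlap);
  return ctgs_out(ctgs);
}

// [[Rcpp::export]]
CharacterVector reassemble_cpp(CharacterVector seqs, CharacterVector reads,
                               int min_overlap, int min_support, int max_step,
                               int max_rounds, int self_overlap_cap) {
  std::vector<Ctg> ctgs = make_ctgs(seqs);
  std::vector<std::string> rcv;
  std::vector<std::string> fwd = orient_reads(reads, rcv);
  AnchorMap am;
  build_anchor_map(am, fwd, rcv, min_overlap);
  for (int round = 0; round < max_rounds; ++round) {
    bool changed = false;
    for (size_t c = 0; c < ctgs.size(); ++c) {
      if (cb_border(ctgs[c].seq) >= self_overlap_cap) continue;
      std::string e3 = extend_core(ctgs[c].seq, fwd, rcv, am, min_overlap,
                                   min_support, max_step);
      if (!e3.empty()) { ctgs[c].seq += e3; changed = true; }
      if (cb_border(ctgs[c].seq) >= self_overlap_cap) continue;
      std::string rcs = cb_revcomp(ctgs[c].seq);
      std::string e5 = extend_core(rcs, fwd, rcv, am, min_overlap,
                                   min_support, max_step);
      if (!e5.empty()) {
        ctgs[c].seq = cb_revcomp(rcs + e5);
        changed = true;
      }
    }
    if (merge_pass(ctgs, min_overlap)) changed = true;
    if (dedup_pass(ctgs)) changed = true;
    if (!changed) break;
  }
  return ctgs_out(ctgs);
}
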