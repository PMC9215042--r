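// Core sequence machinery: strand-canonical rolling k-mer hashing, the
// Bloom filter membership index, canonical k-mer counting, and unitig
// construction by chain compaction of a node-centric de Bruijn graph.
//
// Hashing: a multiplicative rolling hash (odd 64-bit multiplier, arithmetic
// mod 2^64) is maintained for the forward window and for its reverse
// complement; the canonical value is the minimum of the two, finalized with
// a splitmix64 mix. h bit positions are derived by double hashing
// (Kirsch-Mitzenmacher). Only membership behaviour matters downstream; the
// canonical and no-false-negative properties are what the tests pin.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <map>
#include <set>
#include <algorithm>

using namespace Rcpp;

static const uint64_t MULT = 0x9E3779B97F4A7C15ULL; // odd -> invertible mod 2^64

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static uint64_t mult_inverse() {
  // Newton iteration for the inverse of MULT mod 2^64
  uint64_t inv = 1;
  for (int i = 0; i < 6; ++i) inv *= 2 - MULT * inv;
  return inv;
}
static const uint64_t MULT_INV = mult_inverse();

static uint64_t mult_pow(int e) {
  uint64_t r = 1;
  for (int i = 0; i < e; ++i) r *= MULT;
  return r;
}

// Rolling state over one window of size k: fwd is the polynomial hash of
// the window, rcv the polynomial hash of its reverse complement.
struct RollState {
  uint64_t fwd, rcv;
  int k;
  uint64_t pk1; // MULT^(k-1)
};

// Initialize from seq[pos, pos+k); returns false on non-ACGT.
static bool roll_init(const char* s, int pos, int k, RollState& st) {
  st.k = k;
  st.pk1 = mult_pow(k - 1);
  uint64_t f = 0, r = 0, pj = 1;
  for (int j = 0; j < k; ++j, pj *= MULT) {
    int c = base_code(s[pos + j]);
    if (c < 0) return false;
    f = f * MULT + (uint64_t)c;
    r += (uint64_t)(3 - c) * pj;
  }
  st.fwd = f;
  st.rcv = r;
  return true;
}

// Slide one base to the right: drop s[pos], add s[pos+k].
static bool roll_step(const char* s, int pos, RollState& st) {
  int cout_ = base_code(s[pos]);
  int cin_ = base_code(s[pos + st.k]);
  if (cout_ < 0 || cin_ < 0) return false;
  st.fwd = (st.fwd - (uint64_t)cout_ * st.pk1) * MULT + (uint64_t)cin_;
  st.rcv = (st.rcv - (uint64_t)(3 - cout_)) * MULT_INV +
           (uint64_t)(3 - cin_) * st.pk1;
  return true;
}

static inline uint64_t canonical_value(const RollState& st) {
  return st.fwd < st.rcv ? st.fwd : st.rcv;
}

static inline void derive_hashes(uint64_t canon, int h, uint64_t nbits,
                                 uint64_t* out) {
  uint64_t v1 = splitmix64(canon ^ 0xA5A5A5A55A5A5A5AULL);
  uint64_t v2 = splitmix64(canon ^ 0x0F0F0F0FF0F0F0F0ULL) | 1ULL;
  for (int j = 0; j < h; ++j) out[j] = (v1 + (uint64_t)j * v2) % nbits;
}

// ---------------------------------------------------------------- Bloom --

struct BloomFilter {
  std::vector<uint64_t> words;
  uint64_t nbits;
  int h;
  int k;
  double n_inserted;
  BloomFilter(uint64_t nbits_, int h_, int k_)
    : words((nbits_ + 63) / 64, 0ULL), nbits(nbits_), h(h_), k(k_),
      n_inserted(0) {}
  inline void set_bit(uint64_t i) { words[i >> 6] |= (1ULL << (i & 63)); }
  inline bool get_bit(uint64_t i) const {
    return (words[i >> 6] >> (i & 63)) & 1ULL;
  }
  void insert(uint64_t canon) {
    uint64_t idx[64];
    derive_hashes(canon, h, nbits, idx);
    for (int j = 0; j < h; ++j) set_bit(idx[j]);
    n_inserted += 1;
  }
  bool query(uint64_t canon) const {
    uint64_t idx[64];
    derive_hashes(canon, h, nbits, idx);
    for (int j = 0; j < h; ++j)
      if (!get_bit(idx[j])) return false;
    return true;
  }
};

typedef XPtr<BloomFilter> BloomXPtr;

// [[Rcpp::export]]
SEXP cpp_bf_new(double nbits, int h, int k) {
  if (nbits < 64) stop("Bloom filter must have at least 64 bits");
  if (h < 1 || h > 64) stop("hash count h must be in [1, 64]");
  if (k < 1) stop("k must be positive");
  BloomFilter* bf = new BloomFilter((uint64_t)nbits, h, k);
  return BloomXPtr(bf, true);
}

// [[Rcpp::export]]
List cpp_bf_info(SEXP xp) {
  BloomXPtr bf(xp);
  return List::create(_["nbits"] = (double)bf->nbits, _["h"] = bf->h,
                      _["k"] = bf->k, _["n_inserted"] = bf->n_inserted);
}

// [[Rcpp::export]]
double cpp_bf_popcount(SEXP xp) {
  BloomXPtr bf(xp);
  double n = 0;
  for (size_t i = 0; i < bf->words.size(); ++i)
    n += __builtin_popcountll(bf->words[i]);
  return n;
}

// Insert the first per_read k-mers (5'-anchored) of each read. Reads whose
// first k + per_read - 1 bases contain a non-ACGT symbol are skipped whole;
// returns the skip count. Reads shorter than k + per_read - 1 are an error
// (callers enforce the read-length precondition).
// [[Rcpp::export]]
int cpp_bf_insert_reads(SEXP xp, CharacterVector reads, int per_read) {
  BloomXPtr bf(xp);
  int k = bf->k, skipped = 0;
  int need = k + per_read - 1;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int n = (int)LENGTH(STRING_ELT(reads, i));
    if (n < need)
      stop("read %d is shorter (%d bp) than k + t - 1 = %d bp", (int)(i + 1),
           n, need);
    RollState st;
    if (!roll_init(s, 0, k, st)) { ++skipped; continue; }
    bool ok = true;
    // validate the remaining needed bases up front so a bad read is
    // skipped atomically rather than partially inserted
    for (int p = k; p < need; ++p)
      if (base_code(s[p]) < 0) { ok = false; break; }
    if (!ok) { ++skipped; continue; }
    bf->insert(canonical_value(st));
    for (int p = 1; p < per_read; ++p) {
      roll_step(s, p - 1, st);
      bf->insert(canonical_value(st));
    }
  }
  return skipped;
}

// Insert whole strings, each exactly one k-mer.
// [[Rcpp::export]]
void cpp_bf_insert_kmers(SEXP xp, CharacterVector kmers) {
  BloomXPtr bf(xp);
  int k = bf->k;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k)
      stop("k-mer %d has length != k", (int)(i + 1));
    RollState st;
    if (!roll_init(s, 0, k, st)) stop("non-ACGT symbol in k-mer");
    bf->insert(canonical_value(st));
  }
}

// Query the k-mers at the given 1-based start positions of seq.
// Windows containing non-ACGT return NA.
// [[Rcpp::export]]
LogicalVector cpp_bf_query_starts(SEXP xp, std::string seq,
                                  IntegerVector starts) {
  BloomXPtr bf(xp);
  int k = bf->k, n = (int)seq.size();
  LogicalVector out(starts.size());
  for (R_xlen_t i = 0; i < starts.size(); ++i) {
    int st0 = starts[i] - 1;
    if (st0 < 0 || st0 + k > n)
      stop("window start %d out of bounds", (int)starts[i]);
    RollState rs;
    if (!roll_init(seq.c_str(), st0, k, rs)) {
      out[i] = NA_LOGICAL;
    } else {
      out[i] = bf->query(canonical_value(rs));
    }
  }
  return out;
}

// Query every k-mer of seq (rolling); requires pure ACGT.
// [[Rcpp::export]]
LogicalVector cpp_bf_query_seq(SEXP xp, std::string seq) {
  BloomXPtr bf(xp);
  int k = bf->k, n = (int)seq.size();
  if (n < k) stop("sequence shorter than k");
  int m = n - k + 1;
  LogicalVector out(m);
  RollState st;
  if (!roll_init(seq.c_str(), 0, k, st)) stop("non-ACGT symbol in sequence");
  out[0] = bf->query(canonical_value(st));
  for (int i = 1; i < m; ++i) {
    if (!roll_step(seq.c_str(), i - 1, st))
      stop("non-ACGT symbol in sequence");
    out[i] = bf->query(canonical_value(st));
  }
  return out;
}

// ------------------------------------------------------------ hash views --

// Rolling hash indices for every window of seq: (n-k+1) x h matrix of bit
// positions modulo nbits. Positions after the first are produced by the
// O(1) rolling update.
// [[Rcpp::export]]
NumericMatrix cpp_kmer_hashes(std::string seq, int k, int h, double nbits) {
  int n = (int)seq.size();
  if (n < k) stop("sequence shorter than k");
  uint64_t B = (uint64_t)nbits;
  int m = n - k + 1;
  NumericMatrix out(m, h);
  uint64_t idx[64];
  RollState st;
  if (!roll_init(seq.c_str(), 0, k, st)) stop("non-ACGT symbol in sequence");
  derive_hashes(canonical_value(st), h, B, idx);
  for (int j = 0; j < h; ++j) out(0, j) = (double)idx[j];
  for (int i = 1; i < m; ++i) {
    if (!roll_step(seq.c_str(), i - 1, st))
      stop("non-ACGT symbol in sequence");
    derive_hashes(canonical_value(st), h, B, idx);
    for (int j = 0; j < h; ++j) out(i, j) = (double)idx[j];
  }
  return out;
}

// Same quantity computed from scratch per window (no rolling update):
// the independent oracle for the rolling path.
// [[Rcpp::export]]
NumericMatrix cpp_kmer_hashes_scratch(std::string seq, int k, int h,
                                      double nbits) {
  int n = (int)seq.size();
  if (n < k) stop("sequence shorter than k");
  uint64_t B = (uint64_t)nbits;
  int m = n - k + 1;
  NumericMatrix out(m, h);
  uint64_t idx[64];
  for (int i = 0; i < m; ++i) {
    uint64_t f = 0, r = 0, pj = 1;
    for (int j = 0; j < k; ++j, pj *= MULT) {
      int c = base_code(seq[i + j]);
      if (c < 0) stop("non-ACGT symbol in sequence");
      f = f * MULT + (uint64_t)c;
      r += (uint64_t)(3 - c) * pj;
    }
    uint64_t canon = f < r ? f : r;
    derive_hashes(canon, h, B, idx);
    for (int j = 0; j < h; ++j) out(i, j) = (double)idx[j];
  }
  return out;
}

// --------------------------------------------------------- k-mer counts --

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_char(r[i]);
  return r;
}

static inline std::string canonical_string(const std::string& s) {
  std::string r = revcomp_str(s);
  return s < r ? s : r;
}

// Count canonical k-mers over a set of sequences; windows containing
// non-ACGT are skipped. Returns k-mers with count >= kc_min, sorted.
// [[Rcpp::export]]
List cpp_count_canonical_kmers(CharacterVector seqs, int k, int kc_min) {
  std::map<std::string, int> counts; // ordered map -> deterministic output
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int n = (int)s.size();
    for (int p = 0; p + k <= n; ++p) {
      bool ok = true;
      for (int j = 0; j < k; ++j)
        if (base_code(s[p + j]) < 0) { ok = false; break; }
      if (!ok) continue;
      ++counts[canonical_string(s.substr(p, k))];
    }
  }
  std::vector<std::string> kmers;
  std::vector<int> cnt;
  for (std::map<std::string, int>::iterator it = counts.begin();
       it != counts.end(); ++it) {
    if (it->second >= kc_min) {
      kmers.push_back(it->first);
      cnt.push_back(it->second);
    }
  }
  return List::create(_["kmer"] = wrap(kmers), _["count"] = wrap(cnt));
}

// ------------------------------------------------------------- unitigs --

// Node-centric DBG compaction. Oriented k-mers are strings; membership and
// counts are canonical. Emits unitig sequences, per-unitig k-mer
// multiplicity sums, and the overlap-(k-1) link set between unitigs.
namespace {

struct UnitigBuilder {
  int k;
  std::map<std::string, int> counts; // canonical kmer -> multiplicity

  bool present(const std::string& kmer) const {
    return counts.count(canonical_string(kmer)) > 0;
  }

  std::vector<std::string> successors(const std::string& x) const {
    std::vector<std::string> out;
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    std::string cand = x.substr(1) + "A";
    for (int b = 0; b < 4; ++b) {
      cand[k - 1] = bases[b];
      if (present(cand)) out.push_back(cand);
    }
    return out;
  }
  std::vector<std::string> predecessors(const std::string& x) const {
    std::vector<std::string> out;
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    std::string cand = "A" + x.substr(0, k - 1);
    for (int b = 0; b < 4; ++b) {
      cand[0] = bases[b];
      if (present(cand)) out.push_back(cand);
    }
    return out;
  }

  bool is_chain_start(const std::string& x) const {
    std::vector<std::string> preds = predecessors(x);
    if (preds.size() != 1) return true;
    if (successors(preds[0]).size() != 1) return true;
    if (preds[0] == x) return true; // 1-node self loop
    return false;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_build_unitigs(CharacterVector seqs, int k, int kc_min) {
  UnitigBuilder ub;
  ub.k = k;
  {
    List counted = cpp_count_canonical_kmers(seqs, k, kc_min);
    CharacterVector km = counted["kmer"];
    IntegerVector ct = counted["count"];
    for (R_xlen_t i = 0; i < km.size(); ++i)
      ub.counts[as<std::string>(km[i])] = ct[i];
  }
  if (ub.counts.empty())
    stop("no k-mers left after multiplicity filtering (kc_min = %d)", kc_min);

  std::set<std::string> used; // canonical forms consumed by a unitig
  std::vector<std::string> useq;
  std::vector<double> ucov;

  // Walk forward from x while the chain stays unambiguous.
  // Consumes canonical forms into `used`.
  struct Walker {
    UnitigBuilder& ub;
    std::set<std::string>& used;
    Walker(UnitigBuilder& u, std::set<std::string>& s) : ub(u), used(s) {}
    void walk(const std::string& start, std::string& seq, double& cov) {
      std::string cur = start;
      seq = cur;
      cov = ub.counts[canonical_string(cur)];
      used.insert(canonical_string(cur));
      for (;;) {
        std::vector<std::string> nxt = ub.successors(cur);
        if (nxt.size() != 1) break;
        const std::string& nx = nxt[0];
        if (ub.predecessors(nx).size() != 1) break;
        if (used.count(canonical_string(nx))) break; // cycle closure
        seq += nx[nx.size() - 1];
        cov += ub.counts[canonical_string(nx)];
        used.insert(canonical_string(nx));
        cur = nx;
      }
    }
  } walker(ub, used);

  // Pass 1: chains anchored at branch points / tips, in sorted k-mer order.
  for (std::map<std::string, int>::iterator it = ub.counts.begin();
       it != ub.counts.end(); ++it) {
    const std::string& canon = it->first;
    if (used.count(canon)) continue;
    std::string rc = revcomp_str(canon);
    std::string chosen;
    if (ub.is_chain_start(canon)) chosen = canon;
    else if (canon != rc && ub.is_chain_start(rc)) chosen = rc;
    else continue;
    std::string seq;
    double cov;
    walker.walk(chosen, seq, cov);
    useq.push_back(seq);
    ucov.push_back(cov);
  }
  // Pass 2: anything left lives on perfect cycles; break at the smallest
  // canonical k-mer.
  for (std::map<std::string, int>::iterator it = ub.counts.begin();
       it != ub.counts.end(); ++it) {
    if (used.count(it->first)) continue;
    std::string seq;
    double cov;
    walker.walk(it->first, seq, cov);
    useq.push_back(seq);
    ucov.push_back(cov);
  }

  // Links: oriented first-kmer -> (unitig, orientation) lookup, then probe
  // successors of every oriented last k-mer.
  int nu = (int)useq.size();
  std::map<std::string, std::pair<int, char> > start_of;
  for (int u = 0; u < nu; ++u) {
    std::string fwd_first = useq[u].substr(0, k);
    std::string rc = revcomp_str(useq[u]);
    std::string rev_first = rc.substr(0, k);
    start_of[fwd_first] = std::make_pair(u, '+');
    if (rev_first != fwd_first)
      start_of[rev_first] = std::make_pair(u, '-');
  }
  // edge tuple (from, fo, to, to_or), stored in mirror-canonical form
  std::set<std::vector<int> > edges;
  for (int u = 0; u < nu; ++u) {
    for (int o = 0; o < 2; ++o) {
      std::string s = o == 0 ? useq[u] : revcomp_str(useq[u]);
      std::string last = s.substr(s.size() - k);
      std::vector<std::string> nxt = ub.successors(last);
      for (size_t j = 0; j < nxt.size(); ++j) {
        std::map<std::string, std::pair<int, char> >::iterator hit =
          start_of.find(nxt[j]);
        if (hit == start_of.end()) continue; // target k-mer mid-unitig: skip
        int v = hit->second.first;
        int po = hit->second.second == '+' ? 0 : 1;
        std::vector<int> e(4), m(4);
        e[0] = u; e[1] = o; e[2] = v; e[3] = po;
        m[0] = v; m[1] = 1 - po; m[2] = u; m[3] = 1 - o;
        edges.insert(e < m ? e : m);
      }
    }
  }
  int ne = (int)edges.size();
  IntegerVector from(ne), to(ne);
  CharacterVector fo(ne), po(ne);
  int i = 0;
  for (std::set<std::vector<int> >::iterator it = edges.begin();
       it != edges.end(); ++it, ++i) {
    from[i] = (*it)[0] + 1;
    fo[i] = (*it)[1] == 0 ? "+" : "-";
    to[i] = (*it)[2] + 1;
    po[i] = (*it)[3] == 0 ? "+" : "-";
  }
  return List::create(_["seq"] = wrap(useq), _["cov"] = wrap(ucov),
                      _["from"] = from, _["from_or"] = fo, _["to"] = to,
                      _["to_or"] = po);
}
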