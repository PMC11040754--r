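// Low-level k-mer machinery: 2-bit encoded canonical k-mer counting,
// exact-match position scans, seed-membership support for the toy
// fragment mapper, and k-mer containment between two sequences.
// k is limited to 31 so a k-mer fits in one 64-bit word.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASES[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  out = code;
  return true;
}

// Rolling scan over one sequence, calling f(code) for every valid
// k-mer window (forward orientation), and g(pos, code) variant below.
template <typename F>
static void scan_forward(const std::string& seq, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t code = 0;
  int filled = 0;
  const int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { filled = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++filled >= k) f(i - k + 1, code);
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, int> counts;
  counts.reserve(1 << 20);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    scan_forward(seq, k, [&](int, uint64_t code) {
      uint64_t canon = std::min(code, revcomp_code(code, k));
      ++counts[canon];
    });
  }
  const R_xlen_t m = (R_xlen_t)counts.size();
  CharacterVector kmer(m);
  IntegerVector count(m);
  R_xlen_t i = 0;
  for (const auto& kv : counts) {
    kmer[i] = decode_kmer(kv.first, k);
    count[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// Joint canonical k-mer counting across several genomes in one pass;
// only k-mers whose maximum per-genome count strictly exceeds
// min_count are returned (keeps the output small at genome scale).
// `genomes` is a list of CharacterVectors of chromosome sequences.
// [[Rcpp::export]]
List cpp_count_kmers_multi(List genomes, int k, int min_count) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  const int ng = genomes.size();
  std::unordered_map<uint64_t, uint32_t> id;  // k-mer -> row index
  id.reserve(1 << 22);
  std::vector<std::vector<uint32_t>> counts(ng);
  std::vector<double> totals(ng, 0.0);
  for (int g = 0; g < ng; ++g) {
    CharacterVector seqs = genomes[g];
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
      std::string seq = as<std::string>(seqs[s]);
      scan_forward(seq, k, [&](int, uint64_t code) {
        uint64_t canon = std::min(code, revcomp_code(code, k));
        auto it = id.find(canon);
        uint32_t row;
        if (it == id.end()) {
          row = (uint32_t)id.size();
          id.emplace(canon, row);
          for (int gg = 0; gg < ng; ++gg) counts[gg].push_back(0);
        } else {
          row = it->second;
        }
        ++counts[g][row];
        totals[g] += 1.0;
      });
    }
  }
  // retention: max across genomes strictly greater than min_count
  const size_t m = id.size();
  std::vector<char> keep(m, 0);
  size_t n_keep = 0;
  for (size_t i = 0; i < m; ++i) {
    uint32_t mx = 0;
    for (int g = 0; g < ng; ++g) mx = std::max(mx, counts[g][i]);
    if ((int)mx > min_count) { keep[i] = 1; ++n_keep; }
  }
  CharacterVector kmer(n_keep);
  List cnt_cols(ng);
  std::vector<IntegerVector> cols;
  for (int g = 0; g < ng; ++g) cols.push_back(IntegerVector(n_keep));
  size_t j_global = 0;
  std::vector<uint64_t> codes(m);
  for (const auto& kv : id) codes[kv.second] = kv.first;
  for (size_t i = 0; i < m; ++i) {
    if (!keep[i]) continue;
    kmer[j_global] = decode_kmer(codes[i], k);
    for (int g = 0; g < ng; ++g) cols[g][j_global] = counts[g][i];
    ++j_global;
  }
  for (int g = 0; g < ng; ++g) cnt_cols[g] = cols[g];
  return List::create(_["kmer"] = kmer, _["counts"] = cnt_cols,
                      _["totals"] = NumericVector(totals.begin(),
                                                  totals.end()));
}

// Total number of valid (ACGT-only) k-mer windows across sequences.
// [[Rcpp::export]]
double cpp_valid_windows(CharacterVector seqs, int k) {
  double total = 0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    scan_forward(seq, k, [&](int, uint64_t) { ++total; });
  }
  return total;
}

static std::unordered_set<uint64_t> build_canonical_set(CharacterVector kmers,
                                                        int k) {
  std::unordered_set<uint64_t> set;
  set.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) stop("k-mer of wrong length in set");
    uint64_t code;
    if (!encode_kmer(s.c_str(), k, code)) stop("non-ACGT base in k-mer set");
    set.insert(std::min(code, revcomp_code(code, k)));
  }
  return set;
}

// 0-based start positions (per sequence) of windows whose canonical
// k-mer belongs to `kmers`.
// [[Rcpp::export]]
List cpp_match_positions(CharacterVector seqs, CharacterVector kmers, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_set<uint64_t> set = build_canonical_set(kmers, k);
  List out(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    std::vector<int> hits;
    scan_forward(seq, k, [&](int pos, uint64_t code) {
      uint64_t canon = std::min(code, revcomp_code(code, k));
      if (set.count(canon)) hits.push_back(pos);
    });
    out[s] = IntegerVector(hits.begin(), hits.end());
  }
  return out;
}

static std::vector<uint64_t> target_kmer_sorted(CharacterVector targets,
                                                int k, bool canonical) {
  std::vector<uint64_t> keys;
  for (R_xlen_t s = 0; s < targets.size(); ++s) {
    std::string seq = as<std::string>(targets[s]);
    scan_forward(seq, k, [&](int, uint64_t code) {
      keys.push_back(canonical ? std::min(code, revcomp_code(code, k)) : code);
    });
  }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
  return keys;
}

// For each fragment, the fraction of its valid k-mer seeds whose
// canonical form occurs anywhere in the target sequence set.
// Fragments with no valid window get support NA.
// [[Rcpp::export]]
NumericVector cpp_seed_support(CharacterVector frags, CharacterVector targets,
                               int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::vector<uint64_t> keys = target_kmer_sorted(targets, k, true);
  NumericVector out(frags.size());
  for (R_xlen_t f = 0; f < frags.size(); ++f) {
    std::string seq = as<std::string>(frags[f]);
    long total = 0, hit = 0;
    scan_forward(seq, k, [&](int, uint64_t code) {
      ++total;
      uint64_t canon = std::min(code, revcomp_code(code, k));
      if (std::binary_search(keys.begin(), keys.end(), canon)) ++hit;
    });
    out[f] = total == 0 ? NA_REAL : (double)hit / (double)total;
  }
  return out;
}

// Fraction of the distinct canonical k-mers of `a` present among the
// distinct canonical k-mers of `b` (k-mer containment of a in b).
// [[Rcpp::export]]
double cpp_containment(std::string a, std::string b, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_set<uint64_t> bset;
  scan_forward(b, k, [&](int, uint64_t code) {
    bset.insert(std::min(code, revcomp_code(code, k)));
  });
  std::unordered_set<uint64_t> aset;
  scan_forward(a, k, [&](int, uint64_t code) {
    aset.insert(std::min(code, revcomp_code(code, k)));
  });
  if (aset.empty()) return NA_REAL;
  long hit = 0;
  for (uint64_t c : aset) if (bset.count(c)) ++hit;
  return (double)hit / (double)aset.size();
}

// Forward-strand exact seed hits of each query against a set of target
// sequences. Returns, per query, a data frame of (qpos, tpos, target),
// all 0-based; used by the naive seed-chaining aligner.
// [[Rcpp::export]]
List cpp_seed_hits(CharacterVector queries, CharacterVector targets, int k,
                   int max_hits_per_seed = 50) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  // index: forward k-mer -> positions (target idx, pos)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  index.reserve(1 << 20);
  for (R_xlen_t s = 0; s < targets.size(); ++s) {
    std::string seq = as<std::string>(targets[s]);
    scan_forward(seq, k, [&](int pos, uint64_t code) {
      auto& v = index[code];
      if ((int)v.size() < max_hits_per_seed)
        v.push_back(std::make_pair((int)s, pos));
    });
  }
  List out(queries.size());
  for (R_xlen_t q = 0; q < queries.size(); ++q) {
    std::string seq = as<std::string>(queries[q]);
    std::vector<int> qpos, tpos, tidx;
    scan_forward(seq, k, [&](int pos, uint64_t code) {
      auto it = index.find(code);
      if (it == index.end()) return;
      for (const auto& pr : it->second) {
        tidx.push_back(pr.first + 1);  // 1-based target index for R
        qpos.push_back(pos);
        tpos.push_back(pr.second);
      }
    });
    out[q] = DataFrame::create(_["qpos"] = IntegerVector(qpos.begin(), qpos.end()),
                               _["tpos"] = IntegerVector(tpos.begin(), tpos.end()),
                               _["target"] = IntegerVector(tidx.begin(), tidx.end()));
  }
  return out;
}
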