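#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// 2-bit base codes; 4 marks anything outside A/C/G/T
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char bit2base(int b) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  return tab[b];
}

static inline char comp(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  case 'N': case 'n': return 'N';
  default: return c;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

static std::string decode_kmer(uint64_t key, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bit2base((int)(key & 3ULL));
    key >>= 2;
  }
  return s;
}

// Enumerate canonical k-mer keys of one sequence. Windows containing a
// non-ACGT character are skipped. Calls f(canonical_key) per valid window.
template <typename F>
static void scan_canonical(const std::string& seq, int k, F f) {
  const int n = (int)seq.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0; // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int b = base2bit(seq[i]);
    if (b > 3) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) f(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
DataFrame cpp_kmer_counts(CharacterVector seqs, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_map<uint64_t, double> counts;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    scan_canonical(seq, k, [&](uint64_t key) { counts[key] += 1.0; });
  }
  std::vector<std::pair<uint64_t, double>> v(counts.begin(), counts.end());
  std::sort(v.begin(), v.end());
  CharacterVector kmers(v.size());
  NumericVector n(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    kmers[i] = decode_kmer(v[i].first, k);
    n[i] = v[i].second;
  }
  return DataFrame::create(_["kmer"] = kmers, _["count"] = n,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    for (auto& c : s) c = (char)toupper(c);
    std::string r = revcomp_str(s);
    out[i] = (s <= r) ? s : r;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    for (auto& c : s) c = (char)toupper(c);
    out[i] = revcomp_str(s);
  }
  return out;
}

// For each long read, the number of short reads occurring as an exact
// substring on either strand. Each short read counts once per long read.
// [[Rcpp::export]]
IntegerVector cpp_containment_hits(CharacterVector long_seqs,
                                   CharacterVector short_seqs) {
  const int n_long = (int)long_seqs.size();
  const int n_short = (int)short_seqs.size();
  std::unordered_map<std::string, std::vector<int>> index;
  std::vector<int> lens;
  for (int i = 0; i < n_short; ++i) {
    std::string s = as<std::string>(short_seqs[i]);
    for (auto& c : s) c = (char)toupper(c);
    std::string r = revcomp_str(s);
    index[(s <= r) ? s : r].push_back(i);
    lens.push_back((int)s.size());
  }
  std::sort(lens.begin(), lens.end());
  lens.erase(std::unique(lens.begin(), lens.end()), lens.end());
  std::vector<int> last_seen(n_short, -1);
  IntegerVector hits(n_long, 0);
  for (int li = 0; li < n_long; ++li) {
    std::string seq = as<std::string>(long_seqs[li]);
    for (auto& c : seq) c = (char)toupper(c);
    std::string rc = revcomp_str(seq);
    const int n = (int)seq.size();
    for (int L : lens) {
      if (L > n) continue;
      for (int i = 0; i + L <= n; ++i) {
        std::string fwd = seq.substr(i, L);
        std::string rev = rc.substr(n - L - i, L);
        const std::string& key = (fwd <= rev) ? fwd : rev;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (int sid : it->second) {
          if (last_seen[sid] != li) {
            last_seen[sid] = li;
            ++hits[li];
          }
        }
      }
    }
  }
  return hits;
}

// For each long read, the number of short reads sharing at least
// `min_shared` distinct canonical seed k-mers with it.
// [[Rcpp::export]]
IntegerVector cpp_seed_hits(CharacterVector long_seqs,
                            CharacterVector short_seqs,
                            int seed_len, int min_shared) {
  if (seed_len < 1 || seed_len > 32) stop("seed_len must be between 1 and 32");
  if (min_shared < 1) stop("min_shared must be >= 1");
  const int n_long = (int)long_seqs.size();
  std::unordered_map<uint64_t, std::vector<int>> index;
  {
    std::unordered_map<uint64_t, int> last; // dedup seeds within a long read
    for (int li = 0; li < n_long; ++li) {
      std::string seq = as<std::string>(long_seqs[li]);
      scan_canonical(seq, seed_len, [&](uint64_t key) {
        auto it = last.find(key);
        if (it == last.end() || it->second != li) {
          last[key] = li;
          index[key].push_back(li);
        }
      });
    }
  }
  IntegerVector hits(n_long, 0);
  std::vector<uint64_t> seeds;
  std::vector<int> touched;
  for (R_xlen_t si = 0; si < short_seqs.size(); ++si) {
    std::string seq = as<std::string>(short_seqs[si]);
    seeds.clear();
    scan_canonical(seq, seed_len, [&](uint64_t key) { seeds.push_back(key); });
    std::sort(seeds.begin(), seeds.end());
    seeds.erase(std::unique(seeds.begin(), seeds.end()), seeds.end());
    touched.clear();
    for (uint64_t key : seeds) {
      auto it = index.find(key);
      if (it == index.end()) continue;
      touched.insert(touched.end(), it->second.begin(), it->second.end());
    }
    std::sort(touched.begin(), touched.end());
    size_t i = 0;
    while (i < touched.size()) {
      size_t j = i;
      while (j < touched.size() && touched[j] == touched[i]) ++j;
      if ((int)(j - i) >= min_shared) ++hits[touched[i]];
      i = j;
    }
  }
  return hits;
}

// Count, per query k-mer, the long reads (or occurrences) containing it on
// either strand, split by bin. Bins: 1 = Y, 2 = autosomal, 3 = X; anything
// else is ignored. Queries must already be canonical.
// [[Rcpp::export]]
IntegerMatrix cpp_bin_hits(CharacterVector query_kmers,
                           CharacterVector long_seqs,
                           IntegerVector bins, int k,
                           bool occurrences) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  const int nq = (int)query_kmers.size();
  std::unordered_map<uint64_t, int> qindex;
  for (int i = 0; i < nq; ++i) {
    std::string s = as<std::string>(query_kmers[i]);
    if ((int)s.size() != k) stop("query k-mer length differs from k");
    uint64_t key = 0;
    for (char c : s) {
      int b = base2bit(c);
      if (b > 3) stop("query k-mer contains a non-ACGT character");
      key = (key << 2) | (uint64_t)b;
    }
    std::string r = revcomp_str(s);
    if (r < s) stop("query k-mer is not canonical");
    qindex[key] = i;
  }
  IntegerMatrix out(nq, 3);
  std::vector<int> last_seen(nq, -1);
  for (R_xlen_t li = 0; li < long_seqs.size(); ++li) {
    int bin = bins[(int)li];
    if (bin < 1 || bin > 3) continue;
    std::string seq = as<std::string>(long_seqs[li]);
    scan_canonical(seq, k, [&](uint64_t key) {
      auto it = qindex.find(key);
      if (it == qindex.end()) return;
      int qi = it->second;
      if (occurrences) {
        ++out(qi, bin - 1);
      } else if (last_seen[qi] != (int)li) {
        last_seen[qi] = (int)li;
        ++out(qi, bin - 1);
      }
    });
  }
  return out;
}

// Leftmost exact occurrence of `pattern` (either strand) in each sequence.
// Returns 0-based offset (-1 if absent) and strand; on a positional tie the
// plus strand wins.
// [[Rcpp::export]]
DataFrame cpp_first_match(CharacterVector seqs, std::string pattern) {
  for (auto& c : pattern) c = (char)toupper(c);
  std::string prc = revcomp_str(pattern);
  IntegerVector offset(seqs.size(), -1);
  CharacterVector strand(seqs.size(), NA_STRING);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (auto& c : s) c = (char)toupper(c);
    size_t pf = s.find(pattern);
    size_t pr = (prc == pattern) ? std::string::npos : s.find(prc);
    if (pf == std::string::npos && pr == std::string::npos) continue;
    if (pr == std::string::npos || (pf != std::string::npos && pf <= pr)) {
      offset[i] = (int)pf;
      strand[i] = "+";
    } else {
      offset[i] = (int)pr;
      strand[i] = "-";
    }
  }
  return DataFrame::create(_["offset"] = offset, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}
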