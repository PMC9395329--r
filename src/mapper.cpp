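#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit DNA encoding; k <= 31 so a k-mer fits in 62 bits with a sentinel for
// invalid (non-ACGT) windows.
static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

// Rolling enumeration of valid k-mers of s; calls f(kmer, start).
template <typename F>
static void for_each_kmer(const std::string& s, int k, F f) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t kmer = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // length of current valid run
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++run >= k) f(kmer, i - k + 1);
  }
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > KmerIndex;

static KmerIndex build_index(const std::vector<std::string>& genomes, int k) {
  KmerIndex idx;
  for (size_t g = 0; g < genomes.size(); ++g) {
    for_each_kmer(genomes[g], k, [&](uint64_t kmer, int pos) {
      idx[kmer].push_back(std::make_pair((int32_t)g, (int32_t)pos));
    });
  }
  return idx;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = complement(r[i]);
  return r;
}

// Ungapped score of read placed at genome[pos..pos+L): +1 match, -1 mismatch.
static inline int score_at(const std::string& genome, const std::string& read,
                           int pos) {
  int s = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    char a = genome[pos + i], b = read[i];
    if (a >= 'a') a -= 32;
    if (b >= 'a') b -= 32;
    s += (a == b && a != 'N') ? 1 : -1;
  }
  return s;
}

// Unique best-hit mapping of reads against a genome catalog.
// A candidate placement is any (genome, position, strand) sharing at least one
// exact k-mer with the read, with the read fully contained in the genome.
// status: 0 unmapped, 1 unique, 2 ambiguous. Positions are 0-based leftmost.
// strand: +1 forward, -1 reverse. min_score is an absolute score threshold.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector genomes,
                        int k, double min_score_frac) {
  if (k < 4 || k > 31) stop("seed length k must be in [4, 31]");
  std::vector<std::string> gs(genomes.size());
  for (int i = 0; i < genomes.size(); ++i) gs[i] = as<std::string>(genomes[i]);
  KmerIndex idx = build_index(gs, k);

  const int n = reads.size();
  IntegerVector status(n), sgb(n, NA_INTEGER), pos(n, NA_INTEGER),
      strand(n, NA_INTEGER), score(n, NA_INTEGER), n_best(n, 0);

  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = (int)fwd.size();
    if (L < k) { status[r] = 0; continue; }
    std::string rev = revcomp(fwd);
    const int min_score = (int)std::ceil(min_score_frac * L);

    // candidate placements keyed by (genome, pos, strand)
    std::unordered_set<uint64_t> seen;
    int best = INT32_MIN, bestCount = 0;
    int bgenome = -1, bpos = -1, bstrand = 0;

    for (int ori = 0; ori < 2; ++ori) {
      const std::string& rd = (ori == 0) ? fwd : rev;
      for_each_kmer(rd, k, [&](uint64_t kmer, int s) {
        KmerIndex::const_iterator it = idx.find(kmer);
        if (it == idx.end()) return;
        for (size_t j = 0; j < it->second.size(); ++j) {
          int g = it->second[j].first;
          int p = it->second[j].second - s;
          if (p < 0 || p + L > (int)gs[g].size()) continue;
          uint64_t key = ((uint64_t)g << 34) | ((uint64_t)p << 1) | ori;
          if (!seen.insert(key).second) continue;
          int sc = score_at(gs[g], rd, p);
          if (sc > best) {
            best = sc; bestCount = 1;
            bgenome = g; bpos = p; bstrand = (ori == 0) ? 1 : -1;
          } else if (sc == best) {
            ++bestCount;
          }
        }
      });
    }

    if (bestCount == 0 || best < min_score) {
      status[r] = 0;
    } else if (bestCount == 1) {
      status[r] = 1;
      sgb[r] = bgenome + 1;
      pos[r] = bpos;
      strand[r] = bstrand;
      score[r] = best;
    } else {
      status[r] = 2;
      score[r] = best;
    }
    n_best[r] = bestCount;
  }

  return DataFrame::create(_["status"] = status, _["sgb"] = sgb,
                           _["pos"] = pos, _["strand"] = strand,
                           _["score"] = score, _["n_best"] = n_best);
}

// Fraction of each read's k-mers (forward or reverse complement) present in
// the k-mer set of the host sequences. Reads shorter than k score 0.
// [[Rcpp::export]]
NumericVector cpp_kmer_hit_fraction(CharacterVector reads,
                                    CharacterVector host_seqs, int k) {
  if (k < 4 || k > 31) stop("k-mer length must be in [4, 31]");
  std::unordered_set<uint64_t> host;
  for (int i = 0; i < host_seqs.size(); ++i) {
    std::string s = as<std::string>(host_seqs[i]);
    for_each_kmer(s, k, [&](uint64_t kmer, int) { host.insert(kmer); });
  }
  const int n = reads.size();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    if ((int)fwd.size() < k) { out[r] = 0.0; continue; }
    std::string rev = revcomp(fwd);
    int total = 0, hit = 0;
    // k-mer at read offset i maps to rc k-mer at rev offset L - k - i
    const int L = (int)fwd.size();
    std::vector<uint64_t> fk(L, UINT64_MAX), rk(L, UINT64_MAX);
    for_each_kmer(fwd, k, [&](uint64_t kmer, int p) { fk[p] = kmer; });
    for_each_kmer(rev, k, [&](uint64_t kmer, int p) { rk[p] = kmer; });
    for (int i = 0; i + k <= L; ++i) {
      if (fk[i] == UINT64_MAX) continue;  // invalid window
      ++total;
      uint64_t rcmer = rk[L - k - i];
      if (host.count(fk[i]) || (rcmer != UINT64_MAX && host.count(rcmer)))
        ++hit;
    }
    out[r] = total > 0 ? (double)hit / total : 0.0;
  }
  return out;
}
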