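#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Scoring follows the clustering module's definition: match +1, mismatch and
// gap contribute nothing, end gaps free. Under that scheme the optimal
// alignment score is the longest common subsequence restricted to exact base
// matches; 'N' (or any non-ACGT symbol) never matches anything.

static inline bool base_match(char a, char b) {
  if (a != b) return false;
  return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

static int lcs_matches(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? 1 : 0);
      int u = prev[j];
      int l = cur[j - 1];
      cur[j] = d > u ? (d > l ? d : l) : (u > l ? u : l);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int match_count_cpp(std::string a, std::string b) {
  return lcs_matches(a, b);
}

// [[Rcpp::export]]
IntegerVector match_counts_cpp(std::string query, CharacterVector refs) {
  IntegerVector out(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i)
    out[i] = lcs_matches(query, std::string(refs[i]));
  return out;
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return out;
}

struct AlnSpan {
  int matches;
  int q_first, q_last;   // 0-based inclusive, on the query (spacer variant)
  int r_first, r_last;   // 0-based inclusive, on the window
};

// final DP row: best[j] = max matches of a against any alignment with the
// first j characters of b
static std::vector<int> lcs_row(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? 1 : 0);
      cur[j] = std::max(d, std::max(prev[j], cur[j - 1]));
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), 0);
  }
  return prev;
}

static inline int first_reaching(const std::vector<int>& row, int target) {
  for (size_t j = 0; j < row.size(); ++j)
    if (row[j] == target) return (int)j;
  return (int)row.size() - 1;
}

// Tightest span of an optimal free-end-gap alignment: with gaps costing
// nothing the optimum can be stretched arbitrarily, so coordinates are
// pinned down by forward/reverse DP rows (smallest prefix on each side that
// still attains the optimal match count).
static AlnSpan aligned_span(const std::string& q, const std::string& w) {
  std::vector<int> fwd = lcs_row(q, w);
  const int mstar = fwd[w.size()];
  AlnSpan s{mstar, -1, -1, -1, -1};
  if (mstar == 0) return s;

  int j_hi = first_reaching(fwd, mstar);            // exclusive right end
  std::string w1(w.rbegin() + (w.size() - j_hi), w.rend());
  std::string qr(q.rbegin(), q.rend());
  int j_lo_rev = first_reaching(lcs_row(qr, w1), mstar);
  s.r_first = j_hi - j_lo_rev;
  s.r_last = j_hi - 1;

  std::string w2 = w.substr(s.r_first, j_hi - s.r_first);
  s.q_last = first_reaching(lcs_row(w2, q), mstar) - 1;
  std::string w2r(w2.rbegin(), w2.rend());
  int i_lo_rev = first_reaching(lcs_row(w2r, qr), mstar);
  s.q_first = (int)q.size() - i_lo_rev;
  return s;
}

static inline int encode_base(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

// Exact k-mer seed positions of a read, 2-bit encoded; k-mers containing N
// are skipped (they can never seed an exact match).
static std::unordered_map<uint64_t, std::vector<int>>
index_kmers(const std::string& read, int k) {
  std::unordered_map<uint64_t, std::vector<int>> idx;
  const int rl = (int)read.size();
  if (rl < k) return idx;
  uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < rl; ++i) {
    int e = encode_base(read[i]);
    if (e < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)e) & mask;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }
  return idx;
}

// [[Rcpp::export]]
DataFrame protospacer_scan_cpp(CharacterVector spacer_ids,
                               CharacterVector spacer_seqs,
                               CharacterVector read_ids,
                               CharacterVector read_seqs,
                               int k,
                               double min_identity,
                               double min_coverage) {
  std::vector<std::string> h_spacer, h_read, h_strand;
  std::vector<int> h_start, h_end;
  std::vector<double> h_identity, h_coverage;

  for (R_xlen_t r = 0; r < read_seqs.size(); ++r) {
    const std::string read = as<std::string>(read_seqs[r]);
    const std::string rid = as<std::string>(read_ids[r]);
    const int rl = (int)read.size();
    auto idx = index_kmers(read, k);

    for (R_xlen_t s = 0; s < spacer_seqs.size(); ++s) {
      const std::string fwd = as<std::string>(spacer_seqs[s]);
      const std::string sid = as<std::string>(spacer_ids[s]);
      const int len = (int)fwd.size();
      if (len == 0) continue;
      const int pad = std::max(3, len / 10);

      for (int strand = 0; strand < 2; ++strand) {
        const std::string q = strand == 0 ? fwd : revcomp_cpp(fwd);
        std::set<int> offsets;
        if (len >= k) {
          uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
          int run = 0;
          for (int i = 0; i < len; ++i) {
            int e = encode_base(q[i]);
            if (e < 0) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)e) & mask;
            if (++run >= k) {
              auto it = idx.find(key);
              if (it != idx.end())
                for (int p : it->second) offsets.insert(p - (i - k + 1));
            }
          }
        } else {
          for (int off = -len; off < rl; ++off) offsets.insert(off);
        }

        int last_end = -1;  // suppress duplicate hits from clustered seeds
        for (int off : offsets) {
          int ws = std::max(0, off - pad);
          int we = std::min(rl, off + len + pad);
          if (we - ws < 1) continue;
          AlnSpan a = aligned_span(q, read.substr(ws, we - ws));
          if (a.matches <= 0) continue;
          double identity = (double)a.matches / len;
          double coverage = (double)(a.q_last - a.q_first + 1) / len;
          if (identity < min_identity || coverage < min_coverage) continue;
          int start = ws + a.r_first, end = ws + a.r_last + 1;
          if (start < last_end) continue;
          last_end = end;
          h_spacer.push_back(sid);
          h_read.push_back(rid);
          h_strand.push_back(strand == 0 ? "+" : "-");
          h_start.push_back(start);
          h_end.push_back(end);
          h_identity.push_back(identity);
          h_coverage.push_back(coverage);
        }
      }
    }
  }

  return DataFrame::create(
      _["spacer_cluster_id"] = h_spacer, _["read_id"] = h_read,
      _["start"] = h_start, _["end"] = h_end, _["strand"] = h_strand,
      _["identity"] = h_identity, _["coverage"] = h_coverage,
      _["stringsAsFactors"] = false);
}
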