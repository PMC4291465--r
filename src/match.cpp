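#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

// Mismatch count over the first 42 positions; 'N' on either side always
// counts as a mismatch. Early exit above `limit`.
static inline int mm42(const char *a, const char *b, int limit) {
  int d = 0;
  for (int i = 0; i < 42; ++i) {
    if (a[i] != b[i] || a[i] == 'N' || b[i] == 'N') {
      if (++d > limit) return d;
    }
  }
  return d;
}

// [[Rcpp::export]]
List match_reads_cpp(CharacterVector reads, CharacterVector db_seqs) {
  int n_db = db_seqs.size();
  std::vector<std::string> db(n_db);
  // pigeonhole index: any 42-mer within Hamming distance 1 of an entry
  // matches the entry exactly on at least one 21-nt half
  std::unordered_multimap<std::string, int> left, right;
  left.reserve(n_db * 2);
  right.reserve(n_db * 2);
  for (int j = 0; j < n_db; ++j) {
    db[j] = as<std::string>(db_seqs[j]);
    if (db[j].size() < 42)
      stop("database entry %d shorter than 42 nt", j + 1);
    left.emplace(db[j].substr(0, 21), j);
    right.emplace(db[j].substr(21, 21), j);
  }

  int n = reads.size();
  IntegerVector hit(n);     // 1-based entry index; 0 NO_MATCH; -1 AMBIGUOUS; -2 short
  IntegerVector dist(n);    // best distance (NA when no hit)
  std::vector<int> seen(n_db, -1);
  std::vector<int> cand;
  cand.reserve(64);

  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    if (r.size() < 42) {
      hit[i] = -2;
      dist[i] = NA_INTEGER;
      continue;
    }
    cand.clear();
    auto lr = left.equal_range(r.substr(0, 21));
    for (auto it = lr.first; it != lr.second; ++it)
      if (seen[it->second] != i) { seen[it->second] = i; cand.push_back(it->second); }
    auto rr = right.equal_range(r.substr(21, 21));
    for (auto it = rr.first; it != rr.second; ++it)
      if (seen[it->second] != i) { seen[it->second] = i; cand.push_back(it->second); }

    int best = 3, n_best = 0, best_j = -1;
    for (int j : cand) {
      int d = mm42(r.c_str(), db[j].c_str(), 1);
      if (d > 1) continue;
      if (d < best) { best = d; n_best = 1; best_j = j; }
      else if (d == best) ++n_best;
    }
    if (n_best == 0) {
      hit[i] = 0;
      dist[i] = NA_INTEGER;
    } else if (n_best == 1) {
      hit[i] = best_j + 1;
      dist[i] = best;
    } else {
      hit[i] = -1;
      dist[i] = best;
    }
  }
  return List::create(_["hit"] = hit, _["dist"] = dist);
}
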