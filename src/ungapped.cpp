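#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Gap-free seed-and-extend local alignment of short reads against a small
// set of reference sequences. Seeds are exact k-mers; each seeded diagonal
// is scanned once with a maximal-scoring-segment (Kadane) pass under a
// match/mismatch scoring scheme, so every reported alignment is the best
// gap-free local alignment on its diagonal.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: break;
    }
  }
  return r;
}

struct Hit {
  int read_idx; int read_start; int read_end;
  int ref_idx; int ref_start; int ref_end;
  bool fwd; int mismatches; int score;
};

// best-scoring segment on one diagonal; returns false if below thresholds
static bool scan_diagonal(const std::string& read, const std::string& ref,
                          long diag, int match, int mismatch,
                          int min_score, int min_len,
                          int& best_rs, int& best_re, int& best_score,
                          int& best_mm) {
  // read position j aligns to ref position diag + j
  long j0 = diag < 0 ? -diag : 0;                 // first valid read pos
  long j1 = std::min<long>(read.size(), (long)ref.size() - diag); // one past last
  if (j1 - j0 < min_len) return false;
  long cur_start = j0; int cur = 0;
  best_score = 0; best_rs = -1; best_re = -1;
  for (long j = j0; j < j1; ++j) {
    int s = (read[j] == ref[diag + j]) ? match : mismatch;
    if (cur <= 0) { cur = s; cur_start = j; }
    else cur += s;
    if (cur > best_score) { best_score = cur; best_rs = (int)cur_start; best_re = (int)j + 1; }
  }
  if (best_score < min_score || best_rs < 0 || best_re - best_rs < min_len)
    return false;
  best_mm = 0;
  for (int j = best_rs; j < best_re; ++j)
    if (read[j] != ref[diag + j]) ++best_mm;
  return true;
}

// [[Rcpp::export]]
DataFrame ungapped_align_cpp(CharacterVector read_seqs,
                             CharacterVector ref_seqs,
                             int k, int match, int mismatch,
                             int min_score, int min_len) {
  int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);

  // k-mer index over all references: hash -> (ref_idx, pos) pairs
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < nref; ++r) {
    const std::string& s = refs[r];
    uint64_t h = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[h].push_back({r, (int)(i + 1 - k)});
    }
  }

  std::vector<Hit> hits;
  std::vector<std::pair<long, int>> diags; // (diag, ref_idx) seen this strand

  int nreads = read_seqs.size();
  for (int ri = 0; ri < nreads; ++ri) {
    std::string fwd = as<std::string>(read_seqs[ri]);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string read = strand == 0 ? fwd : revcomp(fwd);
      if ((int)read.size() < k) continue;
      diags.clear();
      uint64_t h = 0; int run = 0;
      for (size_t j = 0; j < read.size(); ++j) {
        int c = base_code(read[j]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          auto it = index.find(h);
          if (it == index.end()) continue;
          long rpos = (long)j + 1 - k;
          for (auto& pr : it->second)
            diags.push_back({(long)pr.second - rpos, pr.first});
        }
      }
      std::sort(diags.begin(), diags.end(),
                [](const std::pair<long,int>& a, const std::pair<long,int>& b) {
                  return a.second != b.second ? a.second < b.second : a.first < b.first;
                });
      diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
      for (auto& d : diags) {
        int rs, re, sc, mm;
        if (!scan_diagonal(read, refs[d.second], d.first, match, mismatch,
                           min_score, min_len, rs, re, sc, mm)) continue;
        Hit hit;
        hit.read_idx = ri; hit.ref_idx = d.second;
        hit.fwd = (strand == 0);
        hit.ref_start = (int)(d.first + rs);
        hit.ref_end = (int)(d.first + re);
        if (strand == 0) { hit.read_start = rs; hit.read_end = re; }
        else { // convert back to original read coordinates
          int L = (int)read.size();
          hit.read_start = L - re; hit.read_end = L - rs;
        }
        hit.mismatches = mm; hit.score = sc;
        hits.push_back(hit);
      }
    }
  }

  int n = (int)hits.size();
  IntegerVector read_idx(n), read_start(n), read_end(n), ref_idx(n),
      ref_start(n), ref_end(n), mismatches(n), score(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    const Hit& t = hits[i];
    read_idx[i] = t.read_idx + 1; ref_idx[i] = t.ref_idx + 1;
    read_start[i] = t.read_start; read_end[i] = t.read_end;
    ref_start[i] = t.ref_start; ref_end[i] = t.ref_end;
    strand[i] = t.fwd ? "+" : "-";
    mismatches[i] = t.mismatches; score[i] = t.score;
  }
  return DataFrame::create(
      _["read_idx"] = read_idx, _["read_start"] = read_start,
      _["read_end"] = read_end, _["ref_idx"] = ref_idx,
      _["ref_start"] = ref_start, _["ref_end"] = ref_end,
      _["strand"] = strand, _["mismatches"] = mismatches,
      _["score"] = score, _["stringsAsFactors"] = false);
}
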