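// Constrained gapped direct-repeat search between two border windows.
//
// An alignment is a column sequence over {match, mismatch, gap5, gap3}
// (gap5 = gap in the 5' copy, i.e. the column consumes a base of the 3'
// window only). Constraints: terminal columns are matches; every maximal
// non-match run ("linker") has at most max_linker columns; every match block
// adjacent to a linker has at least min_flank_block columns; repeat length
// L = #match + #mismatch lies in [min_length, max_length]; similarity
// matches/L >= min_similarity. Bases code 0..3 (A,C,G,T); 4 = N or other,
// which never forms a match column.
//
// The optimum is defined by the total order: larger L, then larger
// similarity (= matches at fixed L), then smaller d5+d3 (distances of the
// two copies to their borders), then smaller copy5 start, copy3 start,
// copy5 end, copy3 end, then lexicographically smaller column sequence
// (match < mismatch < gap5 < gap3). The search is a depth-first
// branch-and-bound over column sequences; pruning bounds are conservative,
// so the result equals exhaustive enumeration under the same order.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

namespace {

struct Params {
  int min_len, max_len, max_linker, mfb;
  double min_sim;
};

struct Cand {
  int L = 0, matches = 0, dsum = 0, s5 = 0, s3 = 0, e5 = 0, e3 = 0;
  std::vector<int> cols;
  bool found = false;
};

inline int border_dist(int s, int e, int b) {
  if (s < b && e > b) return 0;   // straddles the border
  if (e <= b) return b - e;       // upstream; abutting = 0
  return s - b;                   // downstream
}

inline bool better(const Cand& a, const Cand& b) {
  if (a.L != b.L) return a.L > b.L;
  if (a.matches != b.matches) return a.matches > b.matches;
  if (a.dsum != b.dsum) return a.dsum < b.dsum;
  if (a.s5 != b.s5) return a.s5 < b.s5;
  if (a.s3 != b.s3) return a.s3 < b.s3;
  if (a.e5 != b.e5) return a.e5 < b.e5;
  if (a.e3 != b.e3) return a.e3 < b.e3;
  return a.cols < b.cols;
}

class Search {
public:
  Search(const std::vector<int>& x5, const std::vector<int>& x3,
         int b5, int b3, const Params& p)
    : x5_(x5), x3_(x3), n5_((int)x5.size()), n3_((int)x3.size()),
      b5_(b5), b3_(b3), p_(p) {}

  Cand run() {
    for (int s5 = 0; s5 < n5_; ++s5) {
      for (int s3 = 0; s3 < n3_; ++s3) {
        if (!is_match(s5, s3)) continue;
        if (start_prunable(s5, s3)) continue;
        s5_ = s5; s3_ = s3;
        cols_.clear();
        cols_.push_back(0);
        block(s5 + 1, s3 + 1, 1, false, 1, 1);
        cols_.pop_back();
      }
    }
    return best_;
  }

private:
  const std::vector<int>& x5_;
  const std::vector<int>& x3_;
  int n5_, n3_, b5_, b3_;
  Params p_;
  Cand best_;
  std::vector<int> cols_;
  int s5_ = 0, s3_ = 0;

  inline bool is_match(int i, int j) const {
    return i < n5_ && j < n3_ && x5_[i] < 4 && x5_[i] == x3_[j];
  }

  // conservative: skip a whole start pair only when nothing from it can beat
  // the incumbent under the total order
  bool start_prunable(int s5, int s3) const {
    if (!best_.found) return false;
    int bound_L = std::min(std::min(n5_ - s5, n3_ - s3), p_.max_len);
    if (bound_L < best_.L) return true;
    if (bound_L > best_.L) return false;
    if (bound_L < best_.matches) return true;
    if (bound_L > best_.matches) return false;
    int d5lb = s5 >= b5_ ? s5 - b5_ : 0;
    int d3lb = s3 >= b3_ ? s3 - b3_ : 0;
    if (d5lb + d3lb > best_.dsum) return true;
    if (d5lb + d3lb < best_.dsum) return false;
    if (s5 != best_.s5) return s5 > best_.s5;
    return s3 > best_.s3;
  }

  bool prunable(int i, int j, int L, int matches) const {
    if (!best_.found) return false;
    int bound_L = std::min(L + std::min(n5_ - i, n3_ - j), p_.max_len);
    if (bound_L < best_.L) return true;
    if (bound_L > best_.L) return false;
    int bound_m = matches + (bound_L - L);
    if (bound_m < best_.matches) return true;
    if (bound_m > best_.matches) return false;
    int d5lb = s5_ >= b5_ ? s5_ - b5_ : 0;
    int d3lb = s3_ >= b3_ ? s3_ - b3_ : 0;
    if (d5lb + d3lb > best_.dsum) return true;
    if (d5lb + d3lb < best_.dsum) return false;
    if (s5_ != best_.s5) return s5_ > best_.s5;
    if (s3_ != best_.s3) return s3_ > best_.s3;
    // tie on (L, matches, dsum, starts): remaining L-columns consume one base
    // per side, so span ends are bounded below
    int e5lb = i + (best_.L - L);
    int e3lb = j + (best_.L - L);
    if (e5lb > best_.e5) return true;
    if (e5lb < best_.e5) return false;
    return e3lb > best_.e3;
  }

  void consider(int i, int j, int L, int matches) {
    if (L < p_.min_len) return;
    if (matches + 1e-9 < p_.min_sim * L) return;
    Cand c;
    c.L = L; c.matches = matches;
    c.dsum = border_dist(s5_, i, b5_) + border_dist(s3_, j, b3_);
    c.s5 = s5_; c.s3 = s3_; c.e5 = i; c.e3 = j;
    c.found = true;
    if (!best_.found) { c.cols = cols_; best_ = std::move(c); return; }
    c.cols = cols_;
    if (better(c, best_)) best_ = std::move(c);
  }

  // in a match block; r = current run length capped at mfb; had = a linker
  // has occurred somewhere before this block
  void block(int i, int j, int r, bool had, int L, int matches) {
    if (!had || r >= p_.mfb) consider(i, j, L, matches);
    if (prunable(i, j, L, matches)) return;
    if (L < p_.max_len && is_match(i, j)) {
      cols_.push_back(0);
      block(i + 1, j + 1, std::min(r + 1, p_.mfb), had, L + 1, matches + 1);
      cols_.pop_back();
    }
    if (r >= p_.mfb && p_.max_linker > 0) linker(i, j, 0, L, matches);
  }

  // inside a linker; c columns emitted so far
  void linker(int i, int j, int c, int L, int matches) {
    if (c > 0 && L < p_.max_len && is_match(i, j)) {
      // close the linker: next column must be a match
      cols_.push_back(0);
      block(i + 1, j + 1, 1, true, L + 1, matches + 1);
      cols_.pop_back();
    }
    if (c >= p_.max_linker) return;
    if (prunable(i, j, L, matches)) return;
    if (i < n5_ && j < n3_ && !(x5_[i] < 4 && x5_[i] == x3_[j]) &&
        L < p_.max_len) {
      cols_.push_back(1);
      linker(i + 1, j + 1, c + 1, L + 1, matches);
      cols_.pop_back();
    }
    if (j < n3_) {                 // gap in the 5' copy
      cols_.push_back(2);
      linker(i, j + 1, c + 1, L, matches);
      cols_.pop_back();
    }
    if (i < n5_) {                 // gap in the 3' copy
      cols_.push_back(3);
      linker(i + 1, j, c + 1, L, matches);
      cols_.pop_back();
    }
  }
};

} // namespace

// [[Rcpp::export]]
Rcpp::RObject cpp_find_best_dr(Rcpp::IntegerVector w5_codes,
                               Rcpp::IntegerVector w3_codes,
                               int border5, int border3,
                               int min_length, int max_length,
                               int max_linker, int min_flank_block,
                               double min_similarity) {
  std::vector<int> x5(w5_codes.begin(), w5_codes.end());
  std::vector<int> x3(w3_codes.begin(), w3_codes.end());
  Params p{min_length, max_length, max_linker, min_flank_block,
           min_similarity};
  Search s(x5, x3, border5, border3, p);
  Cand best = s.run();
  if (!best.found) return R_NilValue;
  return Rcpp::List::create(
    Rcpp::Named("s5") = best.s5, Rcpp::Named("e5") = best.e5,
    Rcpp::Named("s3") = best.s3, Rcpp::Named("e3") = best.e3,
    Rcpp::Named("cols") = Rcpp::IntegerVector(best.cols.begin(),
                                              best.cols.end()),
    Rcpp::Named("length") = best.L, Rcpp::Named("matches") = best.matches);
}
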