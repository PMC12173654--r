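#include <Rcpp.h>
#include <string>

using namespace Rcpp;

// Exhaustive scan for the longest pair of direct-repeat copies flanking a
// deletion. Copies are compared without indels; a candidate of length L
// with mm mismatches is valid when mm <= floor(frac * L). The left copy
// must start within `window` bases of the left breakpoint and overlap or
// abut it; likewise the right copy and the right breakpoint. Copies never
// overlap each other.
//
// Coordinates are 0-based half-open: deletion = [del_start, del_end).
//
// [[Rcpp::export(name = ".scan_direct_repeats_cpp")]]
List scan_direct_repeats_cpp(const std::string& seq,
                             const int del_start, const int del_end,
                             const int window, const double frac,
                             const int min_len) {
  const int n = (int) seq.size();
  if (del_start < 0 || del_end > n || del_start >= del_end)
    stop("deletion interval out of bounds");

  int best_len = 0, best_mm = 0, best_i = -1, best_j = -1;

  const int i_lo = std::max(0, del_start - window);
  const int j_lo = std::max(0, del_end - window);

  for (int i = i_lo; i <= del_start; ++i) {
    for (int j = std::max(j_lo, i + 1); j <= del_end && j < n; ++j) {
      const int lcap = std::min(j - i, n - j);  // non-overlapping copies
      if (lcap < min_len) continue;
      const int mm_cap = (int) (frac * lcap);
      int mm = 0;
      for (int k = 0; k < lcap; ++k) {
        if (seq[i + k] != seq[j + k]) {
          ++mm;
          if (mm > mm_cap) break;
        }
        const int L = k + 1;
        if (mm > (int) (frac * L)) continue;
        if (L < min_len) continue;
        if (i + L < del_start) continue;          // must reach left breakpoint
        if (j + L < del_end) continue;            // must reach right breakpoint
        const bool better = (L > best_len) ||
          (L == best_len && (mm < best_mm ||
            (mm == best_mm && (i < best_i || (i == best_i && j < best_j)))));
        if (better) {
          best_len = L; best_mm = mm; best_i = i; best_j = j;
        }
      }
    }
  }

  if (best_len < min_len)
    return List::create(_["len"] = 0, _["mismatches"] = 0,
                        _["left_start"] = NA_INTEGER,
                        _["right_start"] = NA_INTEGER);
  return List::create(_["len"] = best_len, _["mismatches"] = best_mm,
                      _["left_start"] = best_i, _["right_start"] = best_j);
}
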