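#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>

using namespace Rcpp;

// Banded global alignment under unit edit costs (Levenshtein), with a
// traceback that reports, for every reference position, the read position
// aligned to it (NA when the reference base is deleted in the read).
//
// The band is centred on the main diagonal shifted by the length
// difference, so the result equals the true edit distance whenever the
// optimal path stays within `band` cells of that diagonal; otherwise it is
// an upper bound, which is all the unalignable gate needs.
//
// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(const std::string& ref, const std::string& read,
                      const int band) {
  const int n = (int) ref.size();   // reference length (rows)
  const int m = (int) read.size();  // read length (columns)
  if (n == 0 || m == 0)
    stop("empty sequence");

  const int d = m - n;
  const int lo_off = std::min(0, d) - band;  // j - i lower bound
  const int hi_off = std::max(0, d) + band;  // j - i upper bound
  const int w = hi_off - lo_off + 1;

  const int BIG = INT_MAX / 4;
  std::vector<int> prev((size_t) w, BIG), cur((size_t) w, BIG);
  // traceback: 0 = diag, 1 = up (ref base deleted), 2 = left (insertion)
  std::vector<unsigned char> tb((size_t)(n + 1) * (size_t) w, 0);

  // row 0: cost j for j in band
  for (int j = 0; j <= m; ++j) {
    int k = j - 0 - lo_off;
    if (k < 0 || k >= w) continue;
    prev[(size_t) k] = j;
    tb[(size_t) k] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), BIG);
    const int jmin = std::max(0, i + lo_off);
    const int jmax = std::min(m, i + hi_off);
    for (int j = jmin; j <= jmax; ++j) {
      const int k = j - i - lo_off;
      int best = BIG;
      unsigned char t = 1;
      // up: (i-1, j) -> offset k+1 in prev
      if (k + 1 < w && prev[(size_t)(k + 1)] < BIG) {
        best = prev[(size_t)(k + 1)] + 1;
        t = 1;
      }
      // left: (i, j-1) -> offset k-1 in cur
      if (j > 0 && k - 1 >= 0 && cur[(size_t)(k - 1)] < BIG &&
          cur[(size_t)(k - 1)] + 1 < best) {
        best = cur[(size_t)(k - 1)] + 1;
        t = 2;
      }
      // diag: (i-1, j-1) -> offset k in prev
      if (j > 0 && prev[(size_t) k] < BIG) {
        const int sub = prev[(size_t) k] + (ref[i - 1] == read[j - 1] ? 0 : 1);
        if (sub <= best) {  // prefer diagonal on ties (keeps map dense)
          best = sub;
          t = 0;
        }
      }
      cur[(size_t) k] = best;
      tb[(size_t) i * (size_t) w + (size_t) k] = t;
    }
    std::swap(prev, cur);
  }

  const int kend = m - n - lo_off;
  const int dist = (kend >= 0 && kend < w) ? prev[(size_t) kend] : BIG;
  if (dist >= BIG)
    return List::create(_["dist"] = NA_INTEGER,
                        _["refmap"] = IntegerVector(0));

  // traceback from (n, m)
  IntegerVector refmap(n, NA_INTEGER);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int k = j - i - lo_off;
    const unsigned char t = tb[(size_t) i * (size_t) w + (size_t) k];
    if (i > 0 && t == 0 && j > 0) {
      refmap[i - 1] = j;  // 1-based read position aligned to ref position i
      --i; --j;
    } else if (i > 0 && t == 1) {
      --i;                // ref base deleted in read
    } else if (j > 0) {
      --j;                // inserted read base
    } else {
      --i;
    }
  }

  return List::create(_["dist"] = dist, _["refmap"] = refmap);
}
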