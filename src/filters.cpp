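#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Median of an integer sample; even counts take the lower-biased integer
// mean of the two central order statistics (keeps output integral).
static int int_median(std::vector<int>& v) {
    size_t n = v.size();
    std::sort(v.begin(), v.end());
    if (n % 2 == 1) return v[n / 2];
    // floor of the average of the two middle values
    long s = (long)v[n / 2 - 1] + (long)v[n / 2];
    return (int)(s >= 0 ? s / 2 : -((-s + 1) / 2));
}

// Median filter restricted to mask pixels: each masked pixel is replaced by
// the median of the masked pixels inside its (2r+1)x(2r+1) window; pixels
// outside the mask pass through untouched. Windows never read outside the
// mask, so background zeros cannot bias boundary medians.
// [[Rcpp::export(name = ".masked_median_filter")]]
IntegerMatrix masked_median_filter(IntegerMatrix img, LogicalMatrix mask,
                                   int radius) {
    int nr = img.nrow(), nc = img.ncol();
    if (mask.nrow() != nr || mask.ncol() != nc)
        stop("image and mask dimensions differ");
    if (radius < 1) stop("radius must be >= 1");
    IntegerMatrix out(nr, nc);
    std::vector<int> win;
    win.reserve((2 * radius + 1) * (2 * radius + 1));
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (!mask(i, j)) { out(i, j) = img(i, j); continue; }
            win.clear();
            int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
            int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
            for (int jj = j0; jj <= j1; ++jj)
                for (int ii = i0; ii <= i1; ++ii)
                    if (mask(ii, jj)) win.push_back(img(ii, jj));
            out(i, j) = int_median(win);  // window always holds (i,j) itself
        }
    }
    return out;
}

// 4-connected component labelling of a binary mask. Labels are 1..k in
// first-encounter (column-major) order; background is 0.
// [[Rcpp::export(name = ".label_components4")]]
IntegerMatrix label_components4(LogicalMatrix mask) {
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    int next = 0;
    std::queue<std::pair<int, int> > q;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (!mask(i, j) || lab(i, j) != 0) continue;
            ++next;
            lab(i, j) = next;
            q.push(std::make_pair(i, j));
            while (!q.empty()) {
                int ci = q.front().first, cj = q.front().second;
                q.pop();
                const int di[4] = {-1, 1, 0, 0};
                const int dj[4] = {0, 0, -1, 1};
                for (int k = 0; k < 4; ++k) {
                    int ni = ci + di[k], nj = cj + dj[k];
                    if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
                    if (mask(ni, nj) && lab(ni, nj) == 0) {
                        lab(ni, nj) = next;
                        q.push(std::make_pair(ni, nj));
                    }
                }
            }
        }
    }
    return lab;
}
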