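// Deterministic DBSCAN on 2-D localization coordinates.
//
// Grid-indexed fixed-radius neighbour search (cell width = eps, 3x3 cell
// scan), classic core/border expansion. Determinism: points are visited in
// ascending index order, the seed list is processed in order, and region
// queries return neighbours in ascending index order, so a border point
// reachable from two clusters is assigned to the cluster discovered first.
//
// Labels are 0-based cluster ids, -1 for noise. A point counts as its own
// neighbour, i.e. a core point has >= minPts points within eps inclusive.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static const int UNDEF = -2;
static const int NOISE = -1;

static inline int64_t cell_key(int cx, int cy) {
    return (static_cast<int64_t>(cx) << 32) ^
           (static_cast<int64_t>(cy) & 0xffffffffLL);
}

// [[Rcpp::export(name = ".dbscan_cpp")]]
IntegerVector dbscan_cpp(NumericVector x, NumericVector y,
                         double eps, int minPts) {
    const int n = x.size();
    if (n == 0)
        return IntegerVector(0);
    if (eps <= 0)
        stop("eps must be > 0");
    if (minPts < 1)
        stop("minPts must be >= 1");

    const double eps2 = eps * eps;

    // spatial hash grid, cell width eps; member lists ascending by index
    std::unordered_map<int64_t, std::vector<int> > grid;
    grid.reserve(static_cast<size_t>(n));
    std::vector<int> cxs(n), cys(n);
    for (int i = 0; i < n; ++i) {
        cxs[i] = static_cast<int>(std::floor(x[i] / eps));
        cys[i] = static_cast<int>(std::floor(y[i] / eps));
        grid[cell_key(cxs[i], cys[i])].push_back(i);
    }

    std::vector<int> neigh;
    neigh.reserve(64);
    auto region_query = [&](int i) {
        neigh.clear();
        for (int dx = -1; dx <= 1; ++dx) {
            for (int dy = -1; dy <= 1; ++dy) {
                auto it = grid.find(cell_key(cxs[i] + dx, cys[i] + dy));
                if (it == grid.end())
                    continue;
                for (int j : it->second) {
                    const double ddx = x[j] - x[i];
                    const double ddy = y[j] - y[i];
                    if (ddx * ddx + ddy * ddy <= eps2)
                        neigh.push_back(j);
                }
            }
        }
        std::sort(neigh.begin(), neigh.end());
    };

    std::vector<int> labels(n, UNDEF);
    std::vector<int> seeds;
    int cluster = -1;

    for (int i = 0; i < n; ++i) {
        if (labels[i] != UNDEF)
            continue;
        region_query(i);
        if (static_cast<int>(neigh.size()) < minPts) {
            labels[i] = NOISE; // may be claimed later as a border point
            continue;
        }
        ++cluster;
        labels[i] = cluster;
        seeds.assign(neigh.begin(), neigh.end());
        for (size_t si = 0; si < seeds.size(); ++si) {
            const int q = seeds[si];
            if (labels[q] == NOISE)
                labels[q] = cluster; // border point
            if (labels[q] != UNDEF)
                continue;
            labels[q] = cluster;
            region_query(q);
            if (static_cast<int>(neigh.size()) >= minPts)
                seeds.insert(seeds.end(), neigh.begin(), neigh.end());
        }
    }

    IntegerVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = labels[i] == UNDEF ? NOISE : labels[i];
    return out;
}
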