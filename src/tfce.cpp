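#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// neighbour offsets for 6/18/26 connectivity on a 3D grid
static std::vector<std::array<int,3>> neighbour_offsets(int connectivity) {
    std::vector<std::array<int,3>> offs;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (nz == 0) continue;
                if (connectivity == 6 && nz > 1) continue;
                if (connectivity == 18 && nz > 2) continue;
                offs.push_back({dx, dy, dz});
            }
    return offs;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int n = nx * ny * nz;
    IntegerVector labels(n, 0);
    std::vector<std::array<int,3>> offs = neighbour_offsets(connectivity);
    int current = 0;
    std::queue<int> q;
    for (int i = 0; i < n; ++i) {
        if (!mask[i] || labels[i] != 0) continue;
        ++current;
        labels[i] = current;
        q.push(i);
        while (!q.empty()) {
            int v = q.front(); q.pop();
            int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
            for (size_t k = 0; k < offs.size(); ++k) {
                int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                int w = xx + nx * (yy + ny * zz);
                if (mask[w] && labels[w] == 0) {
                    labels[w] = current;
                    q.push(w);
                }
            }
        }
    }
    labels.attr("dim") = dims;
    return labels;
}

struct DSU {
    std::vector<int> parent, size, node;
    int find(int v) {
        while (parent[v] != v) {
            parent[v] = parent[parent[v]];
            v = parent[v];
        }
        return v;
    }
};

// TFCE enhancement of a non-negative statistic map (one sign branch).
// enhanced(v) = sum over thresholds h = dh, 2dh, ... of
//   extent_h(component of v)^E * h^H * dh.
// Implemented by processing thresholds from high to low with a union-find
// merge tree: per threshold each active component root accrues one
// contribution, pushed down to member voxels at the end. NaN / negative
// values are background.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       double E, double H, double dh, int connectivity) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int n = nx * ny * nz;
    NumericVector out(n, 0.0);
    out.attr("dim") = dims;
    double mx = 0.0;
    for (int i = 0; i < n; ++i)
        if (R_finite(stat[i]) && stat[i] > mx) mx = stat[i];
    if (mx <= 0.0 || dh <= 0.0) return out;
    int T = (int)std::floor(mx / dh + 1e-12);
    if (T < 1) return out;

    std::vector<std::array<int,3>> offs = neighbour_offsets(connectivity);
    std::vector<int> order;
    order.reserve(n / 4);
    for (int i = 0; i < n; ++i)
        if (R_finite(stat[i]) && stat[i] >= dh) order.push_back(i);
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return stat[a] > stat[b]; });

    DSU dsu;
    dsu.parent.assign(n, -1);
    dsu.size.assign(n, 0);
    dsu.node.assign(n, -1);
    // merge-tree nodes: leaves = voxels, internal = merges; parent index
    // always larger than child indices
    std::vector<double> acc;
    std::vector<int> child1, child2, leaf_of(n, -1);
    acc.reserve(2 * order.size());
    std::vector<int> roots;            // candidate root voxels (may go stale)

    size_t next = 0;
    for (int t = T; t >= 1; --t) {
        double h = t * dh;
        // activate voxels with stat >= h
        while (next < order.size() && stat[order[next]] >= h) {
            int v = order[next++];
            dsu.parent[v] = v;
            dsu.size[v] = 1;
            int leaf = (int)acc.size();
            acc.push_back(0.0); child1.push_back(-1); child2.push_back(-1);
            dsu.node[v] = leaf;
            leaf_of[v] = leaf;
            roots.push_back(v);
            int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
            for (size_t k = 0; k < offs.size(); ++k) {
                int xx = x + offs[k][0], yy = y + offs[k][1],
                    zz = z + offs[k][2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz)
                    continue;
                int w = xx + nx * (yy + ny * zz);
                if (dsu.parent[w] == -1) continue;   // not yet active
                int rv = dsu.find(v), rw = dsu.find(w);
                if (rv == rw) continue;
                if (dsu.size[rv] < dsu.size[rw]) std::swap(rv, rw);
                int m = (int)acc.size();
                acc.push_back(0.0);
                child1.push_back(dsu.node[rv]);
                child2.push_back(dsu.node[rw]);
                dsu.parent[rw] = rv;
                dsu.size[rv] += dsu.size[rw];
                dsu.node[rv] = m;
            }
        }
        // one contribution per live component at this threshold
        double hH = std::pow(h, H) * dh;
        size_t keep = 0;
        for (size_t i = 0; i < roots.size(); ++i) {
            int v = roots[i];
            if (dsu.find(v) != v) continue;          // stale: absorbed
            roots[keep++] = v;
            acc[dsu.node[v]] += std::pow((double)dsu.size[v], E) * hH;
        }
        roots.resize(keep);
    }
    // push accumulated contributions down the merge tree
    for (int m = (int)acc.size() - 1; m >= 0; --m) {
        if (child1[m] >= 0) acc[child1[m]] += acc[m];
        if (child2[m] >= 0) acc[child2[m]] += acc[m];
    }
    for (int i = 0; i < n; ++i)
        if (leaf_of[i] >= 0) out[i] = acc[leaf_of[i]];
    return out;
}
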