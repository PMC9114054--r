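#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 3D logical mask.
// connectivity: 26 (full 3D) or 8 (in-plane only; used per-slice from R,
// where it reduces to classical 2D 8-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label_cc(LogicalVector mask, IntegerVector dim,
                           int connectivity) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector labels(n);
    const int* msk = LOGICAL(mask);
    int* lab = INTEGER(labels);

    // neighbour offsets
    std::vector<int> dxs, dys, dzs;
    const int zmax = (connectivity == 8) ? 0 : 1;
    for (int dz = -zmax; dz <= zmax; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
            }
    const int nn = (int)dxs.size();

    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!msk[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            const int z = (int)(cur / ((R_xlen_t)nx * ny));
            const int rem = (int)(cur - (R_xlen_t)z * nx * ny);
            const int y = rem / nx, x = rem - y * nx;
            for (int k = 0; k < nn; ++k) {
                const int x2 = x + dxs[k], y2 = y + dys[k], z2 = z + dzs[k];
                if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                    z2 < 0 || z2 >= nz) continue;
                const R_xlen_t j = (R_xlen_t)x2 + (R_xlen_t)nx * ((R_xlen_t)y2 + (R_xlen_t)ny * z2);
                if (msk[j] && !lab[j]) {
                    lab[j] = next;
                    stack.push_back(j);
                }
            }
        }
    }
    labels.attr("n_components") = next;
    return labels;
}
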