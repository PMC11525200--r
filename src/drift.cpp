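#include <Rcpp.h>
#include <vector>
#include <functional>
#include <cmath>
using namespace Rcpp;

// Critical birth-death (birth = death = kappa per cell) clone trajectories.
// One Gillespie stream per clone; sizes recorded at the requested times.
// [[Rcpp::export]]
IntegerMatrix cpp_bd_trajectories(IntegerVector n0, double kappa,
                                  NumericVector times) {
    const int nclone = n0.size(), nt = times.size();
    IntegerMatrix out(nclone, nt);
    for (int c = 0; c < nclone; ++c) {
        long n = n0[c];
        double t = 0.0;
        int j = 0;
        while (j < nt) {
            if (n == 0) {
                for (; j < nt; ++j) out(c, j) = 0;
                break;
            }
            double rate = 2.0 * kappa * (double)n;
            double dt = R::rexp(1.0 / rate);
            while (j < nt && t + dt > times[j]) {
                out(c, j) = (int)n;
                ++j;
            }
            if (j >= nt) break;
            t += dt;
            if (R::unif_rand() < 0.5) ++n; else --n;
        }
    }
    return out;
}

static inline int wrap(int i, int n) { return i < 0 ? n - 1 : (i >= n ? 0 : i); }

// Voter-model lattice of division-stratification events. States: 0 =
// unlabeled, 1..k = label colors. Every event a uniformly chosen cell
// divides; the displaced (stratifying) cell is a uniform von Neumann
// neighbor ("neighbor" mode) or a uniform lattice site ("mean_field" mode)
// and is replaced by the daughter, so occupancy is conserved exactly.
// Returns snapshots at multiples of sampleInterval (including t = 0).
// [[Rcpp::export]]
List cpp_run_lattice(IntegerVector grid0, int width, int height,
                     bool periodic, bool meanField, double lambda,
                     double duration, double sampleInterval) {
    const int N = width * height;
    std::vector<int> grid(grid0.begin(), grid0.end());
    const double totalRate = lambda * (double)N;
    int nsamp = (int)std::floor(duration / sampleInterval + 1e-9) + 1;
    List snaps(nsamp);
    NumericVector stimes(nsamp);
    // snapshot at t = 0
    snaps[0] = IntegerVector(grid.begin(), grid.end());
    stimes[0] = 0.0;
    if (lambda <= 0.0) {
        for (int s = 1; s < nsamp; ++s) {
            snaps[s] = IntegerVector(grid.begin(), grid.end());
            stimes[s] = s * sampleInterval;
        }
        return List::create(_["times"] = stimes, _["snapshots"] = snaps);
    }
    double t = 0.0;
    int s = 1;
    while (s < nsamp) {
        double dt = R::rexp(1.0 / totalRate);
        while (s < nsamp && t + dt > s * sampleInterval) {
            snaps[s] = IntegerVector(grid.begin(), grid.end());
            stimes[s] = s * sampleInterval;
            ++s;
        }
        if (s >= nsamp) break;
        t += dt;
        int mother = (int)(R::unif_rand() * N);
        if (mother >= N) mother = N - 1;
        int target;
        if (meanField) {
            target = (int)(R::unif_rand() * N);
            if (target >= N) target = N - 1;
        } else {
            int x = mother % width, y = mother / width;
            int dir = (int)(R::unif_rand() * 4.0);
            int nx = x, ny = y;
            switch (dir) {
            case 0: nx = x + 1; break;
            case 1: nx = x - 1; break;
            case 2: ny = y + 1; break;
            default: ny = y - 1; break;
            }
            if (periodic) {
                nx = wrap(nx, width);
                ny = wrap(ny, height);
            } else { // reflecting: off-lattice moves bounce back
                if (nx < 0 || nx >= width) nx = x;
                if (ny < 0 || ny >= height) ny = y;
            }
            target = ny * width + nx;
        }
        grid[target] = grid[mother]; // daughter replaces stratifying cell
    }
    return List::create(_["times"] = stimes, _["snapshots"] = snaps);
}

// Same-color connected components (union-find). Unlabeled (0) excluded.
// connectivity: 4 or 8. Non-periodic: measured images have edges.
// Returns a labeling matrix-vector of component ids (0 for unlabeled) and
// per-component (color, size) tables.
// [[Rcpp::export]]
List cpp_label_components(IntegerVector grid, int width, int height,
                          int connectivity) {
    const int N = width * height;
    std::vector<int> parent(N);
    for (int i = 0; i < N; ++i) parent[i] = i;
    std::function<int(int)> find = [&](int i) {
        while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
        return i;
    };
    auto unite = [&](int a, int b) {
        a = find(a); b = find(b);
        if (a != b) parent[b] = a;
    };
    for (int y = 0; y < height; ++y) {
        for (int x = 0; x < width; ++x) {
            int i = y * width + x;
            int c = grid[i];
            if (c == 0) continue;
            if (x + 1 < width && grid[i + 1] == c) unite(i, i + 1);
            if (y + 1 < height && grid[i + width] == c) unite(i, i + width);
            if (connectivity == 8) {
                if (x + 1 < width && y + 1 < height &&
                    grid[i + width + 1] == c) unite(i, i + width + 1);
                if (x > 0 && y + 1 < height &&
                    grid[i + width - 1] == c) unite(i, i + width - 1);
            }
        }
    }
    std::vector<int> compId(N, 0), compColor, compSize;
    int nextId = 0;
    std::vector<int> rootId(N, -1);
    for (int i = 0; i < N; ++i) {
        if (grid[i] == 0) continue;
        int r = find(i);
        if (rootId[r] < 0) {
            rootId[r] = nextId++;
            compColor.push_back(grid[i]);
            compSize.push_back(0);
        }
        compId[i] = rootId[r] + 1;
        compSize[rootId[r]] += 1;
    }
    return List::create(
        _["component"] = IntegerVector(compId.begin(), compId.end()),
        _["color"] = IntegerVector(compColor.begin(), compColor.end()),
        _["size"] = IntegerVector(compSize.begin(), compSize.end()));
}
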