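#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Incremental NODF bookkeeping for a binary bipartite matrix.
//
// NODF pair term (pairwise, order-invariant form): for an unordered pair of
// rows (or columns) with degrees d_i, d_j and shared-link count o, the term
// is 100 * o / min(d_i, d_j) when d_i != d_j, else 0.  NODF is the sum of
// all row-pair and column-pair terms divided by C(m,2) + C(n,2).
//
// A single-link move touches at most 2 rows and 2 columns, so only pair
// terms involving those lines change; each move costs O(m + n).

static inline double pair_term(int di, int dj, int o) {
    if (di == dj) return 0.0;
    int mn = di < dj ? di : dj;
    if (mn == 0) return 0.0;
    return 100.0 * (double)o / (double)mn;
}

struct NodfState {
    int m, n;
    std::vector<int> M;      // row-major m x n, entries 0/1
    std::vector<int> rdeg, cdeg;
    std::vector<int> orow;   // m x m shared-link counts (diag = degree)
    std::vector<int> ocol;   // n x n
    double npairs;
    double pairsum;

    int cell(int r, int c) const { return M[(size_t)r * n + c]; }
    void set_cell(int r, int c, int v) { M[(size_t)r * n + c] = v; }
    int& ov_r(int i, int j) { return orow[(size_t)i * m + j]; }
    int& ov_c(int i, int j) { return ocol[(size_t)i * n + j]; }

    void init(const IntegerMatrix& mat) {
        m = mat.nrow(); n = mat.ncol();
        M.assign((size_t)m * n, 0);
        rdeg.assign(m, 0); cdeg.assign(n, 0);
        orow.assign((size_t)m * m, 0);
        ocol.assign((size_t)n * n, 0);
        for (int r = 0; r < m; ++r)
            for (int c = 0; c < n; ++c)
                if (mat(r, c) != 0) { set_cell(r, c, 1); rdeg[r]++; cdeg[c]++; }
        for (int i = 0; i < m; ++i)
            for (int j = i; j < m; ++j) {
                int o = 0;
                for (int c = 0; c < n; ++c) o += cell(i, c) & cell(j, c);
                ov_r(i, j) = o; ov_r(j, i) = o;
            }
        for (int i = 0; i < n; ++i)
            for (int j = i; j < n; ++j) {
                int o = 0;
                for (int r = 0; r < m; ++r) o += cell(r, i) & cell(r, j);
                ov_c(i, j) = o; ov_c(j, i) = o;
            }
        npairs = 0.5 * m * (m - 1) + 0.5 * n * (n - 1);
        recompute_pairsum();
    }

    void recompute_pairsum() {
        double s = 0.0;
        for (int i = 0; i < m; ++i)
            for (int j = i + 1; j < m; ++j)
                s += pair_term(rdeg[i], rdeg[j], ov_r(i, j));
        for (int i = 0; i < n; ++i)
            for (int j = i + 1; j < n; ++j)
                s += pair_term(cdeg[i], cdeg[j], ov_c(i, j));
        pairsum = s;
    }

    double nodf() const { return npairs > 0 ? pairsum / npairs : 0.0; }

    // sum of row-pair terms over pairs involving r1 or r2 (r2 may equal r1)
    double rows_sum_involving(int r1, int r2) {
        double s = 0.0;
        for (int i = 0; i < m; ++i) {
            if (i == r1) continue;
            s += pair_term(rdeg[i], rdeg[r1], ov_r(i, r1));
        }
        if (r2 != r1)
            for (int i = 0; i < m; ++i) {
                if (i == r2 || i == r1) continue;
                s += pair_term(rdeg[i], rdeg[r2], ov_r(i, r2));
            }
        return s;
    }
    double cols_sum_involving(int c1, int c2) {
        double s = 0.0;
        for (int j = 0; j < n; ++j) {
            if (j == c1) continue;
            s += pair_term(cdeg[j], cdeg[c1], ov_c(j, c1));
        }
        if (c2 != c1)
            for (int j = 0; j < n; ++j) {
                if (j == c2 || j == c1) continue;
                s += pair_term(cdeg[j], cdeg[c2], ov_c(j, c2));
            }
        return s;
    }

    void remove_link(int r, int c) {
        set_cell(r, c, 0); rdeg[r]--; cdeg[c]--;
        for (int i = 0; i < m; ++i) {
            int d = cell(i, c);
            if (i == r) { ov_r(r, r) = rdeg[r]; continue; }
            ov_r(i, r) -= d; ov_r(r, i) -= d;
        }
        for (int j = 0; j < n; ++j) {
            int d = cell(r, j);
            if (j == c) { ov_c(c, c) = cdeg[c]; continue; }
            ov_c(j, c) -= d; ov_c(c, j) -= d;
        }
    }
    void add_link(int r, int c) {
        set_cell(r, c, 1); rdeg[r]++; cdeg[c]++;
        for (int i = 0; i < m; ++i) {
            int d = cell(i, c);
            if (i == r) { ov_r(r, r) = rdeg[r]; continue; }
            ov_r(i, r) += d; ov_r(r, i) += d;
        }
        for (int j = 0; j < n; ++j) {
            int d = cell(r, j);
            if (j == c) { ov_c(c, c) = cdeg[c]; continue; }
            ov_c(j, c) += d; ov_c(c, j) += d;
        }
    }

    // move link from (r1,c1) to (r2,c2), updating pairsum incrementally
    void move(int r1, int c1, int r2, int c2) {
        double before = rows_sum_involving(r1, r2) + cols_sum_involving(c1, c2);
        remove_link(r1, c1);
        add_link(r2, c2);
        double after = rows_sum_involving(r1, r2) + cols_sum_involving(c1, c2);
        pairsum += after - before;
    }

    // NODF gain of hypothetically adding a link at empty (r,c)
    double add_gain(int r, int c) {
        double before = rows_sum_involving(r, r) + cols_sum_involving(c, c);
        add_link(r, c);
        double after = rows_sum_involving(r, r) + cols_sum_involving(c, c);
        remove_link(r, c);
        return (after - before) / (npairs > 0 ? npairs : 1.0);
    }

    IntegerMatrix as_matrix() const {
        IntegerMatrix out(m, n);
        for (int r = 0; r < m; ++r)
            for (int c = 0; c < n; ++c) out(r, c) = cell(r, c);
        return out;
    }
};

// [[Rcpp::export(name = ".nodf_total_cpp")]]
double nodf_total_cpp(IntegerMatrix mat) {
    NodfState st;
    st.init(mat);
    return st.nodf();
}

// Greedy maximization: add L links one at a time, each at the position with
// the largest NODF gain (first in row-major order on ties), restricted to
// positions that keep full row/column coverage achievable with the budget
// left: when only max(#uncovered rows, #uncovered cols) links remain, every
// new link must cover a new row/column as needed.
// [[Rcpp::export(name = ".greedy_max_cpp")]]
List greedy_max_cpp(int m, int n, int L) {
    NodfState st;
    st.init(IntegerMatrix(m, n));
    int u_r = m, u_c = n;
    long long evals = 0;
    for (int k = 0; k < L; ++k) {
        int remaining = L - k;
        int best_r = -1, best_c = -1;
        double best_gain = 0.0;
        bool have = false;
        for (int r = 0; r < m; ++r) {
            for (int c = 0; c < n; ++c) {
                if (st.cell(r, c)) continue;
                int ur2 = u_r - (st.rdeg[r] == 0 ? 1 : 0);
                int uc2 = u_c - (st.cdeg[c] == 0 ? 1 : 0);
                if ((ur2 > uc2 ? ur2 : uc2) > remaining - 1) continue;
                double g = st.add_gain(r, c);
                ++evals;
                if (!have || g > best_gain + 1e-12) {
                    have = true; best_gain = g; best_r = r; best_c = c;
                }
            }
        }
        if (!have) stop("greedy: no admissible position (infeasible shape?)");
        if (st.rdeg[best_r] == 0) u_r--;
        if (st.cdeg[best_c] == 0) u_c--;
        st.add_link(best_r, best_c);
    }
    st.recompute_pairsum();
    return List::create(_["matrix"] = st.as_matrix(),
                        _["nodf"] = st.nodf(),
                        _["evaluations"] = (double)evals);
}

static inline int sample_int(int k) {
    int v = (int)(unif_rand() * k);
    return v >= k ? k - 1 : v;
}

// Classical simulated annealing over single-link moves.
// Uses R's RNG stream (seed via set.seed() before the call).
// t0 = NA -> calibrate so the initial uphill acceptance rate is about
// accept_target; tmin = NA -> t0 * 1e-4.
// [[Rcpp::export(name = ".sa_cpp")]]
List sa_cpp(IntegerMatrix init, double t0, double tmin, double alpha,
            int n_per_temp, double accept_target, bool record_trajectory) {
    NodfState st;
    st.init(init);
    int m = st.m, n = st.n;
    int ncell = m * n;

    // occupied / empty cell lists with positional index for O(1) moves
    std::vector<int> occ, emp, pos((size_t)ncell), inocc((size_t)ncell);
    for (int r = 0; r < m; ++r)
        for (int c = 0; c < n; ++c) {
            int idx = r * n + c;
            if (st.cell(r, c)) { inocc[idx] = 1; pos[idx] = occ.size(); occ.push_back(idx); }
            else { inocc[idx] = 0; pos[idx] = emp.size(); emp.push_back(idx); }
        }
    int L = occ.size();

    double best_nodf = st.nodf();
    IntegerMatrix best_mat = clone(st.as_matrix());
    long long evals = 1;

    // a legal move needs a removable link (row & col degree > 1) and an
    // empty target; if none exists the start is returned unchanged
    bool movable = false;
    for (int i = 0; i < L && !movable; ++i) {
        int r = occ[i] / n, c = occ[i] % n;
        if (st.rdeg[r] > 1 && st.cdeg[c] > 1) movable = true;
    }
    if (!movable || emp.empty()) {
        return List::create(_["best_matrix"] = best_mat,
                            _["best_nodf"] = best_nodf,
                            _["evaluations"] = (double)evals,
                            _["t0"] = NA_REAL, _["t_min"] = NA_REAL,
                            _["trajectory"] = R_NilValue);
    }

    auto draw_removal = [&]() {
        for (;;) {
            int idx = occ[sample_int(L)];
            int r = idx / n, c = idx % n;
            if (st.rdeg[r] > 1 && st.cdeg[c] > 1) return idx;
        }
    };

    // temperature calibration from 100 sampled moves
    if (!R_finite(t0)) {
        double up_sum = 0.0; int up_n = 0;
        double cost0 = 1.0 - st.nodf() / 100.0;
        for (int s = 0; s < 100; ++s) {
            int a = draw_removal();
            int b = emp[sample_int((int)emp.size())];
            st.move(a / n, a % n, b / n, b % n);
            ++evals;
            double d = (1.0 - st.nodf() / 100.0) - cost0;
            st.move(b / n, b % n, a / n, a % n);
            if (d > 0) { up_sum += d; ++up_n; }
        }
        t0 = up_n > 0 ? (up_sum / up_n) / (-std::log(accept_target)) : 1e-2;
        if (t0 <= 0) t0 = 1e-2;
    }
    if (!R_finite(tmin)) tmin = t0 * 1e-4;

    double T = t0;
    double cost = 1.0 - st.nodf() / 100.0;
    double best_cost = 1.0 - best_nodf / 100.0;
    std::vector<double> traj_T, traj_best, traj_acc;
    long long moves_since_sync = 0;

    while (T > tmin) {
        int accepted = 0;
        for (int it = 0; it < n_per_temp; ++it) {
            int a = draw_removal();
            int b = emp[sample_int((int)emp.size())];
            int r1 = a / n, c1 = a % n, r2 = b / n, c2 = b % n;
            st.move(r1, c1, r2, c2);
            ++evals;
            if (++moves_since_sync >= 4096) {   // cancel float drift
                st.recompute_pairsum();
                moves_since_sync = 0;
            }
            double cost2 = 1.0 - st.nodf() / 100.0;
            bool accept = (cost2 <= cost) ||
                          (unif_rand() < std::exp((cost - cost2) / T));
            if (accept) {
                cost = cost2;
                ++accepted;
                // swap cell list membership
                int pa = pos[a], pb = pos[b];
                occ[pa] = b; emp[pb] = a;
                pos[b] = pa; pos[a] = pb;
                inocc[a] = 0; inocc[b] = 1;
                if (cost < best_cost) {
                    best_cost = cost;
                    best_nodf = st.nodf();
                    best_mat = clone(st.as_matrix());
                }
            } else {
                st.move(r2, c2, r1, c1);
            }
        }
        if (record_trajectory) {
            traj_T.push_back(T);
            traj_best.push_back(best_nodf);
            traj_acc.push_back((double)accepted / n_per_temp);
        }
        T *= alpha;
    }

    SEXP traj = R_NilValue;
    if (record_trajectory) {
        traj = DataFrame::create(_["temperature"] = traj_T,
                                 _["best_nodf"] = traj_best,
                                 _["acceptance_rate"] = traj_acc);
    }
    return List::create(_["best_matrix"] = best_mat,
                        _["best_nodf"] = best_nodf,
                        _["evaluations"] = (double)evals,
                        _["t0"] = t0, _["t_min"] = tmin,
                        _["trajectory"] = traj);
}
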