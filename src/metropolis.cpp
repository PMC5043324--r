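#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Pair-wise contribution to the heterosexual-fraction integrand:
// g(A, B) = (A^2 + B^2) / (A + B), with the 0/0 cell defined as 0
// (no individuals exist in either reciprocal group).
static inline double gfun(double A, double B) {
    double s = A + B;
    return (s > 0.0) ? (A * A + B * B) / s : 0.0;
}

// Full double sum S = sum_{i,j} g(p_i q_j, q_i p_j) with q = reverse(p).
// The heterosexual fraction is n = S * dx^2 / 2.
static double het_sum(const std::vector<double>& p) {
    const int M = (int)p.size();
    double S = 0.0;
    for (int i = 0; i < M; ++i) {
        const double pi = p[i], qi = p[M - 1 - i];
        for (int j = 0; j < M; ++j) {
            S += gfun(pi * p[M - 1 - j], qi * p[j]);
        }
    }
    return S;
}

// Contribution to S of all pairs (i,j) with i or j in the index set D.
// Used for O(M) incremental updates when only cells in D changed.
static double het_sum_affected(const std::vector<double>& p,
                               const std::vector<int>& D,
                               const std::vector<char>& inD) {
    const int M = (int)p.size();
    double S = 0.0;
    for (size_t k = 0; k < D.size(); ++k) {
        const int i = D[k];
        const double pi = p[i], qi = p[M - 1 - i];
        for (int j = 0; j < M; ++j)
            S += gfun(pi * p[M - 1 - j], qi * p[j]);
    }
    // columns j in D, rows i not in D (avoid double count)
    for (size_t k = 0; k < D.size(); ++k) {
        const int j = D[k];
        const double pj = p[j], qj = p[M - 1 - j];
        for (int i = 0; i < M; ++i) {
            if (inD[i]) continue;
            S += gfun(p[i] * qj, p[M - 1 - i] * pj);
        }
    }
    return S;
}

static inline double xlogx(double v) { return (v > 0.0) ? v * std::log(v) : 0.0; }

// Build the per-cell density changes of a smoothed mass-exchange move:
// withdraw mass dp (density units) as a kernel bump at cell a — capped at
// the mass available in each cell — and deposit exactly the withdrawn
// total as a kernel bump at cell b. R = 0 gives single-cell moves with a
// hard negativity rejection. Returns false if the move is void.
static bool build_move(const std::vector<double>& p, int M, int R,
                       const std::vector<double>& kern, int a, int b,
                       double dp, std::vector<int>& chg_idx,
                       std::vector<double>& chg_dp) {
    chg_idx.clear(); chg_dp.clear();
    if (a == b || dp <= 0.0) return false;
    if (R == 0) {
        if (p[a] - dp < 0.0) return false;
        chg_idx.push_back(a); chg_dp.push_back(-dp);
        chg_idx.push_back(b); chg_dp.push_back(dp);
        return true;
    }
    double wa = 0.0, wb = 0.0;
    for (int k = -R; k <= R; ++k) {
        if (a + k >= 0 && a + k < M) wa += kern[k + R];
        if (b + k >= 0 && b + k < M) wb += kern[k + R];
    }
    double W = 0.0;
    for (int k = -R; k <= R; ++k) {
        const int ia = a + k;
        if (ia < 0 || ia >= M) continue;
        const double want = dp * kern[k + R] / wa;
        const double take = (want > p[ia]) ? p[ia] : want;
        if (take > 0.0) { chg_idx.push_back(ia); chg_dp.push_back(-take); W += take; }
    }
    if (W <= 0.0) return false;
    for (int k = -R; k <= R; ++k) {
        const int ib = b + k;
        if (ib >= 0 && ib < M) { chg_idx.push_back(ib); chg_dp.push_back(W * kern[k + R] / wb); }
    }
    return true;
}

// [[Rcpp::export]]
double cpp_het_sum(NumericVector p) {
    std::vector<double> pv(p.begin(), p.end());
    return het_sum(pv);
}

// Gradient of the heterosexual double sum S with respect to the density
// values p (q = reverse(p) is eliminated via the mirror symmetry).
// [[Rcpp::export]]
NumericVector cpp_het_sum_grad(NumericVector p) {
    const int M = p.size();
    NumericVector grad(M);
    for (int i = 0; i < M; ++i) {
        const double pi = p[i], qi = p[M - 1 - i];
        for (int j = 0; j < M; ++j) {
            const double qj = p[M - 1 - j], pj = p[j];
            const double A = pi * qj, B = qi * pj;
            const double s = A + B;
            if (s <= 1e-150) continue;   // also guards s^2 underflow
            const double gA = (A * A + 2.0 * A * B - B * B) / (s * s);
            const double gB = (B * B + 2.0 * A * B - A * A) / (s * s);
            grad[i]         += gA * qj;
            grad[M - 1 - j] += gA * pi;
            grad[M - 1 - i] += gB * pj;
            grad[j]         += gB * qi;
        }
    }
    return grad;
}

// Metropolis simulated annealing over the discretized trait density.
// measure: 0 = entropy diversity term, 1 = variance diversity term.
// Proposals move a uniform amount of probability mass (at most
// step_size * dx) from one random cell to another, so normalization is
// conserved exactly; moves that would drive a cell negative are rejected.
// beta is annealed geometrically from beta_start to beta_end.
// [[Rcpp::export]]
List cpp_metropolis(NumericVector p0, double dx, double t, int measure,
                    int n_iter, double beta_start, double beta_end,
                    double step_size, int trace_every, double tol,
                    int window, int avg_from, double kw_start, double kw_end,
                    double step_end) {
    const int M = p0.size();
    std::vector<double> p(p0.begin(), p0.end());
    std::vector<double> p_acc(M, 0.0);
    long long n_acc = 0;

    // proposal kernel: mass is deposited/removed as a small Gaussian bump
    // (width in cells; <= 0.05 treated as single-cell moves). The width is
    // annealed geometrically from kw_start to kw_end alongside beta, so the
    // macroscopic shape forms under smooth proposals and only sharpens once
    // the chain is nearly greedy (coarse-to-fine). Kernels are truncated at
    // radius 3*sigma and re-normalized per proposal at the grid boundary so
    // each bump carries exactly the proposed mass.
    const double KW_MIN = 0.05;
    int R = 0;
    std::vector<double> kern;
    double kw_cur = -1.0;
    auto set_kernel = [&](double kw) {
        if (kw <= KW_MIN) { R = 0; kern.assign(1, 1.0); kw_cur = 0.0; return; }
        if (kw_cur > 0.0 && std::fabs(kw - kw_cur) < 0.02 * kw_cur) return;
        R = (int)std::ceil(3.0 * kw);
        kern.assign(2 * R + 1, 0.0);
        for (int k = -R; k <= R; ++k)
            kern[k + R] = std::exp(-0.5 * (k * k) / (kw * kw));
        kw_cur = kw;
    };
    set_kernel(kw_start);
    const double kw_log_ratio =
        (kw_start > KW_MIN) ? std::log(std::max(kw_end, KW_MIN / 2) / kw_start) : 0.0;
    const double step_log_ratio =
        (step_end > 0.0) ? std::log(step_end / step_size) : 0.0;

    // tracked state
    double S = het_sum(p);                        // heterosexual double sum
    double H = 0.0, m1 = 0.0, m2 = 0.0;           // entropy sum, moments
    for (int i = 0; i < M; ++i) {
        const double x = (i + 0.5) * dx;
        H  -= xlogx(p[i]) * dx;
        m1 += x * p[i] * dx;
        m2 += x * x * p[i] * dx;
    }

    auto fitness_of = [&](double Sv, double Hv, double m1v, double m2v) {
        double n = 0.5 * Sv * dx * dx;
        if (n < 0.0) n = 0.0;
        if (n > 1.0) n = 1.0;
        double div = (measure == 0) ? Hv : (m2v - m1v * m1v);
        return n * (1.0 + t * div);
    };

    double f = fitness_of(S, H, m1, m2);
    std::vector<double> best_p = p;
    double best_f = f;

    const double log_ratio = std::log(beta_end / beta_start);
    long long accepted = 0;
    std::vector<int> trace_it;
    std::vector<double> trace_f;
    std::vector<int> D;
    std::vector<char> inD(M, 0);
    std::vector<int> chg_idx;
    std::vector<double> chg_dp;
    std::vector<double> acc_dp(M, 0.0);
    std::vector<double> p_save;

    double window_ref = best_f;
    bool converged = false;

    for (int it = 0; it < n_iter; ++it) {
        const double frac = (n_iter > 1) ? (double)it / (n_iter - 1) : 1.0;
        const double beta = beta_start * std::exp(log_ratio * frac);
        if (kw_log_ratio != 0.0 && (it % 1000) == 0)
            set_kernel(kw_start * std::exp(kw_log_ratio * frac));
        const double step_cur = step_size * std::exp(step_log_ratio * frac);

        // propose: move mass dp from a bump at cell a to a bump at cell b
        int a = (int)(unif_rand() * M); if (a >= M) a = M - 1;
        int b = (int)(unif_rand() * M); if (b >= M) b = M - 1;
        double dp = unif_rand() * step_cur;    // change in density units
        bool proposed = build_move(p, M, R, kern, a, b, dp, chg_idx, chg_dp);

        if (proposed) {
        for (size_t k = 0; k < chg_idx.size(); ++k) acc_dp[chg_idx[k]] += chg_dp[k];

        // affected index set: changed cells and their mirrors
        D.clear();
        for (size_t k = 0; k < chg_idx.size(); ++k) {
            const int i = chg_idx[k], mi = M - 1 - chg_idx[k];
            if (!inD[i])  { inD[i] = 1;  D.push_back(i); }
            if (!inD[mi]) { inD[mi] = 1; D.push_back(mi); }
        }

        const double S_aff_old = het_sum_affected(p, D, inD);
        double H_old = 0.0, m1_old = 0.0, m2_old = 0.0;
        for (size_t k = 0; k < D.size(); ++k) {
            const int i = D[k];
            if (acc_dp[i] == 0.0) continue;
            const double x = (i + 0.5) * dx;
            H_old  -= xlogx(p[i]) * dx;
            m1_old += x * p[i] * dx;
            m2_old += x * x * p[i] * dx;
        }

        p_save.assign(D.size(), 0.0);
        for (size_t k = 0; k < D.size(); ++k) {
            const int i = D[k];
            p_save[k] = p[i];
            if (acc_dp[i] != 0.0) p[i] += acc_dp[i];
        }

        double H_new2 = 0.0, m1_new2 = 0.0, m2_new2 = 0.0;
        for (size_t k = 0; k < D.size(); ++k) {
            const int i = D[k];
            if (acc_dp[i] == 0.0) continue;
            const double x = (i + 0.5) * dx;
            H_new2  -= xlogx(p[i]) * dx;
            m1_new2 += x * p[i] * dx;
            m2_new2 += x * x * p[i] * dx;
        }

        const double S_new  = S + het_sum_affected(p, D, inD) - S_aff_old;
        const double H_new  = H  + H_new2  - H_old;
        const double m1_new = m1 + m1_new2 - m1_old;
        const double m2_new = m2 + m2_new2 - m2_old;
        const double f_new = fitness_of(S_new, H_new, m1_new, m2_new);

        const double df = f_new - f;
        bool accept = (df >= 0.0) || (unif_rand() < std::exp(beta * df));
        if (accept) {
            S = S_new; H = H_new; m1 = m1_new; m2 = m2_new; f = f_new;
            ++accepted;
            if (f > best_f) { best_f = f; best_p = p; }
        } else {
            for (size_t k = 0; k < D.size(); ++k) p[D[k]] = p_save[k];
        }
        for (size_t k = 0; k < D.size(); ++k) inD[D[k]] = 0;
        for (size_t k = 0; k < chg_idx.size(); ++k) acc_dp[chg_idx[k]] = 0.0;
        } // proposed

        // periodic full recompute to cancel accumulated round-off
        if ((it + 1) % 50000 == 0) {
            S = het_sum(p);
            H = 0.0; m1 = 0.0; m2 = 0.0;
            for (int i = 0; i < M; ++i) {
                const double x = (i + 0.5) * dx;
                H  -= xlogx(p[i]) * dx;
                m1 += x * p[i] * dx;
                m2 += x * x * p[i] * dx;
            }
            f = fitness_of(S, H, m1, m2);
        }

        if (avg_from >= 0 && it >= avg_from) {
            for (int i = 0; i < M; ++i) p_acc[i] += p[i];
            ++n_acc;
        }
        if (trace_every > 0 && (it + 1) % trace_every == 0) {
            trace_it.push_back(it + 1);
            trace_f.push_back(best_f);
        }
        if (window > 0 && (it + 1) % window == 0) {
            const double rel = std::fabs(best_f - window_ref) /
                std::max(1e-12, std::fabs(best_f));
            converged = (rel < tol);
            window_ref = best_f;
        }
    }

    if (n_acc > 0)
        for (int i = 0; i < M; ++i) p_acc[i] /= (double)n_acc;

    return List::create(
        _["p"] = NumericVector(best_p.begin(), best_p.end()),
        _["p_last"] = NumericVector(p.begin(), p.end()),
        _["p_avg"] = NumericVector(p_acc.begin(), p_acc.end()),
        _["f"] = best_f,
        _["accepted_fraction"] = (double)accepted / (double)n_iter,
        _["trace_iter"] = IntegerVector(trace_it.begin(), trace_it.end()),
        _["trace_f"] = NumericVector(trace_f.begin(), trace_f.end()),
        _["converged"] = converged);
}

// Deterministic zero-temperature quench over the same smoothed
// mass-exchange move set: cyclic sweeps over cell pairs, with a
// golden-section line search on the exchanged mass, applying a move only
// when it strictly increases the fitness. Terminates when a full sweep
// gains less than tol. The returned profile is a local maximum of the
// fitness with respect to every single smoothed exchange.
// [[Rcpp::export]]
List cpp_quench(NumericVector p0, double dx, double t, int measure,
                double kernel_width, double step_max, int max_sweeps,
                double tol) {
    const int M = p0.size();
    std::vector<double> p(p0.begin(), p0.end());

    const double KW_MIN = 0.05;
    const int R = (kernel_width > KW_MIN) ? (int)std::ceil(3.0 * kernel_width) : 0;
    std::vector<double> kern(2 * R + 1, 1.0);
    if (R > 0)
        for (int k = -R; k <= R; ++k)
            kern[k + R] = std::exp(-0.5 * (k * k) / (kernel_width * kernel_width));

    double S = het_sum(p), H = 0.0, m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < M; ++i) {
        const double x = (i + 0.5) * dx;
        H  -= xlogx(p[i]) * dx;
        m1 += x * p[i] * dx;
        m2 += x * x * p[i] * dx;
    }
    auto fitness_of = [&](double Sv, double Hv, double m1v, double m2v) {
        double n = 0.5 * Sv * dx * dx;
        if (n < 0.0) n = 0.0;
        if (n > 1.0) n = 1.0;
        double div = (measure == 0) ? Hv : (m2v - m1v * m1v);
        return n * (1.0 + t * div);
    };
    double f = fitness_of(S, H, m1, m2);

    std::vector<int> chg_idx, D;
    std::vector<double> chg_dp, p_save;
    std::vector<char> inD(M, 0);
    std::vector<double> acc_dp(M, 0.0);
    double S_try = 0, H_try = 0, m1_try = 0, m2_try = 0;

    // evaluate f after a signed exchange between (a, b); does not mutate state
    auto eval_move = [&](int a, int b, double dps) -> double {
        const int from = (dps >= 0.0) ? a : b, to = (dps >= 0.0) ? b : a;
        if (!build_move(p, M, R, kern, from, to, std::fabs(dps), chg_idx, chg_dp))
            return -HUGE_VAL;
        for (size_t k = 0; k < chg_idx.size(); ++k) acc_dp[chg_idx[k]] += chg_dp[k];
        D.clear();
        for (size_t k = 0; k < chg_idx.size(); ++k) {
            const int i = chg_idx[k], mi = M - 1 - chg_idx[k];
            if (!inD[i])  { inD[i] = 1;  D.push_back(i); }
            if (!inD[mi]) { inD[mi] = 1; D.push_back(mi); }
        }
        const double S_aff_old = het_sum_affected(p, D, inD);
        double dH = 0, dm1 = 0, dm2 = 0;
        p_save.assign(D.size(), 0.0);
        for (size_t k = 0; k < D.size(); ++k) {
            const int i = D[k];
            p_save[k] = p[i];
            if (acc_dp[i] == 0.0) continue;
            const double x = (i + 0.5) * dx;
            dH  += xlogx(p[i]) * dx;
            dm1 -= x * p[i] * dx;
            dm2 -= x * x * p[i] * dx;
        }
        for (size_t k = 0; k < D.size(); ++k)
            if (acc_dp[D[k]] != 0.0) p[D[k]] += acc_dp[D[k]];
        for (size_t k = 0; k < D.size(); ++k) {
            const int i = D[k];
            if (acc_dp[i] == 0.0) continue;
            const double x = (i + 0.5) * dx;
            dH  -= xlogx(p[i]) * dx;
            dm1 += x * p[i] * dx;
            dm2 += x * x * p[i] * dx;
        }
        S_try  = S + het_sum_affected(p, D, inD) - S_aff_old;
        H_try  = H + dH; m1_try = m1 + dm1; m2_try = m2 + dm2;
        // revert
        for (size_t k = 0; k < D.size(); ++k) p[D[k]] = p_save[k];
        for (size_t k = 0; k < D.size(); ++k) inD[D[k]] = 0;
        for (size_t k = 0; k < chg_idx.size(); ++k) acc_dp[chg_idx[k]] = 0.0;
        return fitness_of(S_try, H_try, m1_try, m2_try);
    };

    auto apply_move = [&](int a, int b, double dps) {
        const int from = (dps >= 0.0) ? a : b, to = (dps >= 0.0) ? b : a;
        build_move(p, M, R, kern, from, to, std::fabs(dps), chg_idx, chg_dp);
        for (size_t k = 0; k < chg_idx.size(); ++k) p[chg_idx[k]] += chg_dp[k];
        S = het_sum(p);  // exact refresh keeps the quench drift-free
        H = 0.0; m1 = 0.0; m2 = 0.0;
        for (int i = 0; i < M; ++i) {
            const double x = (i + 0.5) * dx;
            H  -= xlogx(p[i]) * dx;
            m1 += x * p[i] * dx;
            m2 += x * x * p[i] * dx;
        }
        f = fitness_of(S, H, m1, m2);
    };

    const double gold = 0.6180339887498949;
    const int offsets[] = {1, 2, 3, 5, 8, 13, 21, 34, 55, 89};
    int sweeps_done = 0;
    bool converged = false;
    for (int sw = 0; sw < max_sweeps; ++sw) {
        double f_before = f;
        for (int a = 0; a < M; ++a) {
            for (int o = 0; o < 11; ++o) {
                int b;
                if (o < 10) { b = a + offsets[o]; if (b >= M) continue; }
                else { b = M - 1 - a; if (b == a) continue; }
                // golden-section line search on signed exchanged mass
                double lo = -step_max, hi = step_max;
                double x1 = hi - gold * (hi - lo), x2 = lo + gold * (hi - lo);
                double f1 = eval_move(a, b, x1), f2 = eval_move(a, b, x2);
                for (int itls = 0; itls < 28; ++itls) {
                    if (f1 < f2) {
                        lo = x1; x1 = x2; f1 = f2;
                        x2 = lo + gold * (hi - lo); f2 = eval_move(a, b, x2);
                    } else {
                        hi = x2; x2 = x1; f2 = f1;
                        x1 = hi - gold * (hi - lo); f1 = eval_move(a, b, x1);
                    }
                }
                const double xb = (f1 > f2) ? x1 : x2;
                const double fb = (f1 > f2) ? f1 : f2;
                if (fb > f && std::fabs(xb) > 0.0) apply_move(a, b, xb);
            }
        }
        ++sweeps_done;
        if (f - f_before < tol) { converged = true; break; }
    }

    return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                        _["f"] = f, _["sweeps"] = sweeps_done,
                        _["converged"] = converged);
}
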