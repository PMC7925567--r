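#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pair index for 0-based i < j over L sites.
static inline int pair_index(int i, int j, int L) {
    return i * L - i * (i + 1) / 2 + (j - i - 1);
}

// Sequence weights: w_s = 1 / #{t : identity(s,t) >= theta}, self included.
// Identity = matches / (columns where both rows are non-gap). States are
// 1-based; gap_state <= 0 means no gap state. Columns where either row is
// the gap state are excluded from the denominator; identity is 0 when no
// column qualifies.
// [[Rcpp::export]]
NumericVector cpp_seq_weights(const IntegerMatrix& X, double theta,
                              int gap_state) {
    const int n = X.nrow(), L = X.ncol();
    IntegerVector neigh(n, 1); // self
    for (int s = 0; s < n; ++s) {
        for (int t = s + 1; t < n; ++t) {
            int match = 0, denom = 0;
            for (int c = 0; c < L; ++c) {
                const int a = X(s, c), b = X(t, c);
                if (gap_state > 0 && (a == gap_state || b == gap_state))
                    continue;
                ++denom;
                if (a == b) ++match;
            }
            const double id = denom > 0 ? (double)match / denom : 0.0;
            if (id >= theta) { ++neigh[s]; ++neigh[t]; }
        }
    }
    NumericVector w(n);
    for (int s = 0; s < n; ++s) w[s] = 1.0 / neigh[s];
    return w;
}

// Negative log pseudo-likelihood of a symmetric Potts model plus L2
// penalties, with its exact gradient.
//
// Parameter vector: h (L*q entries, h_i(a) at i*q + a), then the upper
// triangle of J ((L choose 2) blocks of q*q entries, element (a,b) of pair
// (i,j) at offset Lq + pair_index(i,j)*q*q + a*q + b, a = state at i).
// X0 holds 0-based states, w per-row weights. Penalty:
// lambda_h * sum h^2 + lambda_J * sum_{i<j} J_ij^2 (each pair counted once).
// [[Rcpp::export]]
List cpp_plm_obj_grad(const NumericVector& par, const IntegerMatrix& X0,
                      const NumericVector& w, int q, double lambda_h,
                      double lambda_J) {
    const int n = X0.nrow(), L = X0.ncol();
    const int hlen = L * q;
    const int npair = L * (L - 1) / 2;
    if (par.size() != hlen + (R_xlen_t)npair * q * q)
        stop("parameter vector has wrong length");

    const double* h = &par[0];
    const double* J = &par[hlen];
    NumericVector grad(par.size());
    double* gh = &grad[0];
    double* gJ = &grad[hlen];
    double obj = 0.0;

    std::vector<double> E(L * q);     // E[i*q + a]
    std::vector<double> P(L * q);     // softmax probabilities
    std::vector<int> x(L);

    for (int s = 0; s < n; ++s) {
        const double ws = w[s];
        for (int i = 0; i < L; ++i) {
            x[i] = X0(s, i);
            for (int a = 0; a < q; ++a) E[i * q + a] = h[i * q + a];
        }
        // couplings: E_i(a) += J_ij(a, x_j); E_j(b) += J_ij(x_i, b)
        for (int i = 0; i < L; ++i) {
            for (int j = i + 1; j < L; ++j) {
                const double* Jij = J + (R_xlen_t)pair_index(i, j, L) * q * q;
                const int xi = x[i], xj = x[j];
                double* Ei = &E[i * q];
                double* Ej = &E[j * q];
                for (int a = 0; a < q; ++a) Ei[a] += Jij[a * q + xj];
                const double* Jrow = Jij + xi * q;
                for (int b = 0; b < q; ++b) Ej[b] += Jrow[b];
            }
        }
        // per-site log-softmax and probabilities
        for (int i = 0; i < L; ++i) {
            double* Ei = &E[i * q];
            double m = Ei[0];
            for (int a = 1; a < q; ++a) if (Ei[a] > m) m = Ei[a];
            double Z = 0.0;
            for (int a = 0; a < q; ++a) Z += std::exp(Ei[a] - m);
            const double logZ = m + std::log(Z);
            obj += ws * (logZ - Ei[x[i]]);
            double* Pi = &P[i * q];
            for (int a = 0; a < q; ++a)
                Pi[a] = std::exp(Ei[a] - logZ);
        }
        // gradient: dh_i(a) += w (P_i(a) - delta(a, x_i))
        for (int i = 0; i < L; ++i) {
            double* Pi = &P[i * q];
            double* ghi = gh + i * q;
            for (int a = 0; a < q; ++a) ghi[a] += ws * Pi[a];
            ghi[x[i]] -= ws;
        }
        // dJ_ij(a, x_j) += w (P_i(a) - delta); dJ_ij(x_i, b) += w (P_j(b) - delta)
        for (int i = 0; i < L; ++i) {
            for (int j = i + 1; j < L; ++j) {
                double* gJij = gJ + (R_xlen_t)pair_index(i, j, L) * q * q;
                const int xi = x[i], xj = x[j];
                const double* Pi = &P[i * q];
                const double* Pj = &P[j * q];
                for (int a = 0; a < q; ++a) gJij[a * q + xj] += ws * Pi[a];
                gJij[xi * q + xj] -= ws;
                double* gJrow = gJij + xi * q;
                for (int b = 0; b < q; ++b) gJrow[b] += ws * Pj[b];
                gJrow[xj] -= ws;
            }
        }
    }

    // L2 penalties
    double pen = 0.0;
    for (int k = 0; k < hlen; ++k) {
        pen += lambda_h * par[k] * par[k];
        gh[k] += 2.0 * lambda_h * par[k];
    }
    const R_xlen_t jlen = (R_xlen_t)npair * q * q;
    for (R_xlen_t k = 0; k < jlen; ++k) {
        pen += lambda_J * J[k] * J[k];
        gJ[k] += 2.0 * lambda_J * J[k];
    }
    obj += pen;

    return List::create(_["value"] = obj, _["gradient"] = grad);
}

// Single-chain Gibbs sampler for a Potts model. h is q x L; Jvec uses the
// same upper-triangle block layout as cpp_plm_obj_grad. Returns an
// n_seq x L matrix of 1-based states. Uses R's RNG (set.seed reproducible).
// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_sample(const NumericMatrix& h, const NumericVector& Jvec,
                               int n_seq, int burnin, int thin) {
    const int q = h.nrow(), L = h.ncol();
    IntegerMatrix out(n_seq, L);
    std::vector<int> x(L);
    std::vector<double> e(q), p(q);

    RNGScope scope;
    // random initial state
    for (int i = 0; i < L; ++i)
        x[i] = (int)std::floor(unif_rand() * q) % q;

    const int total_sweeps = burnin + n_seq * thin;
    int recorded = 0, since = 0;
    for (int sweep = 0; sweep < total_sweeps; ++sweep) {
        for (int i = 0; i < L; ++i) {
            for (int a = 0; a < q; ++a) e[a] = h(a, i);
            for (int j = 0; j < L; ++j) {
                if (j == i) continue;
                if (i < j) {
                    const double* Jij =
                        &Jvec[(R_xlen_t)pair_index(i, j, L) * q * q];
                    const int xj = x[j];
                    for (int a = 0; a < q; ++a) e[a] += Jij[a * q + xj];
                } else {
                    const double* Jji =
                        &Jvec[(R_xlen_t)pair_index(j, i, L) * q * q];
                    const double* row = Jji + x[j] * q;
                    for (int a = 0; a < q; ++a) e[a] += row[a];
                }
            }
            double m = e[0];
            for (int a = 1; a < q; ++a) if (e[a] > m) m = e[a];
            double Z = 0.0;
            for (int a = 0; a < q; ++a) { p[a] = std::exp(e[a] - m); Z += p[a]; }
            double u = unif_rand() * Z, acc = 0.0;
            int pick = q - 1;
            for (int a = 0; a < q; ++a) {
                acc += p[a];
                if (u <= acc) { pick = a; break; }
            }
            x[i] = pick;
        }
        if (sweep >= burnin) {
            if (++since == thin) {
                for (int i = 0; i < L; ++i) out(recorded, i) = x[i] + 1;
                ++recorded;
                since = 0;
                if (recorded == n_seq) break;
            }
        }
    }
    return out;
}
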