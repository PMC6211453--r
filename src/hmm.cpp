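#include <Rcpp.h>
using namespace Rcpp;

// Non-homogeneous HMM with 4 states and transition matrix between
// positions i and i+1 given by T = f[i] * I + (1 - f[i]) / 3 * (J - I).
// Emissions are supplied as log-probabilities (n x 4).

// [[Rcpp::export(name = ".fb_nhmm")]]
List fb_nhmm(NumericMatrix log_emissions, NumericVector f) {
    const int n = log_emissions.nrow();
    const int S = log_emissions.ncol();
    NumericMatrix gamma(n, S);
    NumericVector stay(std::max(n - 1, 0));
    double logZ = 0.0;

    NumericMatrix E(n, S);     // scaled emissions
    NumericVector mrow(n);
    for (int i = 0; i < n; ++i) {
        double m = R_NegInf;
        for (int s = 0; s < S; ++s) m = std::max(m, log_emissions(i, s));
        mrow[i] = m;
        for (int s = 0; s < S; ++s)
            E(i, s) = std::exp(log_emissions(i, s) - m);
    }

    NumericMatrix alpha(n, S), beta(n, S);
    NumericVector cnorm(n);
    // forward
    double c0 = 0.0;
    for (int s = 0; s < S; ++s) { alpha(0, s) = E(0, s) / S; c0 += alpha(0, s); }
    for (int s = 0; s < S; ++s) alpha(0, s) /= c0;
    cnorm[0] = c0;
    logZ += std::log(c0) + mrow[0];
    for (int i = 1; i < n; ++i) {
        const double fi = f[i - 1];
        const double off = (1.0 - fi) / 3.0;
        const double diag = fi - off;
        double ci = 0.0;
        for (int s = 0; s < S; ++s) {
            double v = E(i, s) * (off + diag * alpha(i - 1, s));
            alpha(i, s) = v;
            ci += v;
        }
        for (int s = 0; s < S; ++s) alpha(i, s) /= ci;
        cnorm[i] = ci;
        logZ += std::log(ci) + mrow[i];
    }
    // backward
    for (int s = 0; s < S; ++s) beta(n - 1, s) = 1.0;
    for (int i = n - 2; i >= 0; --i) {
        const double fi = f[i];
        const double off = (1.0 - fi) / 3.0;
        const double diag = fi - off;
        double tot = 0.0;
        for (int t = 0; t < S; ++t)
            tot += E(i + 1, t) * beta(i + 1, t);
        for (int s = 0; s < S; ++s)
            beta(i, s) = (off * tot +
                diag * E(i + 1, s) * beta(i + 1, s)) / cnorm[i + 1];
    }
    // posteriors
    for (int i = 0; i < n; ++i) {
        double tot = 0.0;
        for (int s = 0; s < S; ++s) {
            gamma(i, s) = alpha(i, s) * beta(i, s);
            tot += gamma(i, s);
        }
        for (int s = 0; s < S; ++s) gamma(i, s) /= tot;
    }
    // diagonal pair-marginal mass (probability of staying)
    for (int i = 0; i + 1 < n; ++i) {
        const double fi = f[i];
        const double off = (1.0 - fi) / 3.0;
        const double diag = fi - off;
        double tot = 0.0, stot = 0.0;
        double cross = 0.0;
        for (int t = 0; t < S; ++t)
            cross += E(i + 1, t) * beta(i + 1, t);
        for (int s = 0; s < S; ++s) {
            double d = alpha(i, s) *
                (off * cross + diag * E(i + 1, s) * beta(i + 1, s));
            tot += d;
            stot += alpha(i, s) * fi * E(i + 1, s) * beta(i + 1, s);
        }
        stay[i] = stot / tot;
    }
    return List::create(_["gamma"] = gamma, _["stay"] = stay,
        _["logZ"] = logZ);
}

// [[Rcpp::export(name = ".viterbi_nhmm")]]
IntegerVector viterbi_nhmm(NumericMatrix log_emissions, NumericVector f,
                           double peak_penalty) {
    const int n = log_emissions.nrow();
    const int S = log_emissions.ncol();
    IntegerVector path(n);
    if (n == 0) return path;
    NumericMatrix delta(n, S);
    IntegerMatrix psi(n, S);
    for (int s = 0; s < S; ++s)
        delta(0, s) = log_emissions(0, s) - std::log((double)S) +
            (s == 0 ? peak_penalty : 0.0);
    for (int i = 1; i < n; ++i) {
        const double fi = f[i - 1];
        const double lstay = std::log(fi);
        const double lswitch = std::log((1.0 - fi) / 3.0);
        for (int t = 0; t < S; ++t) {
            double best = R_NegInf;
            int arg = 0;
            for (int s = 0; s < S; ++s) {
                double v = delta(i - 1, s) + (s == t ? lstay : lswitch);
                if (v > best) { best = v; arg = s; }
            }
            delta(i, t) = best + log_emissions(i, t) +
                (t == 0 ? peak_penalty : 0.0);
            psi(i, t) = arg;
        }
    }
    double best = R_NegInf;
    int arg = 0;
    for (int s = 0; s < S; ++s)
        if (delta(n - 1, s) > best) { best = delta(n - 1, s); arg = s; }
    path[n - 1] = arg + 1;
    for (int i = n - 1; i > 0; --i) {
        arg = psi(i, arg);
        path[i - 1] = arg + 1;
    }
    return path;
}
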