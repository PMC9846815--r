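#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fast path for MAS5-style probeset summarization and detection.
// The exported R functions tukeyBiweight(), probesetSignal() and
// detectionPvalue() are the reference implementations; the test suite
// asserts equivalence between the two routes.

static double median_of(std::vector<double> v) {
    const size_t n = v.size();
    if (n == 0) return NA_REAL;
    const size_t h = n / 2;
    std::nth_element(v.begin(), v.begin() + h, v.end());
    double m = v[h];
    if (n % 2 == 0) {
        double lo = *std::max_element(v.begin(), v.begin() + h);
        m = (m + lo) / 2.0;
    }
    return m;
}

static double tukey_biweight(const std::vector<double>& x, double c, double eps) {
    const size_t n = x.size();
    if (n == 1) return x[0];
    double m = median_of(x);
    std::vector<double> ad(n);
    for (size_t i = 0; i < n; ++i) ad[i] = std::fabs(x[i] - m);
    double s = median_of(ad);
    const double denom = c * s + eps;
    double sw = 0.0, swx = 0.0;
    for (size_t i = 0; i < n; ++i) {
        double u = (x[i] - m) / denom;
        if (std::fabs(u) < 1.0) {
            double w = (1.0 - u * u);
            w *= w;
            sw += w;
            swx += w * x[i];
        }
    }
    return swx / sw;
}

// Midranks of |d|; returns ranks doubled so ties give exact integers.
static void midranks2(const std::vector<double>& absd, std::vector<int>& r2) {
    const size_t n = absd.size();
    std::vector<size_t> idx(n);
    for (size_t i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](size_t a, size_t b) { return absd[a] < absd[b]; });
    r2.assign(n, 0);
    size_t i = 0;
    while (i < n) {
        size_t j = i;
        while (j + 1 < n && absd[idx[j + 1]] == absd[idx[i]]) ++j;
        // midrank of positions i..j (1-based ranks i+1..j+1), doubled
        int mr2 = (int)(i + 1 + j + 1); // 2 * average rank
        for (size_t k = i; k <= j; ++k) r2[idx[k]] = mr2;
        i = j + 1;
    }
}

// Exact one-sided upper tail of the signed-rank statistic by counting all
// 2^n sign assignments, computed as a subset-sum distribution over the
// doubled midranks (identical to literal enumeration).
static double signrank_tail_exact(const std::vector<int>& r2, double w2obs, size_t n) {
    int total = 0;
    for (size_t i = 0; i < n; ++i) total += r2[i];
    std::vector<double> f(total + 1, 0.0);
    f[0] = 1.0;
    for (size_t i = 0; i < n; ++i) {
        const int R = r2[i];
        for (int s = total - R; s >= 0; --s)
            if (f[s] > 0) f[s + R] += f[s];
    }
    int wlo = (int)std::ceil(w2obs - 1e-9);
    if (wlo < 0) wlo = 0;
    double count = 0.0;
    for (int s = wlo; s <= total; ++s) count += f[s];
    return count / std::pow(2.0, (double)n);
}

static double signrank_tail_normal(const std::vector<int>& r2, double w2obs, size_t n) {
    // W on the ordinary rank scale
    double W = w2obs / 2.0;
    double mu = n * (n + 1.0) / 4.0;
    double var = n * (n + 1.0) * (2.0 * n + 1.0) / 24.0;
    // tie correction: subtract sum(t^3 - t)/48 per tie group
    std::vector<int> sorted(r2);
    std::sort(sorted.begin(), sorted.end());
    size_t i = 0;
    while (i < n) {
        size_t j = i;
        while (j + 1 < n && sorted[j + 1] == sorted[i]) ++j;
        double t = (double)(j - i + 1);
        var -= (t * t * t - t) / 48.0;
        i = j + 1;
    }
    if (var <= 0) return 1.0;
    double z = (W - mu - 0.5) / std::sqrt(var);
    double p = R::pnorm(z, 0.0, 1.0, 0, 0);
    if (p > 1.0) p = 1.0;
    if (p <= 0.0) p = 1e-300;
    return p;
}

// One-sided Wilcoxon signed-rank p for H1: median(R) > tau, where
// R = (pm - mm)/(pm + mm). Zero differences are dropped (signed-rank
// convention); exact for n <= exact_limit pairs, normal approximation with
// continuity and tie correction above.
static double detection_p(const std::vector<double>& pm, const std::vector<double>& mm,
                          double tau, int exact_limit) {
    std::vector<double> d;
    d.reserve(pm.size());
    for (size_t i = 0; i < pm.size(); ++i) {
        double R = (pm[i] - mm[i]) / (pm[i] + mm[i]);
        double di = R - tau;
        if (di != 0.0) d.push_back(di);
    }
    const size_t n = d.size();
    if (n == 0) return 1.0;
    std::vector<double> absd(n);
    for (size_t i = 0; i < n; ++i) absd[i] = std::fabs(d[i]);
    std::vector<int> r2;
    midranks2(absd, r2);
    double w2 = 0.0;
    for (size_t i = 0; i < n; ++i)
        if (d[i] > 0) w2 += r2[i];
    if ((int)n <= exact_limit) return signrank_tail_exact(r2, w2, n);
    return signrank_tail_normal(r2, w2, n);
}

// [[Rcpp::export(name = ".mas5_core")]]
List mas5_core(NumericMatrix pm, NumericMatrix mm, IntegerVector group, int ngroups,
               double tau, double bw_c, double bw_eps, double contrast_tau,
               double scale_tau, double delta_floor, int exact_limit) {
    const int npairs = pm.nrow(), ns = pm.ncol();
    if (mm.nrow() != npairs || mm.ncol() != ns)
        stop("pm and mm dimensions differ");
    if (group.size() != npairs)
        stop("group index length must equal number of probe pairs");

    std::vector<std::vector<int>> members(ngroups);
    for (int i = 0; i < npairs; ++i) {
        int g = group[i];
        if (g < 0 || g >= ngroups) stop("group index out of range");
        members[g].push_back(i);
    }

    NumericMatrix signal(ngroups, ns), detp(ngroups, ns);
    const double log2e = std::log(2.0);

    for (int g = 0; g < ngroups; ++g) {
        const std::vector<int>& rows = members[g];
        const size_t k = rows.size();
        if (k == 0) stop("probeset with no probe pairs");
        std::vector<double> pmv(k), mmv(k), ratios, v(k);
        ratios.reserve(k);
        for (int j = 0; j < ns; ++j) {
            ratios.clear();
            for (size_t i = 0; i < k; ++i) {
                pmv[i] = pm(rows[i], j);
                mmv[i] = mm(rows[i], j);
                if (pmv[i] + mmv[i] <= 0)
                    stop("pm + mm must be positive for every probe pair");
                if (pmv[i] > 0 && mmv[i] > 0)
                    ratios.push_back(std::log(pmv[i] / mmv[i]) / log2e);
            }
            detp(g, j) = detection_p(pmv, mmv, tau, exact_limit);

            // specific background: biweight of log2(pm/mm), only needed for
            // pairs with mm >= pm, which always contribute a finite ratio
            double SB = ratios.empty() ? 0.0 : tukey_biweight(ratios, bw_c, bw_eps);
            for (size_t i = 0; i < k; ++i) {
                double im;
                if (mmv[i] < pmv[i]) {
                    im = mmv[i];
                } else if (SB > contrast_tau) {
                    im = pmv[i] / std::pow(2.0, SB);
                } else {
                    double ex = contrast_tau / (1.0 + (contrast_tau - SB) / scale_tau);
                    im = pmv[i] / std::pow(2.0, ex);
                }
                double adj = pmv[i] - im;
                if (adj < delta_floor) adj = delta_floor;
                v[i] = std::log(adj) / log2e;
            }
            signal(g, j) = std::pow(2.0, tukey_biweight(v, bw_c, bw_eps));
        }
    }
    return List::create(_["signal"] = signal, _["detp"] = detp);
}
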