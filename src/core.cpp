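#include <Rcpp.h>
using namespace Rcpp;

// Block-mosaic haplotype genotypes. Each individual carries two
// haplotype copies; within a block a copy starts from a pool haplotype
// drawn by the population weights and switches to a freshly drawn pool
// haplotype with probability switch_prob[j] at each variant step
// (recombination). switch_prob >= 1 forces a restart (block starts).
// pool is H x m binary; wcum is H x n_blocks cumulative population
// weights; block is the 1-based block index per variant. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix sim_mosaic_genotypes(int n, IntegerMatrix pool,
                                   NumericMatrix wcum,
                                   NumericVector switch_prob,
                                   IntegerVector block) {
  int H = pool.nrow(), m = pool.ncol();
  if (wcum.nrow() != H) stop("weight rows must match pool haplotypes");
  IntegerMatrix geno(n, m);
  std::vector<int> h1(n), h2(n);
  for (int j = 0; j < m; ++j) {
    int b = block[j] - 1;
    const double* w = &wcum(0, b);
    double sp = switch_prob[j];
    const int* pj = &pool(0, j);
    int* col = &geno(0, j);
    for (int i = 0; i < n; ++i) {
      if (sp >= 1.0 || unif_rand() < sp) {
        double u = unif_rand();
        int h = 0;
        while (h < H - 1 && u > w[h]) ++h;
        h1[i] = h;
      }
      if (sp >= 1.0 || unif_rand() < sp) {
        double u = unif_rand();
        int h = 0;
        while (h < H - 1 && u > w[h]) ++h;
        h2[i] = h;
      }
      col[i] = pj[h1[i]] + pj[h2[i]];
    }
  }
  return geno;
}

// Per-variant simple linear regression of y on dosage (with intercept).
// Missing dosages are dropped pairwise. Returns beta, se, t and the
// residual degrees of freedom; monomorphic variants get NA.
// [[Rcpp::export]]
List gwas_ols(IntegerMatrix x, NumericVector y) {
  int n = x.nrow(), m = x.ncol();
  if (y.size() != n) stop("phenotype length does not match panel samples");
  NumericVector beta(m), se(m), tstat(m);
  IntegerVector df(m);
  for (int j = 0; j < m; ++j) {
    double sx = 0, sxx = 0, sxy = 0, sy = 0, syy = 0;
    int nc = 0;
    const int* col = &x(0, j);
    for (int i = 0; i < n; ++i) {
      int xi = col[i];
      if (xi == NA_INTEGER) continue;
      double yi = y[i];
      sx += xi; sxx += (double)xi * xi;
      sy += yi; syy += yi * yi;
      sxy += xi * yi;
      ++nc;
    }
    double Sxx = sxx - sx * sx / nc;
    if (nc < 3 || Sxx <= 0) {
      beta[j] = NA_REAL; se[j] = NA_REAL; tstat[j] = NA_REAL; df[j] = nc - 2;
      continue;
    }
    double Sxy = sxy - sx * sy / nc;
    double Syy = syy - sy * sy / nc;
    double b = Sxy / Sxx;
    double rss = Syy - b * Sxy;
    if (rss < 0) rss = 0;
    double sigma2 = rss / (nc - 2);
    double s = std::sqrt(sigma2 / Sxx);
    beta[j] = b;
    se[j] = s;
    tstat[j] = (s > 0) ? b / s : R_PosInf;
    df[j] = nc - 2;
  }
  return List::create(_["beta"] = beta, _["se"] = se,
                      _["t"] = tstat, _["df"] = df);
}

// Column allele frequencies (counted-allele dosage mean / 2) and
// non-missing counts in one pass.
// [[Rcpp::export]]
List col_freqs(IntegerMatrix g) {
  int n = g.nrow(), m = g.ncol();
  NumericVector p(m);
  IntegerVector nobs(m);
  for (int j = 0; j < m; ++j) {
    const int* col = &g(0, j);
    long sum = 0;
    int nc = 0;
    for (int i = 0; i < n; ++i) {
      if (col[i] == NA_INTEGER) continue;
      sum += col[i];
      ++nc;
    }
    nobs[j] = nc;
    p[j] = nc > 0 ? (double)sum / (2.0 * nc) : NA_REAL;
  }
  return List::create(_["p"] = p, _["n_obs"] = nobs);
}

// Keep the 1-based columns in `cols`, flipping dosage to 2 - x where
// `flip` is true; single copy of the retained submatrix.
// [[Rcpp::export]]
IntegerMatrix subset_flip(IntegerMatrix g, IntegerVector cols, LogicalVector flip) {
  int n = g.nrow(), k = cols.size();
  if (flip.size() != k) stop("flip length must match cols");
  IntegerMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    const int* src = &g(0, cols[j] - 1);
    int* dst = &out(0, j);
    if (flip[j]) {
      for (int i = 0; i < n; ++i)
        dst[i] = (src[i] == NA_INTEGER) ? NA_INTEGER : 2 - src[i];
    } else {
      std::copy(src, src + n, dst);
    }
  }
  return out;
}
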