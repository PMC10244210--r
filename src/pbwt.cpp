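#include <Rcpp.h>
using namespace Rcpp;

// Positional Burrows-Wheeler transform (PBWT) core.
//
// Conventions (0-based throughout):
//   X        m x n allele matrix, entries in {0,1}; row = haplotype.
//   a        m x (n+1) prefix arrays; column k is the haplotype order at
//            site boundary k (sorted by reversed prefixes over sites [0,k)).
//   d        m x (n+1) divergence arrays; d(i,k) is the smallest j such that
//            haplotypes a(i,k) and a(i-1,k) agree on all sites [j,k);
//            sentinel d(0,k) = k.
//   u        (m+1) x n cumulative zero counts; u(i,k) = number of 0 alleles
//            at site k among the first i haplotypes in a(.,k) order.
//   c        length-n vector of total zero counts per site; c[k] = u(m,k).

// [[Rcpp::export]]
List cpp_pbwt_build(const IntegerMatrix& X) {
  const int m = X.nrow(), n = X.ncol();
  IntegerMatrix a(m, n + 1), d(m, n + 1);
  IntegerMatrix u(m + 1, n);
  IntegerVector cc(n);

  for (int i = 0; i < m; ++i) { a(i, 0) = i; d(i, 0) = 0; }
  d(0, 0) = 0; // boundary 0 sentinel: empty reversed prefixes all agree

  std::vector<int> b(m), e(m);
  for (int k = 0; k < n; ++k) {
    // cumulative zero counts for interval extension
    int cnt0 = 0;
    for (int i = 0; i < m; ++i) {
      u(i, k) = cnt0;
      if (X(a(i, k), k) == 0) ++cnt0;
    }
    u(m, k) = cnt0;
    cc[k] = cnt0;

    // stable counting sort on allele at site k, tracking divergences
    int p = k + 1, q = k + 1;
    int iu = 0, iv = 0;
    for (int i = 0; i < m; ++i) {
      const int div = d(i, k);
      if (div > p) p = div;
      if (div > q) q = div;
      const int id = a(i, k);
      if (X(id, k) == 0) {
        a(iu, k + 1) = id;
        d(iu, k + 1) = p;
        ++iu; p = 0;
      } else {
        b[iv] = id;
        e[iv] = q;
        ++iv; q = 0;
      }
    }
    for (int i = 0; i < iv; ++i) {
      a(iu + i, k + 1) = b[i];
      d(iu + i, k + 1) = e[i];
    }
    if (m > 0) d(0, k + 1) = k + 1; // sentinel (also set by p init when iu > 0)
  }

  return List::create(_["a"] = a, _["d"] = d, _["u"] = u, _["c"] = cc,
                      _["n_haps"] = m, _["n_sites"] = n);
}

static inline int ext_pos(const IntegerMatrix& u, const IntegerVector& cc,
                          int k, int i, int allele) {
  return allele == 0 ? u(i, k) : cc[k] + (i - u(i, k));
}

// [[Rcpp::export]]
IntegerVector cpp_extend_interval(const IntegerMatrix& u, const IntegerVector& cc,
                                  int k, int f, int g, int allele) {
  return IntegerVector::create(ext_pos(u, cc, k, f, allele),
                               ext_pos(u, cc, k, g, allele));
}

// All maximal exact matches between `q` and the panel whose length meets the
// cutoff: mode 0 = site count (L sites), mode 1 = genetic span (L cM over cm).
//
// Single left-to-right sweep. The state is
//   t        virtual insertion position of the query at the current boundary,
//   db, da   exact start of the maximal agreement run between the query and
//            its sorted neighbours below (position t-1) and above (position
//            t); sentinel value = boundary index when there is no agreement,
//   [fL,gL)  the long-match block: the sorted interval of haplotypes whose
//            agreement run with the query covers the moving window
//            [W(k), k], where W(k) = k+1-L (sites) or the tracked site
//            distance index max{ i <= k : cm[k]-cm[i] >= L } (cM).
// A haplotype leaving the block on an allele break is reported with end k-1;
// its maximal start is recovered by walking left from the window boundary,
// which is already known to be inside the agreement run.
// [[Rcpp::export]]
DataFrame cpp_long_match_query(const IntegerMatrix& X,
                               const IntegerMatrix& a,
                               const IntegerMatrix& d,
                               const IntegerMatrix& u,
                               const IntegerVector& cc,
                               const IntegerVector& q,
                               int mode, double L,
                               const NumericVector& cm) {
  const int m = X.nrow(), n = X.ncol();
  std::vector<int> out_hap, out_start, out_end;

  const int Ls = mode == 0 ? (int)L : 0;
  if (mode == 0 && Ls < 1) stop("site-count cutoff must be >= 1");
  if (mode == 1 && L < 0) stop("genetic cutoff must be >= 0");

  // report a match ending at `e` for haplotype `h`, with agreement known to
  // cover [wstart, e]; walk left for the maximal start
  auto report = [&](int h, int e, int wstart) {
    int s = wstart;
    while (s > 0 && X(h, s - 1) == q[s - 1]) --s;
    const bool ok = mode == 0 ? (e - s + 1 >= Ls) : (cm[e] - cm[s] >= L);
    if (ok) { out_hap.push_back(h); out_start.push_back(s); out_end.push_back(e); }
  };

  int t = 0, db = 0, da = 0;
  int fL = 0, gL = 0;
  bool active = false;
  int wp = -1;      // site distance track index (cM mode), monotone pointer
  int prevW = 0;    // W(k-1), valid only while active

  for (int k = 0; k < n; ++k) {
    const int qa = q[k];

    // window start W(k)
    int W;
    bool wvalid;
    if (mode == 0) {
      W = k + 1 - Ls;
      wvalid = W >= 0;
    } else {
      while (wp + 1 <= k && cm[k] - cm[wp + 1] >= L) ++wp;
      W = wp;
      wvalid = wp >= 0;
    }

    // 1. extend the block through site k; members with the opposite allele
    //    break here and are reported with end k-1
    if (active) {
      const int lo = ext_pos(u, cc, k, fL, 1 - qa);
      const int hi = ext_pos(u, cc, k, gL, 1 - qa);
      for (int pos = lo; pos < hi; ++pos) report(a(pos, k + 1), k - 1, prevW);
      fL = ext_pos(u, cc, k, fL, qa);
      gL = ext_pos(u, cc, k, gL, qa);
      active = fL < gL;
    }

    // 2. advance the virtual insertion position and the exact neighbour
    //    agreement starts to boundary k+1
    int dbn, dan;
    {
      int jb = t - 1, dd = db;
      while (jb >= 0 && X(a(jb, k), k) != qa) {
        dd = std::max(dd, d(jb, k));
        --jb;
      }
      if (jb < 0) dbn = k + 1;
      else {
        const int h = a(jb, k);
        while (dd > 0 && X(h, dd - 1) == q[dd - 1]) --dd;
        dbn = dd;
      }
      int ja = t, dd2 = da;
      while (ja < m && X(a(ja, k), k) != qa) {
        ++ja;
        if (ja < m) dd2 = std::max(dd2, d(ja, k));
      }
      if (ja >= m) dan = k + 1;
      else {
        const int h = a(ja, k);
        while (dd2 > 0 && X(h, dd2 - 1) == q[dd2 - 1]) --dd2;
        dan = dd2;
      }
      t = ext_pos(u, cc, k, t, qa);
    }
    db = dbn; da = dan;

    // 3. expand (or seed) the block at boundary k+1: neighbours whose
    //    divergence chain stays at or before W(k) also cover the window
    if (wvalid) {
      if (!active) {
        fL = t; gL = t;
        if (t > 0 && db <= W) fL = t - 1;
        if (t < m && da <= W) gL = t + 1;
        active = fL < gL;
      }
      if (active) {
        while (fL > 0 && d(fL, k + 1) <= W) --fL;
        while (gL < m && d(gL, k + 1) <= W) ++gL;
      }
      prevW = W;
    }
  }

  // flush: matches running through the last site
  if (active)
    for (int pos = fL; pos < gL; ++pos) report(a(pos, n), n - 1, prevW);

  return DataFrame::create(_["hap"] = wrap(out_hap),
                           _["start"] = wrap(out_start),
                           _["end"] = wrap(out_end));
}
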