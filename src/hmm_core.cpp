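// Core HMM machinery for grid-based geolocation.
//
// State = (cell, behaviour). One daily transition applies behaviour
// switching first, then spatial diffusion with the new behaviour's
// diffusivity. Diffusion is a truncated Gaussian kernel, separable per
// axis, with land cells excluded and columns renormalised so
// probability is conserved:
//   K_b(x'|x) = G_b(x'-x) * sea(x') / Z_b(x),  Z_b(x) = sum_x'' G_b * sea
// Applying K (or its transpose) reduces to two banded matrix products
// plus the Z correction, so filtering is a handful of small GEMMs/day.

#include <RcppArmadillo.h>
using namespace arma;

static mat conv2(const mat& M, const mat& Grow, const mat& Gcol) {
  return Grow * M * Gcol;
}

// K v: forward application of the transition kernel
static mat apply_K(const mat& v, const mat& Grow, const mat& Gcol,
                   const mat& Z, const mat& sea) {
  mat u = v / Z;                 // Z > 0 wherever v has support (sea)
  u.replace(datum::nan, 0.0);
  u.elem(find(sea == 0)).zeros();
  mat w = conv2(u, Grow, Gcol);
  w %= sea;
  return w;
}

// K^T w: transpose application (for the backward recursion)
static mat apply_Kt(const mat& w, const mat& Grow, const mat& Gcol,
                    const mat& Z, const mat& sea) {
  mat u = w % sea;
  mat v = conv2(u, Grow, Gcol) / Z;
  v.replace(datum::nan, 0.0);
  v.elem(find(sea == 0)).zeros();
  return v;
}

// [[Rcpp::export]]
Rcpp::List bg_forward(const arma::cube& lik, const arma::mat& init,
                      const arma::vec& binit, const arma::mat& sw,
                      const Rcpp::List& Grow, const Rcpp::List& Gcol,
                      const arma::mat& sea, bool smooth) {
  const uword nd = lik.n_slices, nb = sw.n_rows;
  std::vector<mat> GR(nb), GC(nb), Z(nb);
  for (uword b = 0; b < nb; ++b) {
    GR[b] = Rcpp::as<mat>(Grow[b]);
    GC[b] = Rcpp::as<mat>(Gcol[b]);
    Z[b] = conv2(sea, GR[b], GC[b]);
  }

  // filtered (scaled) alpha per behaviour, stored if smoothing
  std::vector<std::vector<mat>> alpha(nb);
  std::vector<mat> a(nb), pred(nb);
  vec logc(nd, fill::zeros);
  double c;

  // day 1: initial surface times likelihood
  c = 0.0;
  for (uword b = 0; b < nb; ++b) {
    a[b] = binit(b) * (init % lik.slice(0));
    c += accu(a[b]);
  }
  if (c <= 0) return Rcpp::List::create(Rcpp::Named("ok") = false,
                                        Rcpp::Named("bad_day") = 1);
  for (uword b = 0; b < nb; ++b) a[b] /= c;
  logc(0) = std::log(c);
  if (smooth) for (uword b = 0; b < nb; ++b) alpha[b].push_back(a[b]);

  for (uword t = 1; t < nd; ++t) {
    // behaviour switch, then diffusion with the target behaviour's kernel
    for (uword b2 = 0; b2 < nb; ++b2) {
      mat mix(size(a[0]), fill::zeros);
      for (uword b1 = 0; b1 < nb; ++b1) mix += sw(b1, b2) * a[b1];
      pred[b2] = apply_K(mix, GR[b2], GC[b2], Z[b2], sea);
    }
    c = 0.0;
    for (uword b = 0; b < nb; ++b) {
      pred[b] %= lik.slice(t);
      c += accu(pred[b]);
    }
    if (c <= 0) return Rcpp::List::create(Rcpp::Named("ok") = false,
                                          Rcpp::Named("bad_day") = (int)(t + 1));
    for (uword b = 0; b < nb; ++b) a[b] = pred[b] / c;
    logc(t) = std::log(c);
    if (smooth) for (uword b = 0; b < nb; ++b) alpha[b].push_back(a[b]);
  }
  double loglik = accu(logc);
  if (!smooth)
    return Rcpp::List::create(Rcpp::Named("ok") = true,
                              Rcpp::Named("loglik") = loglik,
                              Rcpp::Named("logc") = logc);

  // backward pass: beta_t(s) = (1/c_{t+1}) sum_s' P(s'|s) L_{t+1} beta_{t+1}
  cube smoothed(lik.n_rows, lik.n_cols, nd, fill::zeros);
  cube sm_res(lik.n_rows, lik.n_cols, nd, fill::zeros);
  mat beh(nd, nb, fill::zeros);
  std::vector<mat> beta(nb), nbeta(nb);
  for (uword b = 0; b < nb; ++b) beta[b] = mat(size(sea), fill::ones);

  for (uword tt = nd; tt-- > 0;) {
    std::vector<mat> post(nb);
    double tot = 0.0;
    for (uword b = 0; b < nb; ++b) {
      post[b] = alpha[b][tt] % beta[b];
      tot += accu(post[b]);
    }
    for (uword b = 0; b < nb; ++b) {
      post[b] /= tot;
      smoothed.slice(tt) += post[b];
      beh(tt, b) = accu(post[b]);
    }
    sm_res.slice(tt) = post[0];
    if (tt == 0) break;
    // recurse
    std::vector<mat> kt(nb);
    for (uword b2 = 0; b2 < nb; ++b2) {
      mat w = (lik.slice(tt) % beta[b2]) / std::exp(logc(tt));
      kt[b2] = apply_Kt(w, GR[b2], GC[b2], Z[b2], sea);
    }
    for (uword b1 = 0; b1 < nb; ++b1) {
      nbeta[b1] = mat(size(sea), fill::zeros);
      for (uword b2 = 0; b2 < nb; ++b2) nbeta[b1] += sw(b1, b2) * kt[b2];
    }
    for (uword b = 0; b < nb; ++b) beta[b] = nbeta[b];
  }

  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("logc") = logc,
                            Rcpp::Named("smoothed") = smoothed,
                            Rcpp::Named("smoothed_res") = sm_res,
                            Rcpp::Named("behaviour") = beh);
}

// separable max-plus filter: out(r,c) = max_{dr,dc} in(r+dr, c+dc) + f(dr)+f(dc)
// also returns the argmax source linear index (0-based, column-major)
static void maxfilt(const mat& in, double sig, int k,
                    mat& out, umat& argsrc) {
  const int nr = in.n_rows, nc = in.n_cols;
  mat tmp(nr, nc);
  imat argc(nr, nc);
  // pass 1: along columns (shift dc)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = -datum::inf; int barg = c;
      for (int dc = -k; dc <= k; ++dc) {
        int cs = c + dc;
        if (cs < 0 || cs >= nc) continue;
        double pen = (sig > 0) ? -(double)dc * dc / (2 * sig * sig)
                               : (dc == 0 ? 0 : -datum::inf);
        double v = in(r, cs) + pen;
        if (v > best) { best = v; barg = cs; }
      }
      tmp(r, c) = best; argc(r, c) = barg;
    }
  }
  // pass 2: along rows (shift dr)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = -datum::inf; int barg = r;
      for (int dr = -k; dr <= k; ++dr) {
        int rs = r + dr;
        if (rs < 0 || rs >= nr) continue;
        double pen = (sig > 0) ? -(double)dr * dr / (2 * sig * sig)
                               : (dr == 0 ? 0 : -datum::inf);
        double v = tmp(rs, c) + pen;
        if (v > best) { best = v; barg = rs; }
      }
      out(r, c) = best;
      argsrc(r, c) = (uword)(argc(barg, c) * nr + barg);
    }
  }
}

// [[Rcpp::export]]
Rcpp::List bg_viterbi(const arma::cube& lik, const arma::mat& init,
                      const arma::vec& binit, const arma::mat& sw,
                      const arma::vec& sig_cells, const arma::ivec& kvec,
                      const Rcpp::List& Grow, const Rcpp::List& Gcol,
                      const arma::mat& sea) {
  const uword nd = lik.n_slices, nb = sw.n_rows;
  const int nr = lik.n_rows, nc = lik.n_cols;
  std::vector<mat> logZ(nb);
  for (uword b = 0; b < nb; ++b) {
    mat Z = conv2(sea, Rcpp::as<mat>(Grow[b]), Rcpp::as<mat>(Gcol[b]));
    logZ[b] = log(Z);
  }
  mat logsea = log(sea);
  std::vector<mat> ldelta(nb), nldelta(nb);
  for (uword b = 0; b < nb; ++b)
    ldelta[b] = std::log(binit(b)) + log(init) + log(lik.slice(0)) + logsea;

  // backpointers: per day, per target behaviour, joint source index
  std::vector<std::vector<umat>> bp(nd);
  mat filt(nr, nc);
  umat argsrc(nr, nc);

  for (uword t = 1; t < nd; ++t) {
    bp[t].resize(nb);
    std::vector<mat> best(nb);
    for (uword b2 = 0; b2 < nb; ++b2) {
      bp[t][b2].set_size(nr, nc);
      best[b2].set_size(nr, nc);
      best[b2].fill(-datum::inf);
      for (uword b1 = 0; b1 < nb; ++b1) {
        if (sw(b1, b2) <= 0) continue;
        mat in = ldelta[b1] - logZ[b2] + std::log(sw(b1, b2));
        maxfilt(in, sig_cells(b2), kvec(b2), filt, argsrc);
        for (int c = 0; c < nc; ++c)
          for (int r = 0; r < nr; ++r)
            if (filt(r, c) > best[b2](r, c)) {
              best[b2](r, c) = filt(r, c);
              bp[t][b2](r, c) = argsrc(r, c) + (uword)(b1 * nr * nc);
            }
      }
      best[b2] += log(lik.slice(t)) + logsea;
    }
    for (uword b = 0; b < nb; ++b) nldelta[b] = best[b];
    std::swap(ldelta, nldelta);
  }

  // terminal argmax (ties toward the lower joint index)
  double bestv = -datum::inf; uword bcell = 0, bb = 0;
  for (uword b = 0; b < nb; ++b)
    for (uword i = 0; i < (uword)(nr * nc); ++i)
      if (ldelta[b](i) > bestv) { bestv = ldelta[b](i); bcell = i; bb = b; }

  ivec cells(nd), behs(nd);
  cells(nd - 1) = (int)bcell + 1;   // 1-based for R
  behs(nd - 1) = (int)bb + 1;
  for (uword t = nd - 1; t >= 1; --t) {
    uword joint = bp[t][behs(t) - 1]((uword)(cells(t) - 1));
    uword b1 = joint / (uword)(nr * nc);
    uword cell1 = joint % (uword)(nr * nc);
    cells(t - 1) = (int)cell1 + 1;
    behs(t - 1) = (int)b1 + 1;
  }

  return Rcpp::List::create(Rcpp::Named("cells") = cells,
                            Rcpp::Named("behaviours") = behs,
                            Rcpp::Named("logprob") = bestv);
}
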