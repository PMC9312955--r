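// Compiled training path for the multi-channel vision transformer: batched
// forward pass and exact backpropagation of the class-weighted cross-entropy
// loss. Mirrors the R reference implementation (R/backprop.R) operation for
// operation; the test suite asserts that both paths produce identical
// probabilities and gradients. Dropout masks are drawn from R's RNG so runs
// stay reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double INV_SQRT_2PI = 0.3989422804014327;

struct LNCache {
  mat xhat;
  vec invstd;
  mat y;
};

static LNCache lnForward(const mat& x, const rowvec& g, const rowvec& b) {
  LNCache c;
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  c.invstd = 1.0 / arma::sqrt(arma::mean(arma::square(xc), 1) + 1e-5);
  c.xhat = xc.each_col() % c.invstd;
  c.y = c.xhat.each_row() % g;
  c.y.each_row() += b;
  return c;
}

static mat lnBackward(const mat& dy, const LNCache& c, const rowvec& g,
                      rowvec& dg, rowvec& db) {
  mat dxhat = dy.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % c.xhat, 1);
  dg += arma::sum(dy % c.xhat, 0);
  db += arma::sum(dy, 0);
  mat dx = (dxhat.each_col() - m1) - (c.xhat.each_col() % m2);
  dx.each_col() %= c.invstd;
  return dx;
}

static mat softmaxRows(mat S) {
  S.each_col() -= arma::max(S, 1);
  S = arma::exp(S);
  S.each_col() /= arma::sum(S, 1);
  return S;
}

// mask with inverted-dropout scaling, or an empty matrix when p <= 0
static mat dropMask(arma::uword nr, arma::uword nc, double p) {
  if (p <= 0) return mat();
  NumericVector u = Rcpp::runif((int)(nr * nc));
  mat m(nr, nc);
  std::copy(u.begin(), u.end(), m.memptr());
  const double scale = 1.0 / (1.0 - p);
  m.transform([p, scale](double v) { return v >= p ? scale : 0.0; });
  return m;
}

static inline void applyMask(mat& x, const mat& mask) {
  if (!mask.is_empty()) x %= mask;
}

struct LayerParams {
  rowvec ln1g, ln1b, bq, bk, bv, bo, ln2g, ln2b, b1, b2;
  mat Wq, Wk, Wv, Wo, W1, W2;
};

struct LayerCache {
  LNCache c1, c2;
  mat Q, K, V, O, Z1, Pz1, Md, maskAttn, maskMlp;
  std::vector<mat> attn; // one L x L matrix per (sample, head)
};

static rowvec asRow(SEXP s) {
  NumericVector v(s);
  return rowvec(v.begin(), v.size());
}

static LayerParams readLayer(const List& lp) {
  LayerParams out;
  out.ln1g = asRow(lp["ln1g"]); out.ln1b = asRow(lp["ln1b"]);
  out.Wq = as<mat>(lp["Wq"]); out.bq = asRow(lp["bq"]);
  out.Wk = as<mat>(lp["Wk"]); out.bk = asRow(lp["bk"]);
  out.Wv = as<mat>(lp["Wv"]); out.bv = asRow(lp["bv"]);
  out.Wo = as<mat>(lp["Wo"]); out.bo = asRow(lp["bo"]);
  out.ln2g = asRow(lp["ln2g"]); out.ln2b = asRow(lp["ln2b"]);
  out.W1 = as<mat>(lp["W1"]); out.b1 = asRow(lp["b1"]);
  out.W2 = as<mat>(lp["W2"]); out.b2 = asRow(lp["b2"]);
  return out;
}

// [[Rcpp::export(name = ".mvitLossGradCpp")]]
List mvitLossGradCpp(List XpList, IntegerVector y, NumericVector w,
                     List params, int B, int L, int D, int nHeads, int depth,
                     int nBranches, bool share, double dropout, bool train,
                     bool wantGrad, double smooth) {
  const int dh = D / nHeads;
  const double scl = 1.0 / std::sqrt((double)dh);
  const double pdrop = train ? dropout : 0.0;
  List branchesPar = params["branches"];
  List headPar = params["head"];

  // ---- read parameters ----
  const int nb = share ? 1 : nBranches;
  std::vector<mat> Wp(nb), pos(nb);
  std::vector<rowvec> bp(nb);
  std::vector<std::vector<LayerParams> > lpar(nb);
  for (int bi = 0; bi < nb; bi++) {
    List br = branchesPar[bi];
    Wp[bi] = as<mat>(br["Wp"]);
    bp[bi] = asRow(br["bp"]);
    pos[bi] = as<mat>(br["pos"]);
    List layers = br["layers"];
    lpar[bi].resize(depth);
    for (int l = 0; l < depth; l++) lpar[bi][l] = readLayer(layers[l]);
  }
  mat Wh1 = as<mat>(headPar["Wh1"]);
  rowvec bh1 = asRow(headPar["bh1"]);
  mat Wh2 = as<mat>(headPar["Wh2"]);
  rowvec bh2 = asRow(headPar["bh2"]);

  // ---- forward ----
  mat Fcat(B, nBranches * D, arma::fill::zeros);
  std::vector<mat> XpStore(nBranches), maskEmb(nBranches);
  std::vector<std::vector<LayerCache> > caches(nBranches);
  for (int b = 0; b < nBranches; b++) {
    const int bi = share ? 0 : b;
    mat Xp = as<mat>(XpList[b]);
    mat Tok = Xp * Wp[bi];
    Tok.each_row() += bp[bi];
    for (int i = 0; i < B; i++) Tok.rows(i * L, i * L + L - 1) += pos[bi];
    maskEmb[b] = dropMask(Tok.n_rows, Tok.n_cols, pdrop);
    applyMask(Tok, maskEmb[b]);
    if (wantGrad) {
      XpStore[b] = Xp;
      caches[b].resize(depth);
    }
    for (int l = 0; l < depth; l++) {
      const LayerParams& lp = lpar[bi][l];
      LNCache c1 = lnForward(Tok, lp.ln1g, lp.ln1b);
      mat Q = c1.y * lp.Wq; Q.each_row() += lp.bq;
      mat K = c1.y * lp.Wk; K.each_row() += lp.bk;
      mat V = c1.y * lp.Wv; V.each_row() += lp.bv;
      mat O(B * L, D);
      std::vector<mat> attn;
      if (wantGrad) attn.resize((size_t)B * nHeads);
      for (int i = 0; i < B; i++) {
        const arma::uword r0 = i * L, r1 = i * L + L - 1;
        for (int h = 0; h < nHeads; h++) {
          const arma::uword ch0 = h * dh, ch1 = h * dh + dh - 1;
          mat A = softmaxRows(Q.submat(r0, ch0, r1, ch1) *
                              K.submat(r0, ch0, r1, ch1).t() * scl);
          O.submat(r0, ch0, r1, ch1) = A * V.submat(r0, ch0, r1, ch1);
          if (wantGrad) attn[(size_t)i * nHeads + h] = std::move(A);
        }
      }
      mat U = O * lp.Wo;
      U.each_row() += lp.bo;
      mat maskAttn = dropMask(U.n_rows, U.n_cols, pdrop);
      applyMask(U, maskAttn);
      mat Tmid = Tok + U;
      LNCache c2 = lnForward(Tmid, lp.ln2g, lp.ln2b);
      mat Z1 = c2.y * lp.W1;
      Z1.each_row() += lp.b1;
      mat Pz1 = arma::normcdf(Z1);
      mat Md = Z1 % Pz1;
      mat maskMlp = dropMask(Md.n_rows, Md.n_cols, pdrop);
      applyMask(Md, maskMlp);
      Tok = Tmid + Md * lp.W2;
      Tok.each_row() += lp.b2;
      if (wantGrad) {
        LayerCache& lc = caches[b][l];
        lc.c1 = std::move(c1); lc.c2 = std::move(c2);
        lc.Q = std::move(Q); lc.K = std::move(K); lc.V = std::move(V);
        lc.O = std::move(O); lc.Z1 = std::move(Z1); lc.Pz1 = std::move(Pz1);
        lc.Md = std::move(Md); lc.maskAttn = std::move(maskAttn);
        lc.maskMlp = std::move(maskMlp); lc.attn = std::move(attn);
      }
    }
    for (int i = 0; i < B; i++)
      Fcat.submat(i, b * D, i, b * D + D - 1) =
        arma::mean(Tok.rows(i * L, i * L + L - 1), 0);
  }
  mat Z = Fcat * Wh1;
  Z.each_row() += bh1;
  mat Pz = arma::normcdf(Z);
  mat Hd = Z % Pz;
  mat maskHead = dropMask(Hd.n_rows, Hd.n_cols, pdrop);
  applyMask(Hd, maskHead);
  mat logits = Hd * Wh2;
  logits.each_row() += bh2;
  mat probs = softmaxRows(logits);
  if (!probs.is_finite()) stop("non-finite network output");

  // label-smoothed targets: (1 - smooth) one-hot + smooth / 2
  mat Tq(B, 2);
  Tq.fill(smooth / 2.0);
  for (int i = 0; i < B; i++) Tq(i, y[i] - 1) = 1.0 - smooth / 2.0;
  double loss = 0.0;
  for (int i = 0; i < B; i++)
    for (int c = 0; c < 2; c++)
      loss -= w[i] * Tq(i, c) * std::log(std::max(probs(i, c), 1e-300));
  loss /= B;

  if (!wantGrad)
    return List::create(Named("loss") = loss, Named("probs") = probs);

  // ---- backward ----
  mat dlogits = probs - Tq;
  for (int i = 0; i < B; i++) dlogits.row(i) *= w[i] / B;
  mat gWh2 = Hd.t() * dlogits;
  rowvec gbh2 = arma::sum(dlogits, 0);
  mat dHd = dlogits * Wh2.t();
  applyMask(dHd, maskHead);
  mat dZ = dHd % (Pz + Z % (arma::exp(-0.5 * arma::square(Z)) * INV_SQRT_2PI));
  mat gWh1 = Fcat.t() * dZ;
  rowvec gbh1 = arma::sum(dZ, 0);
  mat dF = dZ * Wh1.t();

  std::vector<mat> gWp(nb), gpos(nb);
  std::vector<rowvec> gbp(nb);
  std::vector<std::vector<LayerParams> > glay(nb); // grads, same shapes
  for (int bi = 0; bi < nb; bi++) {
    gWp[bi].zeros(Wp[bi].n_rows, Wp[bi].n_cols);
    gbp[bi].zeros(bp[bi].n_elem);
    gpos[bi].zeros(pos[bi].n_rows, pos[bi].n_cols);
    glay[bi].resize(depth);
    for (int l = 0; l < depth; l++) {
      const LayerParams& lp = lpar[bi][l];
      LayerParams& g = glay[bi][l];
      g.ln1g.zeros(D); g.ln1b.zeros(D);
      g.Wq.zeros(D, D); g.bq.zeros(D);
      g.Wk.zeros(D, D); g.bk.zeros(D);
      g.Wv.zeros(D, D); g.bv.zeros(D);
      g.Wo.zeros(D, D); g.bo.zeros(D);
      g.ln2g.zeros(D); g.ln2b.zeros(D);
      g.W1.zeros(lp.W1.n_rows, lp.W1.n_cols); g.b1.zeros(lp.W1.n_cols);
      g.W2.zeros(lp.W2.n_rows, lp.W2.n_cols); g.b2.zeros(D);
    }
  }

  for (int b = 0; b < nBranches; b++) {
    const int bi = share ? 0 : b;
    mat dT(B * L, D);
    for (int i = 0; i < B; i++) {
      rowvec df = dF.submat(i, b * D, i, b * D + D - 1) / L;
      dT.rows(i * L, i * L + L - 1) = arma::repmat(df, L, 1);
    }
    for (int l = depth - 1; l >= 0; l--) {
      const LayerParams& lp = lpar[bi][l];
      LayerCache& lc = caches[b][l];
      LayerParams& g = glay[bi][l];
      // MLP sub-block
      g.W2 += lc.Md.t() * dT;
      g.b2 += arma::sum(dT, 0);
      mat dMd = dT * lp.W2.t();
      applyMask(dMd, lc.maskMlp);
      mat dZ1 = dMd % (lc.Pz1 + lc.Z1 %
                       (arma::exp(-0.5 * arma::square(lc.Z1)) * INV_SQRT_2PI));
      g.W1 += lc.c2.y.t() * dZ1;
      g.b1 += arma::sum(dZ1, 0);
      mat dTmid = dT + lnBackward(dZ1 * lp.W1.t(), lc.c2, lp.ln2g,
                                  g.ln2g, g.ln2b);
      // attention sub-block
      mat dU = dTmid;
      applyMask(dU, lc.maskAttn);
      g.Wo += lc.O.t() * dU;
      g.bo += arma::sum(dU, 0);
      mat dO = dU * lp.Wo.t();
      mat dQ(B * L, D, arma::fill::zeros);
      mat dK(B * L, D, arma::fill::zeros);
      mat dV(B * L, D, arma::fill::zeros);
      for (int i = 0; i < B; i++) {
        const arma::uword r0 = i * L, r1 = i * L + L - 1;
        for (int h = 0; h < nHeads; h++) {
          const arma::uword ch0 = h * dh, ch1 = h * dh + dh - 1;
          const mat& A = lc.attn[(size_t)i * nHeads + h];
          mat dOi = dO.submat(r0, ch0, r1, ch1);
          mat dA = dOi * lc.V.submat(r0, ch0, r1, ch1).t();
          dV.submat(r0, ch0, r1, ch1) = A.t() * dOi;
          mat dS = A % (dA.each_col() - arma::sum(dA % A, 1));
          dQ.submat(r0, ch0, r1, ch1) = dS * lc.K.submat(r0, ch0, r1, ch1) * scl;
          dK.submat(r0, ch0, r1, ch1) = dS.t() * lc.Q.submat(r0, ch0, r1, ch1) * scl;
        }
      }
      g.Wq += lc.c1.y.t() * dQ; g.bq += arma::sum(dQ, 0);
      g.Wk += lc.c1.y.t() * dK; g.bk += arma::sum(dK, 0);
      g.Wv += lc.c1.y.t() * dV; g.bv += arma::sum(dV, 0);
      mat dA1 = dQ * lp.Wq.t() + dK * lp.Wk.t() + dV * lp.Wv.t();
      dT = dTmid + lnBackward(dA1, lc.c1, lp.ln1g, g.ln1g, g.ln1b);
    }
    applyMask(dT, maskEmb[b]);
    for (int i = 0; i < B; i++) gpos[bi] += dT.rows(i * L, i * L + L - 1);
    gWp[bi] += XpStore[b].t() * dT;
    gbp[bi] += arma::sum(dT, 0);
  }

  // ---- assemble gradient list (same nesting/order as the parameter list,
  // so flattenParams() on R side aligns element-for-element) ----
  List gBranches(nb);
  for (int bi = 0; bi < nb; bi++) {
    List layers(depth);
    for (int l = 0; l < depth; l++) {
      const LayerParams& g = glay[bi][l];
      layers[l] = List::create(
        Named("ln1g") = NumericVector(g.ln1g.begin(), g.ln1g.end()),
        Named("ln1b") = NumericVector(g.ln1b.begin(), g.ln1b.end()),
        Named("Wq") = g.Wq, Named("bq") = NumericVector(g.bq.begin(), g.bq.end()),
        Named("Wk") = g.Wk, Named("bk") = NumericVector(g.bk.begin(), g.bk.end()),
        Named("Wv") = g.Wv, Named("bv") = NumericVector(g.bv.begin(), g.bv.end()),
        Named("Wo") = g.Wo, Named("bo") = NumericVector(g.bo.begin(), g.bo.end()),
        Named("ln2g") = NumericVector(g.ln2g.begin(), g.ln2g.end()),
        Named("ln2b") = NumericVector(g.ln2b.begin(), g.ln2b.end()),
        Named("W1") = g.W1, Named("b1") = NumericVector(g.b1.begin(), g.b1.end()),
        Named("W2") = g.W2, Named("b2") = NumericVector(g.b2.begin(), g.b2.end()));
    }
    gBranches[bi] = List::create(
      Named("Wp") = gWp[bi],
      Named("bp") = NumericVector(gbp[bi].begin(), gbp[bi].end()),
      Named("pos") = gpos[bi],
      Named("layers") = layers);
  }
  List gHead = List::create(
    Named("Wh1") = gWh1, Named("bh1") = NumericVector(gbh1.begin(), gbh1.end()),
    Named("Wh2") = gWh2, Named("bh2") = NumericVector(gbh2.begin(), gbh2.end()));
  return List::create(Named("loss") = loss, Named("probs") = probs,
                      Named("grads") = List::create(
                        Named("branches") = gBranches, Named("head") = gHead));
}
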