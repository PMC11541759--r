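// Fused forward + backward pass over one clip for the recurrent
// attention models (LSTM/GRU x aggregation/selection, optional Dice
// supervision, optional temporal attention, optionally trainable last
// encoder block).  This is the training hot path; it computes exactly
// the same quantities as the R tape (asserted in the test suite) with
// the per-frame loop and all gradient reductions done natively.
//
// Layouts follow the R side: features are stacked frame blocks of
// `cells` rows; the LSTM gate order is i, f, g, o; the GRU gate order
// is r, z, n with separate input/recurrent biases.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec softmax_vec_c(const vec& s) {
  vec e = exp(s - s.max());
  return e / accu(e);
}

// feat: (N*cells) x C_in stacked features (final features, or the
// penultimate stage when train_last).  B: N x cells binary heat maps
// (0 x 0 when unused).  lastW/lastb: the last encoder block when
// train_last.
// [[Rcpp::export]]
Rcpp::List fast_clip_grad(const arma::mat& feat, const arma::mat& Ma,
                          const arma::mat& Ms, const arma::vec& Mo,
                          const arma::mat& W, const arma::mat& U,
                          const arma::vec& b, const arma::vec& bh,
                          const arma::vec& cls_w, const double cls_b,
                          const arma::mat& B, const arma::mat& lastW,
                          const arma::vec& lastb, const int N,
                          const int cells, const double label,
                          const double lambda, const double eps,
                          const bool use_hidden, const bool selection,
                          const bool gru, const bool temporal_attention,
                          const bool train_last,
                          const bool want_attention) {

  const int Ch = cls_w.n_elem;
  const int gate_w = W.n_cols;  // 4*Ch (lstm) or 3*Ch (gru)

  // optional trainable last block: P = relu(feat * lastW + lastb)
  mat P;
  if (train_last) {
    P = feat * lastW;
    P.each_row() += lastb.t();
    P = clamp(P, 0.0, datum::inf);
  } else {
    P = feat;
  }
  const int Ce = P.n_cols;

  // appearance scores for all frames in one product
  mat FAPP = P * Ma;                    // (N*cells) x Catt
  const int Catt = Ma.n_cols;

  // forward storage
  mat Z(N * cells, Catt);               // relu'd pre-activations
  mat A(N, cells);                      // attention weights per frame
  mat X(N, Ce);                         // attended features
  mat GATES(N, gate_w);                 // gate activations
  mat Hs(N, Ch), Cs(N, Ch), TC(N, Ch);  // hidden, cell, tanh(cell)
  mat AH;                               // gru: recurrent pre-activations
  if (gru) AH.set_size(N, gate_w);
  uvec selidx(N);

  vec h(Ch, fill::zeros), c(Ch, fill::zeros);
  for (int i = 0; i < N; ++i) {
    const int r0 = i * cells;
    mat pre = FAPP.rows(r0, r0 + cells - 1);
    if (use_hidden) pre.each_row() += (h.t() * Ms);
    mat Zi = clamp(pre, 0.0, datum::inf);
    Z.rows(r0, r0 + cells - 1) = Zi;
    vec att = softmax_vec_c(Zi * Mo);
    A.row(i) = att.t();
    vec x;
    if (selection) {
      selidx(i) = att.index_max();
      x = P.row(r0 + selidx(i)).t();
    } else {
      x = P.rows(r0, r0 + cells - 1).t() * att;
    }
    X.row(i) = x.t();
    if (!gru) {
      vec a = W.t() * x + U.t() * h + b;
      vec ii = 1.0 / (1.0 + exp(-a.subvec(0, Ch - 1)));
      vec ff = 1.0 / (1.0 + exp(-a.subvec(Ch, 2 * Ch - 1)));
      vec gg = tanh(a.subvec(2 * Ch, 3 * Ch - 1));
      vec oo = 1.0 / (1.0 + exp(-a.subvec(3 * Ch, 4 * Ch - 1)));
      c = ff % c + ii % gg;
      vec tc = tanh(c);
      h = oo % tc;
      GATES.row(i) = join_cols(ii, ff, gg, oo).t();
      Cs.row(i) = c.t(); TC.row(i) = tc.t(); Hs.row(i) = h.t();
    } else {
      vec ax = W.t() * x + b;
      vec ah = U.t() * h + bh;
      AH.row(i) = ah.t();
      vec r = 1.0 / (1.0 + exp(-(ax.subvec(0, Ch - 1) + ah.subvec(0, Ch - 1))));
      vec z = 1.0 / (1.0 + exp(-(ax.subvec(Ch, 2 * Ch - 1) + ah.subvec(Ch, 2 * Ch - 1))));
      vec n = tanh(ax.subvec(2 * Ch, 3 * Ch - 1) + r % ah.subvec(2 * Ch, 3 * Ch - 1));
      h = (1.0 - z) % n + z % h;
      GATES.row(i) = join_cols(r, z, n).t();
      Hs.row(i) = h.t();
    }
  }

  // temporal summary
  vec hf(Ch), at;
  if (temporal_attention) {
    vec hN = Hs.row(N - 1).t();
    vec beta = Hs * hN;
    at = softmax_vec_c(beta);
    hf = Hs.t() * at;
  } else {
    hf = Hs.row(N - 1).t();
  }

  // classifier + losses
  const double logit = dot(hf, cls_w) + cls_b;
  const double p = 1.0 / (1.0 + exp(-logit));
  const double bce = std::max(logit, 0.0) - logit * label +
    std::log1p(std::exp(-std::abs(logit)));
  double dice = NA_REAL, inter = 0.0, den = 0.0;
  const bool use_dice = B.n_rows > 0;
  if (use_dice) {
    inter = accu(A % B);
    den = accu(A) + accu(B) + eps;
    dice = 1.0 - (2.0 * inter + eps) / den;
  }
  const double loss = bce + (use_dice ? lambda * dice : 0.0);

  // ---- backward ----
  const double dlogit = p - label;
  vec ghf = dlogit * cls_w;
  vec gcls_w = dlogit * hf;
  const double gcls_b = dlogit;

  mat gH(N, Ch, fill::zeros);
  if (temporal_attention) {
    vec hN = Hs.row(N - 1).t();
    vec ga = Hs * ghf;
    vec gbeta = at % (ga - dot(ga, at));
    gH = at * ghf.t() + gbeta * hN.t();
    gH.row(N - 1) += (Hs.t() * gbeta).t();
  } else {
    gH.row(N - 1) = ghf.t();
  }

  // dice gradient on attention weights
  mat gA(N, cells, fill::zeros);
  if (use_dice && lambda > 0) {
    const double num = 2.0 * inter + eps;
    gA = lambda * (num / (den * den) - 2.0 * B / den);
  }

  mat GPRE(N * cells, Catt);     // for gMa
  mat GFSP, HPREV_ATT;
  if (use_hidden) { GFSP.set_size(N, Catt); HPREV_ATT.set_size(N, Ch); }
  mat GGA(N, gate_w);            // gate-preactivation grads (x side)
  mat GAH;                       // gru recurrent side
  if (gru) GAH.set_size(N, gate_w);
  mat HPREV(N, Ch);
  vec gMo(Catt, fill::zeros);
  mat gP;
  if (train_last) gP.zeros(N * cells, Ce);

  vec gh_carry(Ch, fill::zeros), gc_carry(Ch, fill::zeros);
  for (int i = N - 1; i >= 0; --i) {
    const int r0 = i * cells;
    vec h_prev = (i == 0) ? vec(Ch, fill::zeros) : Hs.row(i - 1).t();
    HPREV.row(i) = h_prev.t();
    vec gh = gH.row(i).t() + gh_carry;
    vec gx(Ce);
    if (!gru) {
      vec ii = GATES.row(i).subvec(0, Ch - 1).t();
      vec ff = GATES.row(i).subvec(Ch, 2 * Ch - 1).t();
      vec gg = GATES.row(i).subvec(2 * Ch, 3 * Ch - 1).t();
      vec oo = GATES.row(i).subvec(3 * Ch, 4 * Ch - 1).t();
      vec tc = TC.row(i).t();
      vec c_prev = (i == 0) ? vec(Ch, fill::zeros) : Cs.row(i - 1).t();
      vec gc = gc_carry + gh % oo % (1.0 - tc % tc);
      vec go = gh % tc;
      vec gf = gc % c_prev;
      vec gi = gc % gg;
      vec gg_ = gc % ii;
      vec ga = join_cols(gi % ii % (1.0 - ii),
                         gf % ff % (1.0 - ff),
                         gg_ % (1.0 - gg % gg),
                         go % oo % (1.0 - oo));
      GGA.row(i) = ga.t();
      gx = W * ga;
      gh_carry = U * ga;
      gc_carry = gc % ff;
    } else {
      vec r = GATES.row(i).subvec(0, Ch - 1).t();
      vec z = GATES.row(i).subvec(Ch, 2 * Ch - 1).t();
      vec n = GATES.row(i).subvec(2 * Ch, 3 * Ch - 1).t();
      vec ahn = AH.row(i).subvec(2 * Ch, 3 * Ch - 1).t();
      vec gz = gh % (h_prev - n);
      vec gn = gh % (1.0 - z);
      vec gan = gn % (1.0 - n % n);
      vec gr = gan % ahn;
      vec gahn = gan % r;
      vec gaz = gz % z % (1.0 - z);
      vec gar = gr % r % (1.0 - r);
      vec gax = join_cols(gar, gaz, gan);
      vec gah = join_cols(gar, gaz, gahn);
      GGA.row(i) = gax.t();
      GAH.row(i) = gah.t();
      gx = W * gax;
      gh_carry = U * gah + gh % z;
    }
    // attention backward for frame i
    vec att = A.row(i).t();
    vec g_att = gA.row(i).t();
    if (selection) {
      if (train_last) gP.row(r0 + selidx(i)) += gx.t();
    } else {
      g_att += P.rows(r0, r0 + cells - 1) * gx;
      if (train_last) gP.rows(r0, r0 + cells - 1) += att * gx.t();
    }
    vec gs = att % (g_att - dot(g_att, att));
    mat Zi = Z.rows(r0, r0 + cells - 1);
    gMo += Zi.t() * gs;
    mat gpre = (gs * Mo.t()) % (Zi > 0);
    GPRE.rows(r0, r0 + cells - 1) = gpre;
    if (train_last) gP.rows(r0, r0 + cells - 1) += gpre * Ma.t();
    if (use_hidden) {
      vec gfsp = sum(gpre, 0).t();
      GFSP.row(i) = gfsp.t();
      HPREV_ATT.row(i) = h_prev.t();
      gh_carry += Ms * gfsp;
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("prob") = p,
    Rcpp::Named("bce") = bce,
    Rcpp::Named("dice") = dice,
    Rcpp::Named("loss") = loss,
    Rcpp::Named("gMa") = P.t() * GPRE,
    Rcpp::Named("gMo") = gMo,
    Rcpp::Named("gW") = X.t() * GGA,
    Rcpp::Named("gU") = gru ? mat(HPREV.t() * GAH) : mat(HPREV.t() * GGA),
    Rcpp::Named("gb") = gru ? vec(sum(GGA, 0).t()) : vec(sum(GGA, 0).t()),
    Rcpp::Named("gcls_w") = gcls_w,
    Rcpp::Named("gcls_b") = gcls_b);
  if (gru) out["gbh"] = vec(sum(GAH, 0).t());
  if (use_hidden) out["gMs"] = mat(HPREV_ATT.t() * GFSP);
  if (train_last) {
    mat gPm = gP % (P > 0);
    out["glastW"] = mat(feat.t() * gPm);
    out["glastb"] = vec(sum(gPm, 0).t());
  }
  if (want_attention) out["attention"] = A;
  return out;
}
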