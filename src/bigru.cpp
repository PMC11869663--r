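// Batch engine for the bidirectional GRU detector.
//
// All sequence batches are stored "time-major flat": a (T*B) x D matrix whose
// rows t*B ... t*B+B-1 hold the B trials' feature vectors at frame t. This
// keeps each timestep a contiguous block so the recurrence works on plain
// submatrix views while the input projections are done in one large GEMM.
//
// The engine computes in single precision (the usual choice for training
// networks of this size; parameters and gradients cross the R boundary as
// doubles). The update/reset gates share one fused GEMM per step, and the
// hidden-to-hidden weight gradients are accumulated in one GEMM per layer
// after the time loop instead of one per step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline fmat sigm(const fmat& x) { return 1.0f / (1.0f + exp(-x)); }

struct DirParams {
  fmat Wall;   // [Wz; Wr; Wh], 3H x D
  fmat UzUr;   // [Uz; Ur], 2H x H
  fmat Uh;     // H x H
  fvec ball;   // [bz; br; bh]
  int H;
};

static DirParams get_dir(const List& p) {
  DirParams d;
  fmat Wz = conv_to<fmat>::from(Rcpp::as<mat>(p["Wz"]));
  fmat Wr = conv_to<fmat>::from(Rcpp::as<mat>(p["Wr"]));
  fmat Wh = conv_to<fmat>::from(Rcpp::as<mat>(p["Wh"]));
  fmat Uz = conv_to<fmat>::from(Rcpp::as<mat>(p["Uz"]));
  fmat Ur = conv_to<fmat>::from(Rcpp::as<mat>(p["Ur"]));
  d.Uh = conv_to<fmat>::from(Rcpp::as<mat>(p["Uh"]));
  fvec bz = conv_to<fvec>::from(Rcpp::as<vec>(p["bz"]));
  fvec br = conv_to<fvec>::from(Rcpp::as<vec>(p["br"]));
  fvec bh = conv_to<fvec>::from(Rcpp::as<vec>(p["bh"]));
  d.Wall = join_cols(join_cols(Wz, Wr), Wh);
  d.UzUr = join_cols(Uz, Ur);
  d.ball = join_cols(join_cols(bz, br), bh);
  d.H = Uz.n_rows;
  return d;
}

struct DirCache {
  fmat Z, R, C, S, H, Hprev;  // (T*B) x H, time-major; S = r (.) h_prev
};

// One GRU direction over the whole batch. rev = scan the sequence backwards.
static void run_dir(const fmat& XF, int T, int B, const DirParams& p, bool rev,
                    DirCache& c) {
  const int H = p.H, N = T * B;
  fmat P = XF * p.Wall.t();  // N x 3H
  P.each_row() += p.ball.t();
  c.Z.set_size(N, H); c.R.set_size(N, H); c.C.set_size(N, H);
  c.S.set_size(N, H); c.H.set_size(N, H); c.Hprev.set_size(N, H);
  fmat hprev(B, H, fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = rev ? (T - 1 - s) : s;
    int r0 = t * B, r1 = t * B + B - 1;
    c.Hprev.rows(r0, r1) = hprev;
    fmat Azr = hprev * p.UzUr.t();  // B x 2H
    fmat Zt = sigm(P.submat(r0, 0, r1, H - 1) + Azr.cols(0, H - 1));
    fmat Rt = sigm(P.submat(r0, H, r1, 2 * H - 1) + Azr.cols(H, 2 * H - 1));
    fmat St = Rt % hprev;
    fmat Ct = tanh(P.submat(r0, 2 * H, r1, 3 * H - 1) + St * p.Uh.t());
    hprev = (1.0f - Zt) % hprev + Zt % Ct;
    c.Z.rows(r0, r1) = Zt; c.R.rows(r0, r1) = Rt; c.C.rows(r0, r1) = Ct;
    c.S.rows(r0, r1) = St; c.H.rows(r0, r1) = hprev;
  }
}

static Rcpp::NumericMatrix to_dmat(const fmat& x) {
  return Rcpp::wrap(conv_to<mat>::from(x));
}
static Rcpp::NumericVector to_dvec(const fvec& x) {
  return Rcpp::wrap(conv_to<vec>::from(x));
}

// Backprop through one direction. dH = gradient wrt the direction's per-frame
// outputs; accumulates the input gradient into dXF and returns the parameter
// gradients (as doubles, in the same slot order as gru_cell_params).
static List back_dir(const fmat& XF, int T, int B, const DirParams& p, bool rev,
                     const DirCache& c, const fmat& dH, fmat& dXF) {
  const int H = p.H, N = T * B;
  fmat DA(N, 3 * H);
  fmat dcarry(B, H, fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = rev ? (T - 1 - s) : s;
    int r0 = t * B, r1 = t * B + B - 1;
    fmat hprev = c.Hprev.rows(r0, r1);
    fmat z = c.Z.rows(r0, r1), r = c.R.rows(r0, r1), cc = c.C.rows(r0, r1);
    fmat dh = dH.rows(r0, r1) + dcarry;
    fmat daz = dh % (cc - hprev) % z % (1.0f - z);
    fmat dac = dh % z % (1.0f - cc % cc);
    dcarry = dh % (1.0f - z);
    fmat ds = dac * p.Uh;
    fmat dar = (ds % hprev) % r % (1.0f - r);
    dcarry += ds % r + join_rows(daz, dar) * p.UzUr;
    DA.submat(r0, 0, r1, H - 1) = daz;
    DA.submat(r0, H, r1, 2 * H - 1) = dar;
    DA.submat(r0, 2 * H, r1, 3 * H - 1) = dac;
  }
  fmat gW = DA.t() * XF;  // 3H x D
  fmat gUzr = DA.cols(0, 2 * H - 1).t() * c.Hprev;  // [gUz; gUr]
  fmat gUh = DA.cols(2 * H, 3 * H - 1).t() * c.S;
  dXF += DA * p.Wall;
  frowvec gb = sum(DA, 0);
  return List::create(
      Named("Wz") = to_dmat(gW.rows(0, H - 1)),
      Named("Wr") = to_dmat(gW.rows(H, 2 * H - 1)),
      Named("Wh") = to_dmat(gW.rows(2 * H, 3 * H - 1)),
      Named("Uz") = to_dmat(gUzr.rows(0, H - 1)),
      Named("Ur") = to_dmat(gUzr.rows(H, 2 * H - 1)),
      Named("Uh") = to_dmat(gUh),
      Named("bz") = to_dvec(gb.cols(0, H - 1).t()),
      Named("br") = to_dvec(gb.cols(H, 2 * H - 1).t()),
      Named("bh") = to_dvec(gb.cols(2 * H, 3 * H - 1).t()));
}

// Full forward (and optional backward) pass through the two Bi-GRU layers and
// the batch-norm / dropout / dense head.
//
// XF:        (T*B) x D, time-major flat.
// y_true:    length T*B target (time-major) or length 0 for prediction only.
// lambda:    per-frame loss weights, same layout as y_true.
// drop_mask: (T*B) x F2 inverted-dropout mask (entries 0 or 1/(1-p)), or a
//            0-row matrix for no dropout.
// train_bn:  use batch statistics (and report them) instead of running stats.
//
// The training loss is the weighted squared error averaged over all frames in
// the batch: mean(lambda * (y_pred - y_true)^2).
// [[Rcpp::export]]
List cpp_bigru_pass(const arma::mat& XF, int T, int B, const List& params,
                    const arma::vec& y_true, const arma::vec& lambda,
                    const arma::mat& drop_mask, bool train_bn,
                    bool compute_grad, double bn_eps) {
  const int N = T * B;
  fmat XFf = conv_to<fmat>::from(XF);
  DirParams l1f = get_dir(params["l1f"]), l1b = get_dir(params["l1b"]);
  DirParams l2f = get_dir(params["l2f"]), l2b = get_dir(params["l2b"]);
  List head = params["head"];
  fvec gamma = conv_to<fvec>::from(Rcpp::as<vec>(head["gamma"]));
  fvec beta = conv_to<fvec>::from(Rcpp::as<vec>(head["beta"]));
  fvec vdense = conv_to<fvec>::from(Rcpp::as<vec>(head["v"]));
  float bdense = (float)Rcpp::as<double>(head["b"]);
  float eps = (float)bn_eps;

  DirCache c1f, c1b, c2f, c2b;
  run_dir(XFf, T, B, l1f, false, c1f);
  run_dir(XFf, T, B, l1b, true, c1b);
  fmat O1 = join_rows(c1f.H, c1b.H);  // N x 2H1
  run_dir(O1, T, B, l2f, false, c2f);
  run_dir(O1, T, B, l2b, true, c2b);
  fmat O2 = join_rows(c2f.H, c2b.H);  // N x F2

  frowvec mu, var_;
  if (train_bn) {
    mu = mean(O2, 0);
    fmat dev = O2;
    dev.each_row() -= mu;
    var_ = mean(square(dev), 0);  // population variance
  } else {
    mu = conv_to<fvec>::from(Rcpp::as<vec>(head["run_mean"])).t();
    var_ = conv_to<fvec>::from(Rcpp::as<vec>(head["run_var"])).t();
  }
  frowvec istd = 1.0f / sqrt(var_ + eps);
  fmat Xhat = O2;
  Xhat.each_row() -= mu;
  Xhat.each_row() %= istd;
  fmat Y = Xhat;
  Y.each_row() %= gamma.t();
  Y.each_row() += beta.t();
  bool use_drop = drop_mask.n_rows > 0;
  fmat maskf;
  if (use_drop) maskf = conv_to<fmat>::from(drop_mask);
  fmat D = use_drop ? fmat(Y % maskf) : Y;
  fvec y_pred = D * vdense + bdense;

  double loss = NA_REAL;
  fvec yt, lam;
  if (y_true.n_elem == (unsigned)N) {
    yt = conv_to<fvec>::from(y_true);
    lam = conv_to<fvec>::from(lambda);
    loss = dot(conv_to<vec>::from(lam),
               conv_to<vec>::from(fvec(square(y_pred - yt)))) / double(N);
  }

  List out = List::create(Named("y_pred") = to_dvec(y_pred),
                          Named("loss") = loss,
                          Named("bn_mean") = to_dvec(mu.t()),
                          Named("bn_var") = to_dvec(var_.t()));
  if (!compute_grad) return out;

  fvec dyp = 2.0f * (lam % (y_pred - yt)) / float(N);
  fvec gv = D.t() * dyp;
  double gb = accu(conv_to<vec>::from(dyp));
  fmat dD = dyp * vdense.t();  // N x F2
  fmat dY = use_drop ? fmat(dD % maskf) : dD;
  fvec ggamma = sum(dY % Xhat, 0).t();
  fvec gbeta = sum(dY, 0).t();
  fmat dXhat = dY;
  dXhat.each_row() %= gamma.t();
  fmat dO2;
  if (train_bn) {
    frowvec m1 = mean(dXhat, 0);
    frowvec m2 = mean(dXhat % Xhat, 0);
    dO2 = dXhat;
    dO2.each_row() -= m1;
    fmat t2 = Xhat;
    t2.each_row() %= m2;
    dO2 -= t2;
    dO2.each_row() %= istd;
  } else {
    dO2 = dXhat;
    dO2.each_row() %= istd;
  }

  fmat dO1(N, O1.n_cols, fill::zeros);
  int H2 = l2f.H;
  List g2f = back_dir(O1, T, B, l2f, false, c2f, dO2.cols(0, H2 - 1), dO1);
  List g2b = back_dir(O1, T, B, l2b, true, c2b, dO2.cols(H2, 2 * H2 - 1), dO1);
  fmat dXFg(N, XFf.n_cols, fill::zeros);
  int H1 = l1f.H;
  List g1f = back_dir(XFf, T, B, l1f, false, c1f, dO1.cols(0, H1 - 1), dXFg);
  List g1b = back_dir(XFf, T, B, l1b, true, c1b, dO1.cols(H1, 2 * H1 - 1), dXFg);

  out["grads"] = List::create(
      Named("l1f") = g1f, Named("l1b") = g1b, Named("l2f") = g2f,
      Named("l2b") = g2b,
      Named("head") = List::create(Named("gamma") = to_dvec(ggamma),
                                   Named("beta") = to_dvec(gbeta),
                                   Named("v") = to_dvec(gv), Named("b") = gb));
  return out;
}

// Direct-form-II-transposed IIR filter with explicit initial state, the same
// recurrence scipy's lfilter uses. Coefficient vectors b and a must have equal
// length with a[0] == 1; zi has length(a) - 1.
// [[Rcpp::export]]
arma::vec cpp_iir_df2t(const arma::vec& b, const arma::vec& a,
                       const arma::vec& x, const arma::vec& zi) {
  const int n = x.n_elem, m = a.n_elem - 1;
  vec z = zi, y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (m > 0 ? z[0] : 0.0);
    for (int j = 0; j < m - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    if (m > 0) z[m - 1] = b[m] * xi - a[m] * yi;
    y[i] = yi;
  }
  return y;
}
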