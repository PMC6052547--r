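// LSTM forward / backward kernels.
//
// Network: residue index -> embedding row (d) -> forget-gate LSTM (H)
// -> fully connected head (20) -> softmax, one probability column per site.
// Gate order inside concatenated 4H blocks: [input | forget | candidate | output].
// Residue indices are 1-based (1..20); index A (last embedding row) is the
// padding symbol whose embedding row is held at zero and never updated.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

namespace {

struct Params {
  mat E;      // A x d embedding table (row A = padding, all zero)
  mat Wx;     // d x 4H input weights
  mat Wh;     // H x 4H recurrent weights
  rowvec b;   // 4H bias
  mat Wy;     // H x 20 head weights
  rowvec by;  // 20 head bias
  int d, H;
};

Params unpack(const List& par) {
  Params P;
  P.E  = as<mat>(par["embed"]);
  P.Wx = as<mat>(par["Wx"]);
  P.Wh = as<mat>(par["Wh"]);
  P.b  = as<rowvec>(par["b"]);
  P.Wy = as<mat>(par["Wy"]);
  P.by = as<rowvec>(par["by"]);
  P.d  = P.Wx.n_rows;
  P.H  = P.Wh.n_rows;
  if ((int)P.Wx.n_cols != 4 * P.H || (int)P.b.n_elem != 4 * P.H)
    stop("inconsistent LSTM parameter shapes");
  if ((int)P.E.n_cols != P.d) stop("embedding width does not match Wx");
  if (P.Wy.n_rows != (unsigned)P.H || P.Wy.n_cols != 20 || P.by.n_elem != 20)
    stop("inconsistent head shapes");
  return P;
}

inline rowvec sigm(const rowvec& x) { return 1.0 / (1.0 + exp(-x)); }

inline rowvec softmax_row(rowvec s) {
  s -= s.max();
  rowvec y = exp(s);
  return y / accu(y);
}

// Run positions lo..hi (0-based, inclusive) from the null state.
// If Y != nullptr store every softmax row at its absolute position;
// always returns the softmax row of position hi.
rowvec forward_window(const ivec& s, int lo, int hi, const Params& P, mat* Y) {
  const int H = P.H;
  rowvec h(H, fill::zeros), c(H, fill::zeros), y;
  for (int t = lo; t <= hi; ++t) {
    int code = s[t];
    if (code < 1 || code > (int)P.E.n_rows) stop("residue code out of range");
    rowvec u = P.E.row(code - 1);
    rowvec a = u * P.Wx + h * P.Wh + P.b;
    rowvec gi = sigm(a.cols(0, H - 1));
    rowvec gf = sigm(a.cols(H, 2 * H - 1));
    rowvec gz = tanh(a.cols(2 * H, 3 * H - 1));
    rowvec go = sigm(a.cols(3 * H, 4 * H - 1));
    c = gf % c + gi % gz;
    h = go % tanh(c);
    y = softmax_row(h * P.Wy + P.by);
    if (Y) Y->row(t) = y;
  }
  return y;
}

}  // namespace

// [[Rcpp::export]]
List cpp_forward(const IntegerVector& seq, const List& par) {
  Params P = unpack(par);
  const int N = seq.size();
  if (N < 1) stop("empty sequence");
  ivec s(N);
  for (int t = 0; t < N; ++t) s[t] = seq[t];
  mat Y(N, 20);
  forward_window(s, 0, N - 1, P, &Y);
  return List::create(_["profile"] = Y, _["steps"] = N);
}

// Memory-reset prediction: row t is the last output of a fresh run over the
// window max(0, t-L+1)..t, i.e. the network sees at most L sites of context.
// [[Rcpp::export]]
List cpp_truncated_forward(const IntegerVector& seq, const List& par, int L) {
  if (L < 1) stop("L must be >= 1");
  Params P = unpack(par);
  const int N = seq.size();
  if (N < 1) stop("empty sequence");
  ivec s(N);
  for (int t = 0; t < N; ++t) s[t] = seq[t];
  mat Y(N, 20);
  long long steps = 0;
  for (int t = 0; t < N; ++t) {
    int lo = std::max(0, t - L + 1);
    Y.row(t) = forward_window(s, lo, t, P, nullptr);
    steps += t - lo + 1;
  }
  return List::create(_["profile"] = Y, _["steps"] = steps);
}

// Batched forward + BPTT gradients of the RMSE cost over a mini-batch.
// Sequences must be sorted by non-increasing length (lockstep batching: at
// step t the active members are a prefix of the batch). Dropout (inverted
// scaling) is applied to the embedding output; masks come from a dedicated
// mt19937 stream so runs are reproducible given the seed.
// [[Rcpp::export]]
List cpp_batch_grad(const List& seqs, const List& targets, const List& par,
                    double dropout, int dropout_seed) {
  Params P = unpack(par);
  const int B = seqs.size();
  if (targets.size() != B) stop("seqs/targets length mismatch");
  const int d = P.d, H = P.H, A = P.E.n_rows;

  std::vector<ivec> S(B);
  std::vector<mat> T(B);
  ivec lens(B);
  for (int i = 0; i < B; ++i) {
    IntegerVector si = seqs[i];
    S[i] = ivec(si.size());
    for (int t = 0; t < si.size(); ++t) S[i][t] = si[t];
    T[i] = as<mat>(targets[i]);
    lens[i] = si.size();
    if ((int)T[i].n_rows != lens[i] || T[i].n_cols != 20)
      stop("target shape mismatch at pair %d", i + 1);
    if (i > 0 && lens[i] > lens[i - 1])
      stop("batch must be sorted by non-increasing length");
  }
  const int maxN = lens.max();
  // active prefix size per step
  ivec nact(maxN);
  for (int t = 0; t < maxN; ++t) {
    int n = 0;
    while (n < B && lens[n] > t) ++n;
    nact[t] = n;
  }

  const bool drop = dropout > 0.0;
  std::mt19937 gen(static_cast<unsigned>(dropout_seed));
  const double keep = 1.0 - dropout;

  cube U(B, d, maxN, fill::zeros);     // embedding output after dropout
  cube Msk(drop ? B : 0, drop ? d : 0, drop ? maxN : 0); // scaled keep mask
  cube GI(B, H, maxN), GF(B, H, maxN), GZ(B, H, maxN), GO(B, H, maxN);
  cube C(B, H, maxN), V(B, H, maxN), Y(B, 20, maxN);

  mat h(B, H, fill::zeros), c(B, H, fill::zeros);

  for (int t = 0; t < maxN; ++t) {
    const int na = nact[t];
    mat e(na, d);
    for (int i = 0; i < na; ++i) {
      int code = S[i][t];
      if (code < 1 || code > A) stop("residue code out of range");
      e.row(i) = P.E.row(code - 1);
    }
    if (drop) {
      mat m(na, d);
      for (int i = 0; i < na; ++i)
        for (int j = 0; j < d; ++j) {
          double r = gen() * (1.0 / 4294967296.0);
          m(i, j) = (r < dropout) ? 0.0 : 1.0 / keep;
        }
      e %= m;
      Msk.slice(t).rows(0, na - 1) = m;
    }
    U.slice(t).rows(0, na - 1) = e;

    mat a = e * P.Wx + h.rows(0, na - 1) * P.Wh;
    a.each_row() += P.b;
    mat gi = 1.0 / (1.0 + exp(-a.cols(0, H - 1)));
    mat gf = 1.0 / (1.0 + exp(-a.cols(H, 2 * H - 1)));
    mat gz = tanh(a.cols(2 * H, 3 * H - 1));
    mat go = 1.0 / (1.0 + exp(-a.cols(3 * H, 4 * H - 1)));
    mat cn = gf % c.rows(0, na - 1) + gi % gz;
    mat vn = go % tanh(cn);
    GI.slice(t).rows(0, na - 1) = gi;
    GF.slice(t).rows(0, na - 1) = gf;
    GZ.slice(t).rows(0, na - 1) = gz;
    GO.slice(t).rows(0, na - 1) = go;
    C.slice(t).rows(0, na - 1) = cn;
    V.slice(t).rows(0, na - 1) = vn;
    c.rows(0, na - 1) = cn;
    h.rows(0, na - 1) = vn;

    mat s = vn * P.Wy;
    s.each_row() += P.by;
    vec mx = max(s, 1);
    s.each_col() -= mx;
    mat ey = exp(s);
    ey.each_col() /= sum(ey, 1);
    Y.slice(t).rows(0, na - 1) = ey;
  }

  // RMSE over all valid entries of the batch
  const double M = 20.0 * accu(lens);
  double sq = 0.0;
  for (int i = 0; i < B; ++i)
    for (int t = 0; t < lens[i]; ++t) {
      rowvec r = Y.slice(t).row(i) - T[i].row(t);
      sq += dot(r, r);
    }
  const double loss = std::sqrt(sq / M);

  mat gE(A, d, fill::zeros), gWx(d, 4 * H, fill::zeros),
      gWh(H, 4 * H, fill::zeros), gWy(H, 20, fill::zeros);
  rowvec gb(4 * H, fill::zeros), gby(20, fill::zeros);

  if (loss > 0.0) {
    const double k = 1.0 / (M * loss);
    mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);
    for (int t = maxN - 1; t >= 0; --t) {
      const int na = nact[t];
      mat y = Y.slice(t).rows(0, na - 1);
      mat G(na, 20);
      for (int i = 0; i < na; ++i) G.row(i) = k * (y.row(i) - T[i].row(t));
      // softmax backward, row-wise
      vec gdot = sum(G % y, 1);
      mat dS = y % (G.each_col() - gdot);
      mat vt = V.slice(t).rows(0, na - 1);
      gWy += vt.t() * dS;
      gby += sum(dS, 0);
      mat dhh = dh.rows(0, na - 1) + dS * P.Wy.t();

      mat ct = C.slice(t).rows(0, na - 1);
      mat tc = tanh(ct);
      mat go = GO.slice(t).rows(0, na - 1);
      mat dO = dhh % tc;
      mat dC = dc.rows(0, na - 1) + dhh % go % (1.0 - tc % tc);
      mat cprev = (t > 0) ? mat(C.slice(t - 1).rows(0, na - 1))
                          : mat(na, H, fill::zeros);
      mat gi = GI.slice(t).rows(0, na - 1);
      mat gf = GF.slice(t).rows(0, na - 1);
      mat gz = GZ.slice(t).rows(0, na - 1);
      mat dA(na, 4 * H);
      dA.cols(0, H - 1)         = (dC % gz) % gi % (1.0 - gi);
      dA.cols(H, 2 * H - 1)     = (dC % cprev) % gf % (1.0 - gf);
      dA.cols(2 * H, 3 * H - 1) = (dC % gi) % (1.0 - gz % gz);
      dA.cols(3 * H, 4 * H - 1) = dO % go % (1.0 - go);

      mat ut = U.slice(t).rows(0, na - 1);
      gWx += ut.t() * dA;
      gb += sum(dA, 0);
      mat hprev = (t > 0) ? mat(V.slice(t - 1).rows(0, na - 1))
                          : mat(na, H, fill::zeros);
      gWh += hprev.t() * dA;

      mat dU = dA * P.Wx.t();
      dh.rows(0, na - 1) = dA * P.Wh.t();
      dc.rows(0, na - 1) = dC % gf;

      if (drop) dU %= Msk.slice(t).rows(0, na - 1);
      for (int i = 0; i < na; ++i) gE.row(S[i][t] - 1) += dU.row(i);
    }
    gE.row(A - 1).zeros();  // padding embedding is fixed at zero
  }

  return List::create(
      _["loss"] = loss,
      _["grads"] = List::create(_["embed"] = gE, _["Wx"] = gWx, _["Wh"] = gWh,
                                _["b"] = gb, _["Wy"] = gWy, _["by"] = gby));
}

// Batched forward-only RMSE (dropout inactive); same lockstep scheme.
// [[Rcpp::export]]
double cpp_batch_loss(const List& seqs, const List& targets, const List& par) {
  Params P = unpack(par);
  const int B = seqs.size();
  const int H = P.H, d = P.d;
  std::vector<ivec> S(B);
  std::vector<mat> T(B);
  ivec lens(B);
  for (int i = 0; i < B; ++i) {
    IntegerVector si = seqs[i];
    S[i] = ivec(si.size());
    for (int t = 0; t < si.size(); ++t) S[i][t] = si[t];
    T[i] = as<mat>(targets[i]);
    lens[i] = si.size();
    if (i > 0 && lens[i] > lens[i - 1])
      stop("batch must be sorted by non-increasing length");
  }
  const int maxN = lens.max();
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  double sq = 0.0;
  for (int t = 0; t < maxN; ++t) {
    int na = 0;
    while (na < B && lens[na] > t) ++na;
    mat e(na, d);
    for (int i = 0; i < na; ++i) e.row(i) = P.E.row(S[i][t] - 1);
    mat a = e * P.Wx + h.rows(0, na - 1) * P.Wh;
    a.each_row() += P.b;
    mat gi = 1.0 / (1.0 + exp(-a.cols(0, H - 1)));
    mat gf = 1.0 / (1.0 + exp(-a.cols(H, 2 * H - 1)));
    mat gz = tanh(a.cols(2 * H, 3 * H - 1));
    mat go = 1.0 / (1.0 + exp(-a.cols(3 * H, 4 * H - 1)));
    mat cn = gf % c.rows(0, na - 1) + gi % gz;
    mat vn = go % tanh(cn);
    c.rows(0, na - 1) = cn;
    h.rows(0, na - 1) = vn;
    mat s = vn * P.Wy;
    s.each_row() += P.by;
    vec mx = max(s, 1);
    s.each_col() -= mx;
    mat ey = exp(s);
    ey.each_col() /= sum(ey, 1);
    for (int i = 0; i < na; ++i) {
      rowvec r = ey.row(i) - T[i].row(t);
      sq += dot(r, r);
    }
  }
  return std::sqrt(sq / (20.0 * accu(lens)));
}
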