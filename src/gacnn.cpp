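// Forward and backward passes for the patch-classification CNN.
//
// Layout conventions (shared with the R side):
//  * A batch of activations is an arma::mat of size (C, P*N) where C is the
//    channel count, P = H*W the number of spatial positions of one map and
//    N the batch size.  Column index = p + P*n with p = h + H*w (row index
//    h fastest, matching R's column-major matrices).
//  * Convolution weights are (outC, inC*k*k); column index
//    c + inC*(kh + k*kw).  Fully connected weights are (units, C*P) with
//    input feature index c + C*p.
//  * Convolutions use zero padding; pooling windows ignore padded cells.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::umat;
using arma::vec;
using arma::uword;

struct Geom {
  int C;   // input channels
  int H;   // input side (square maps)
  int k, s, p;
  int oH;  // output side, floor((H + 2p - k)/s) + 1
};

static int out_side(int H, int k, int s, int p) {
  int num = H + 2 * p - k;
  if (num < 0) stop("kernel larger than padded input (side %d, kernel %d, pad %d)", H, k, p);
  return num / s + 1;
}

// Sliding window sum across rows (channels): row i gets the sum of rows
// max(0, i-half) .. min(C-1, i+half) of M.
static mat winsum_rows(const mat& M, int half) {
  const int C = M.n_rows;
  mat cum = arma::cumsum(M, 0);
  mat out(arma::size(M));
  for (int i = 0; i < C; ++i) {
    int lo = std::max(0, i - half), hi = std::min(C - 1, i + half);
    if (lo == 0) out.row(i) = cum.row(hi);
    else out.row(i) = cum.row(hi) - cum.row(lo - 1);
  }
  return out;
}

// Cross-channel local response normalization: b_i = a_i / (k + alpha *
// sum_{j in window} a_j^2)^beta, window truncated at channel boundaries.
static mat lrn_fwd(const mat& A, double k, double alpha, double beta, int n, mat& D) {
  D = k + alpha * winsum_rows(arma::square(A), n / 2);
  return A % arma::pow(D, -beta);
}

static mat lrn_bwd(const mat& dB, const mat& A, const mat& D,
                   double alpha, double beta, int n) {
  mat M = dB % A % arma::pow(D, -beta - 1.0);
  return dB % arma::pow(D, -beta) - 2.0 * alpha * beta * (A % winsum_rows(M, n / 2));
}

static void im2col(const mat& A, int N, const Geom& g, mat& col) {
  const int P = g.H * g.H, oP = g.oH * g.oH, kk = g.k * g.k;
  col.zeros((uword)g.C * kk, (uword)oP * N);
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < g.oH; ++ow)
      for (int oh = 0; oh < g.oH; ++oh) {
        const uword cidx = oh + (uword)g.oH * ow + (uword)oP * n;
        double* dst = col.colptr(cidx);
        for (int kw = 0; kw < g.k; ++kw) {
          const int iw = ow * g.s + kw - g.p;
          if (iw < 0 || iw >= g.H) continue;
          for (int kh = 0; kh < g.k; ++kh) {
            const int ih = oh * g.s + kh - g.p;
            if (ih < 0 || ih >= g.H) continue;
            const double* src = A.colptr(ih + (uword)g.H * iw + (uword)P * n);
            std::memcpy(dst + (uword)g.C * (kh + g.k * kw), src, g.C * sizeof(double));
          }
        }
      }
}

static void col2im(const mat& dcol, int N, const Geom& g, mat& dA) {
  const int P = g.H * g.H, oP = g.oH * g.oH;
  dA.zeros(g.C, (uword)P * N);
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < g.oH; ++ow)
      for (int oh = 0; oh < g.oH; ++oh) {
        const uword cidx = oh + (uword)g.oH * ow + (uword)oP * n;
        const double* src = dcol.colptr(cidx);
        for (int kw = 0; kw < g.k; ++kw) {
          const int iw = ow * g.s + kw - g.p;
          if (iw < 0 || iw >= g.H) continue;
          for (int kh = 0; kh < g.k; ++kh) {
            const int ih = oh * g.s + kh - g.p;
            if (ih < 0 || ih >= g.H) continue;
            double* d = dA.colptr(ih + (uword)g.H * iw + (uword)P * n);
            const double* s = src + (uword)g.C * (kh + g.k * kw);
            for (int c = 0; c < g.C; ++c) d[c] += s[c];
          }
        }
      }
}

static void pool_fwd(const mat& A, int N, const Geom& g, mat& B, umat& AM) {
  const int P = g.H * g.H, oP = g.oH * g.oH;
  B.set_size(g.C, (uword)oP * N);
  B.fill(-arma::datum::inf);
  AM.zeros(g.C, (uword)oP * N);
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < g.oH; ++ow)
      for (int oh = 0; oh < g.oH; ++oh) {
        const uword cidx = oh + (uword)g.oH * ow + (uword)oP * n;
        double* b = B.colptr(cidx);
        uword* m = AM.colptr(cidx);
        for (int kw = 0; kw < g.k; ++kw) {
          const int iw = ow * g.s + kw - g.p;
          if (iw < 0 || iw >= g.H) continue;
          for (int kh = 0; kh < g.k; ++kh) {
            const int ih = oh * g.s + kh - g.p;
            if (ih < 0 || ih >= g.H) continue;
            const uword s = ih + (uword)g.H * iw + (uword)P * n;
            const double* a = A.colptr(s);
            for (int c = 0; c < g.C; ++c)
              if (a[c] > b[c]) { b[c] = a[c]; m[c] = s; }
          }
        }
      }
}

static void pool_bwd(const mat& dB, const umat& AM, int N, const Geom& g, mat& dA) {
  dA.zeros(g.C, (uword)g.H * g.H * N);
  for (uword j = 0; j < dB.n_cols; ++j) {
    const double* d = dB.colptr(j);
    const uword* m = AM.colptr(j);
    for (int c = 0; c < g.C; ++c) dA(c, m[c]) += d[c];
  }
}

static mat relu(const mat& Z) {
  mat Y = Z;
  Y.for_each([](double& v) { if (v < 0.0) v = 0.0; });
  return Y;
}

struct Cache {
  std::vector<mat> col, reluY, lrnD, lrnB, poolIn;  // per block
  std::vector<umat> poolAM;
  std::vector<Geom> gconv, gpool;
  mat F, H1relu, H1, dropmask, probs;
  int N;
};

// geom: 6x3 integer matrix, rows conv1,pool1,conv2,pool2,conv3,pool3,
// columns kernel, stride, padding.  Channel counts come from the weights.
static void run_forward(const List& params, const mat& X, const IntegerMatrix& geom,
                        double lk, double lalpha, double lbeta, int ln,
                        double dropout, bool training, Cache& c) {
  const int N = X.n_cols;
  c.N = N;
  int inC = 1;
  int inH = (int)std::lround(std::sqrt((double)X.n_rows));
  if (inH * inH != (int)X.n_rows)
    stop("patch rows (%d) are not a square map", (int)X.n_rows);
  c.col.resize(3); c.reluY.resize(3); c.lrnD.resize(3); c.lrnB.resize(3);
  c.poolIn.resize(3); c.poolAM.resize(3); c.gconv.resize(3); c.gpool.resize(3);

  // view of X as (1, P*N) without copying
  const mat A0((double*)X.memptr(), 1, X.n_elem, false, true);
  const mat* A = &A0;
  for (int i = 0; i < 3; ++i) {
    std::string wi = "W" + std::to_string(i + 1), bi = "b" + std::to_string(i + 1);
    mat W = as<mat>(params[wi]);
    vec b = as<vec>(params[bi]);
    Geom gc{inC, inH, geom(2 * i, 0), geom(2 * i, 1), geom(2 * i, 2), 0};
    gc.oH = out_side(gc.H, gc.k, gc.s, gc.p);
    if ((int)W.n_cols != inC * gc.k * gc.k)
      stop("conv%d weight has %d columns, expected %d", i + 1, (int)W.n_cols, inC * gc.k * gc.k);
    c.gconv[i] = gc;
    im2col(*A, N, gc, c.col[i]);
    mat Z = W * c.col[i];
    Z.each_col() += b;
    c.reluY[i] = relu(Z);
    c.lrnB[i] = lrn_fwd(c.reluY[i], lk, lalpha, lbeta, ln, c.lrnD[i]);
    const int outC = W.n_rows;
    Geom gp{outC, gc.oH, geom(2 * i + 1, 0), geom(2 * i + 1, 1), geom(2 * i + 1, 2), 0};
    gp.oH = out_side(gp.H, gp.k, gp.s, gp.p);
    c.gpool[i] = gp;
    mat B; umat AM;
    pool_fwd(c.lrnB[i], N, gp, B, AM);
    c.poolIn[i] = B;       // pooled output, input of next block
    c.poolAM[i] = AM;
    A = &c.poolIn[i];
    inC = outC;
    inH = gp.oH;
  }
  // flatten (C, P*N) -> (C*P, N)
  const int C = inC, P = inH * inH;
  c.F.set_size((uword)C * P, N);
  for (int n = 0; n < N; ++n)
    c.F.col(n) = arma::vectorise(A->cols((uword)P * n, (uword)P * n + P - 1));

  mat W4 = as<mat>(params["W4"]);
  vec b4 = as<vec>(params["b4"]);
  mat W5 = as<mat>(params["W5"]);
  vec b5 = as<vec>(params["b5"]);
  if (W4.n_cols != c.F.n_rows)
    stop("fc1 weight has %d columns, expected %d", (int)W4.n_cols, (int)c.F.n_rows);
  mat H1pre = W4 * c.F;
  H1pre.each_col() += b4;
  c.H1relu = relu(H1pre);
  c.H1 = c.H1relu;
  if (training && dropout > 0.0) {
    c.dropmask.set_size(arma::size(c.H1));
    const double keep = 1.0 - dropout;
    for (uword j = 0; j < c.dropmask.n_elem; ++j)
      c.dropmask(j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    c.H1 %= c.dropmask;
  }
  mat logits = W5 * c.H1;
  logits.each_col() += b5;
  logits.each_row() -= arma::max(logits, 0);
  mat e = arma::exp(logits);
  c.probs = e;
  c.probs.each_row() /= arma::sum(e, 0);
}

// [[Rcpp::export]]
NumericMatrix cpp_gacnn_forward(List params, NumericMatrix X, IntegerMatrix geom,
                                List lrnp, double dropout, bool training) {
  mat Xa(X.begin(), X.nrow(), X.ncol(), false, true);
  Cache c;
  run_forward(params, Xa, geom,
              as<double>(lrnp["k"]), as<double>(lrnp["alpha"]),
              as<double>(lrnp["beta"]), as<int>(lrnp["n"]),
              dropout, training, c);
  // return N x 2 (column 2 = class 1 = liver)
  mat out = c.probs.t();
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_gacnn_loss_grads(List params, NumericMatrix X, IntegerVector y,
                          IntegerMatrix geom, List lrnp, double dropout) {
  const int N = X.ncol();
  if (y.size() != N) stop("labels do not match batch size");
  mat Xa(X.begin(), X.nrow(), X.ncol(), false, true);
  const double lk = as<double>(lrnp["k"]), lalpha = as<double>(lrnp["alpha"]),
               lbeta = as<double>(lrnp["beta"]);
  const int ln = as<int>(lrnp["n"]);
  Cache c;
  run_forward(params, Xa, geom, lk, lalpha, lbeta, ln, dropout, true, c);

  // mean binary cross-entropy on the liver-class probability (row 1),
  // probabilities clipped away from {0,1} by 1e-12 before the logs
  const double eps = 1e-12;
  double loss = 0.0;
  for (int n = 0; n < N; ++n) {
    double p1 = std::min(1.0 - eps, std::max(eps, c.probs(1, n)));
    loss += (y[n] == 1) ? -std::log(p1) : -std::log(1.0 - p1);
  }
  loss /= N;

  mat dlogits = c.probs;
  for (int n = 0; n < N; ++n) dlogits(y[n], n) -= 1.0;
  dlogits /= (double)N;

  mat W4 = as<mat>(params["W4"]);
  mat W5 = as<mat>(params["W5"]);
  mat dW5 = dlogits * c.H1.t();
  vec db5 = arma::sum(dlogits, 1);
  mat dH1 = W5.t() * dlogits;
  if (dropout > 0.0) dH1 %= c.dropmask;
  dH1.elem(arma::find(c.H1relu <= 0.0)).zeros();
  mat dW4 = dH1 * c.F.t();
  vec db4 = arma::sum(dH1, 1);
  mat dF = W4.t() * dH1;

  // unflatten (C*P, N) -> (C, P*N)
  const int outC = as<mat>(params["W3"]).n_rows;
  const int P = c.gpool[2].oH * c.gpool[2].oH;
  mat dA(outC, (uword)P * N);
  for (int n = 0; n < N; ++n)
    dA.cols((uword)P * n, (uword)P * n + P - 1) =
      arma::reshape(dF.col(n), outC, P);

  List grads;
  grads["W5"] = dW5; grads["b5"] = db5;
  grads["W4"] = dW4; grads["b4"] = db4;
  for (int i = 2; i >= 0; --i) {
    mat dL;
    pool_bwd(dA, c.poolAM[i], N, c.gpool[i], dL);
    mat dY = lrn_bwd(dL, c.reluY[i], c.lrnD[i], lalpha, lbeta, ln);
    dY.elem(arma::find(c.reluY[i] <= 0.0)).zeros();  // ReLU backward
    std::string wi = "W" + std::to_string(i + 1), bi = "b" + std::to_string(i + 1);
    mat W = as<mat>(params[wi]);
    grads[wi] = mat(dY * c.col[i].t());
    grads[bi] = vec(arma::sum(dY, 1));
    if (i > 0) {
      mat dcol = W.t() * dY;
      col2im(dcol, N, c.gconv[i], dA);
    }
  }
  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["probs"] = wrap(mat(c.probs.t())));
}

// Exposed for testing the network's internal LRN against an independent
// oracle: A has channels as rows.
// [[Rcpp::export]]
NumericMatrix cpp_lrn(NumericMatrix A, double k, double alpha, double beta, int n) {
  mat Aa(A.begin(), A.nrow(), A.ncol(), false, true);
  mat D;
  return wrap(lrn_fwd(Aa, k, alpha, beta, n, D));
}
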