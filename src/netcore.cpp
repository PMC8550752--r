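// Core dynamics of the recurrent hub-and-spokes network.
//
// Units use a continuous-time sigmoidal activation with time constant tau:
//   a <- a + tau * (sigmoid(net) - a)
// updated asynchronously, each unit visited once per sweep in a freshly
// permuted order shared across the pattern batch, always reading the latest
// values of all other units. The backward pass replays the identical
// permuted sequence so gradients are exact for the dynamics actually run.
//
// Layout: activations A, external input EXT and targets TGT are stored as
// nunits columns of npat contiguous doubles (pattern index fastest), so the
// per-unit inner loops are simple contiguous axpy/dot operations.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <random>
#include <vector>

using namespace Rcpp;

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

namespace {

struct Net {
  int nunits = 0, npat = 0;
  std::vector<int> lay_off, lay_size;
  std::vector<int> cfrom, cto, woff;  // per directed connection (0-based layers)
  std::vector<int> in_src, in_w;       // CSR incoming edges
  std::vector<int> in_ptr;             // per-unit offsets into in_src/in_w
  std::vector<char> is_io;             // unit belongs to an input/output layer
  std::vector<char> bias_trainable;    // hidden-layer biases only

  void build(const IntegerVector& layer_sizes, const IntegerVector& conn_from,
             const IntegerVector& conn_to, const IntegerVector& io_layers) {
    int nlay = layer_sizes.size();
    lay_size.assign(layer_sizes.begin(), layer_sizes.end());
    lay_off.resize(nlay);
    nunits = 0;
    for (int l = 0; l < nlay; ++l) { lay_off[l] = nunits; nunits += lay_size[l]; }
    is_io.assign(nunits, 0);
    bias_trainable.assign(nunits, 1);
    for (int k = 0; k < io_layers.size(); ++k) {
      int l = io_layers[k] - 1;
      for (int u = lay_off[l]; u < lay_off[l] + lay_size[l]; ++u) {
        is_io[u] = 1;
        bias_trainable[u] = 0;  // I/O biases fixed at -3, untrainable
      }
    }
    int nc = conn_from.size();
    cfrom.resize(nc); cto.resize(nc); woff.resize(nc);
    std::vector<std::vector<int>> tsrc(nunits), tw(nunits);
    int off = 0;
    for (int c = 0; c < nc; ++c) {
      cfrom[c] = conn_from[c] - 1;
      cto[c] = conn_to[c] - 1;
      woff[c] = off;
      int nt = lay_size[cto[c]], nf = lay_size[cfrom[c]];
      for (int jl = 0; jl < nf; ++jl) {
        int j = lay_off[cfrom[c]] + jl;
        for (int ul = 0; ul < nt; ++ul) {
          int u = lay_off[cto[c]] + ul;
          tsrc[u].push_back(j);
          tw[u].push_back(off + ul + nt * jl);  // column-major (to x from)
        }
      }
      off += nt * nf;
    }
    nweights = off;
    in_ptr.assign(nunits + 1, 0);
    for (int u = 0; u < nunits; ++u) in_ptr[u + 1] = in_ptr[u] + (int)tsrc[u].size();
    in_src.resize(in_ptr[nunits]); in_w.resize(in_ptr[nunits]);
    for (int u = 0; u < nunits; ++u) {
      std::copy(tsrc[u].begin(), tsrc[u].end(), in_src.begin() + in_ptr[u]);
      std::copy(tw[u].begin(), tw[u].end(), in_w.begin() + in_ptr[u]);
    }
  }
  int nweights = 0;
};

// One full forward settle over the batch, storing per-sweep snapshots and
// per-unit sigmoid outputs for the backward pass.
struct ForwardLog {
  int sweeps_run = 0;
  std::vector<double> snaps;   // (S+1) frames of nunits*npat (frame 0 = initial)
  std::vector<double> sg;      // sigmoid(net) per sweep, unit, pattern
  std::vector<int> perms;      // S * nunits
  std::vector<int> pos;        // S * nunits inverse permutation
  std::vector<int> stop_sweep; // per pattern; S if never stopped early
  std::vector<double> A, netv;  // reusable work buffers
};

void forward(const Net& net, const double* W, const double* bias,
             const double* ext, const double* tgt, bool have_tgt,
             double tau, int S, double stop_tol, std::mt19937& rng,
             ForwardLog& fl) {
  const int nu = net.nunits, np = net.npat;
  const size_t fsz = (size_t)nu * np;
  if (fl.snaps.size() < (size_t)(S + 1) * fsz) fl.snaps.resize((size_t)(S + 1) * fsz);
  if (fl.sg.size() < (size_t)S * fsz) fl.sg.resize((size_t)S * fsz);
  if (fl.perms.size() < (size_t)S * nu) { fl.perms.resize((size_t)S * nu); fl.pos.resize((size_t)S * nu); }
  fl.stop_sweep.assign(np, S);

  if (fl.A.size() < fsz) { fl.A.resize(fsz); fl.netv.resize(np); }
  std::vector<double>& A = fl.A;
  std::vector<double>& netv = fl.netv;
  // initial state: resting activation sigmoid(bias) for every unit
  for (int u = 0; u < nu; ++u) {
    double a0 = sigm(bias[u]);
    double* au = A.data() + (size_t)u * np;
    for (int p = 0; p < np; ++p) au[p] = a0;
  }
  std::memcpy(fl.snaps.data(), A.data(), fsz * sizeof(double));

  std::vector<char> stopped(np, 0);
  int n_stopped = 0;
  std::vector<int> perm(nu);
  for (int u = 0; u < nu; ++u) perm[u] = u;

  int s;
  for (s = 0; s < S; ++s) {
    // fresh permutation each sweep, shared across patterns
    for (int i = nu - 1; i > 0; --i) {
      std::uniform_int_distribution<int> d(0, i);
      std::swap(perm[i], perm[d(rng)]);
    }
    int* ps = fl.perms.data() + (size_t)s * nu;
    int* qs = fl.pos.data() + (size_t)s * nu;
    for (int i = 0; i < nu; ++i) { ps[i] = perm[i]; qs[perm[i]] = i; }

    for (int i = 0; i < nu; ++i) {
      const int u = perm[i];
      const double bu = bias[u];
      const double* __restrict exu = ext + (size_t)u * np;
      double* __restrict nv = netv.data();
      for (int p = 0; p < np; ++p) nv[p] = bu + exu[p];
      for (int k = net.in_ptr[u]; k < net.in_ptr[u + 1]; ++k) {
        const double w = W[net.in_w[k]];
        const double* __restrict aj = A.data() + (size_t)net.in_src[k] * np;
        for (int p = 0; p < np; ++p) nv[p] += w * aj[p];
      }
      double* __restrict au = A.data() + (size_t)u * np;
      double* __restrict su = fl.sg.data() + ((size_t)s * nu + u) * np;
      for (int p = 0; p < np; ++p) {
        double sg = sigm(nv[p]);
        su[p] = sg;
        au[p] += tau * (sg - au[p]);
      }
    }
    std::memcpy(fl.snaps.data() + (size_t)(s + 1) * fsz, A.data(),
                fsz * sizeof(double));

    if (have_tgt && stop_tol > 0) {
      for (int p = 0; p < np; ++p) {
        if (stopped[p]) continue;
        bool ok = true;
        for (int u = 0; u < nu && ok; ++u) {
          if (!net.is_io[u]) continue;
          double t = tgt[(size_t)u * np + p];
          if (std::fabs(A[(size_t)u * np + p] - t) > stop_tol) ok = false;
        }
        if (ok) { stopped[p] = 1; fl.stop_sweep[p] = s + 1; ++n_stopped; }
      }
      if (n_stopped == np) { ++s; break; }
    }
  }
  fl.sweeps_run = s;
}

// Squared-error loss over all logged frames (0..stop_sweep per pattern):
//   L = loss_scale * sum (a - t)^2 over I/O units.
double loss_of(const Net& net, const ForwardLog& fl, const double* tgt,
               double loss_scale) {
  const int nu = net.nunits, np = net.npat;
  const size_t fsz = (size_t)nu * np;
  double L = 0.0;
  for (int s = 0; s <= fl.sweeps_run; ++s) {
    const double* fr = fl.snaps.data() + (size_t)s * fsz;
    for (int u = 0; u < nu; ++u) {
      if (!net.is_io[u]) continue;
      const double* au = fr + (size_t)u * np;
      const double* tu = tgt + (size_t)u * np;
      for (int p = 0; p < np; ++p) {
        if (s > fl.stop_sweep[p]) continue;
        double d = au[p] - tu[p];
        L += d * d;
      }
    }
  }
  return loss_scale * L;
}

// Exact backward pass through the recorded asynchronous sequence.
void backward(const Net& net, const ForwardLog& fl, const double* W,
              const double* bias, const double* tgt, double tau,
              double loss_scale, double* dW, double* dbias) {
  const int nu = net.nunits, np = net.npat;
  const size_t fsz = (size_t)nu * np;
  std::vector<double> dA(fsz, 0.0), dnet(np);
  const double esc = 2.0 * loss_scale;

  for (int s = fl.sweeps_run; s >= 1; --s) {
    // inject frame-s error for patterns still settling at sweep s
    const double* fr = fl.snaps.data() + (size_t)s * fsz;
    for (int u = 0; u < nu; ++u) {
      if (!net.is_io[u]) continue;
      const double* au = fr + (size_t)u * np;
      const double* tu = tgt + (size_t)u * np;
      double* du = dA.data() + (size_t)u * np;
      for (int p = 0; p < np; ++p)
        if (s <= fl.stop_sweep[p]) du[p] += esc * (au[p] - tu[p]);
    }
    const int* perm = fl.perms.data() + (size_t)(s - 1) * nu;
    const int* pos = fl.pos.data() + (size_t)(s - 1) * nu;
    const double* snap_cur = fl.snaps.data() + (size_t)s * fsz;
    const double* snap_prev = fl.snaps.data() + (size_t)(s - 1) * fsz;
    for (int i = nu - 1; i >= 0; --i) {
      const int u = perm[i];
      double* __restrict du = dA.data() + (size_t)u * np;
      const double* __restrict su = fl.sg.data() + ((size_t)(s - 1) * nu + u) * np;
      double* __restrict dn = dnet.data();
      double dbu = 0.0;
      for (int p = 0; p < np; ++p) {
        double g = du[p];
        double d = g * tau * su[p] * (1.0 - su[p]);
        dn[p] = d;
        du[p] = g * (1.0 - tau);
        dbu += d;
      }
      if (net.bias_trainable[u]) dbias[u] += dbu;
      for (int k = net.in_ptr[u]; k < net.in_ptr[u + 1]; ++k) {
        const int j = net.in_src[k];
        // value of unit j at the moment u was updated in sweep s
        const double* __restrict aj =
            (pos[j] < i ? snap_cur : snap_prev) + (size_t)j * np;
        const double w = W[net.in_w[k]];
        double* __restrict dj = dA.data() + (size_t)j * np;
        double acc = 0.0;
        for (int p = 0; p < np; ++p) acc += dn[p] * aj[p];
        for (int p = 0; p < np; ++p) dj[p] += w * dn[p];
        dW[net.in_w[k]] += acc;
      }
    }
  }
  // gradient through the initial state a0 = sigmoid(bias)
  for (int u = 0; u < nu; ++u) {
    if (!net.bias_trainable[u]) continue;
    double s0 = sigm(bias[u]);
    const double* du = dA.data() + (size_t)u * np;
    double acc = 0.0;
    for (int p = 0; p < np; ++p) acc += du[p];
    dbias[u] += acc * s0 * (1.0 - s0);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_settle(IntegerVector layer_sizes, IntegerVector conn_from,
                IntegerVector conn_to, IntegerVector io_layers,
                NumericVector W, NumericVector bias, NumericMatrix ext,
                Nullable<NumericMatrix> targets, double tau, int n_sweeps,
                double stop_tol, int seed, IntegerVector record_units) {
  Net net;
  net.build(layer_sizes, conn_from, conn_to, io_layers);
  net.npat = ext.nrow();
  if (ext.ncol() != net.nunits) stop("ext must be npat x nunits");
  if (W.size() != net.nweights) stop("weight vector has wrong length");

  // transpose ext to unit-column layout
  const int np = net.npat, nu = net.nunits;
  std::vector<double> extT((size_t)nu * np), tgtT;
  for (int u = 0; u < nu; ++u)
    for (int p = 0; p < np; ++p) extT[(size_t)u * np + p] = ext(p, u);
  bool have_tgt = targets.isNotNull();
  if (have_tgt) {
    NumericMatrix tg(targets);
    if (tg.nrow() != np || tg.ncol() != nu) stop("targets must be npat x nunits");
    tgtT.resize((size_t)nu * np);
    for (int u = 0; u < nu; ++u)
      for (int p = 0; p < np; ++p) tgtT[(size_t)u * np + p] = tg(p, u);
  }

  std::mt19937 rng(seed);
  ForwardLog fl;
  forward(net, W.begin(), bias.begin(), extT.data(),
          have_tgt ? tgtT.data() : nullptr, have_tgt, tau, n_sweeps,
          have_tgt ? stop_tol : -1.0, rng, fl);

  for (double v : fl.snaps)
    if (!std::isfinite(v)) stop("non-finite activation during settling");

  const int nrec = record_units.size();
  const int nframes = fl.sweeps_run + 1;
  NumericVector out((size_t)np * nrec * nframes);
  const size_t fsz = (size_t)nu * np;
  for (int f = 0; f < nframes; ++f)
    for (int r = 0; r < nrec; ++r) {
      int u = record_units[r] - 1;
      const double* au = fl.snaps.data() + (size_t)f * fsz + (size_t)u * np;
      for (int p = 0; p < np; ++p)
        out[(size_t)f * np * nrec + (size_t)r * np + p] = au[p];
    }
  out.attr("dim") = IntegerVector::create(np, nrec, nframes);
  return List::create(_["activations"] = out,
                      _["sweeps_run"] = fl.sweeps_run,
                      _["stop_sweep"] = IntegerVector(fl.stop_sweep.begin(),
                                                      fl.stop_sweep.end()));
}

// [[Rcpp::export]]
List cpp_loss_grad(IntegerVector layer_sizes, IntegerVector conn_from,
                   IntegerVector conn_to, IntegerVector io_layers,
                   NumericVector W, NumericVector bias, NumericMatrix ext,
                   NumericMatrix targets, double tau, int n_sweeps,
                   double stop_tol, int seed, double loss_scale) {
  Net net;
  net.build(layer_sizes, conn_from, conn_to, io_layers);
  net.npat = ext.nrow();
  const int np = net.npat, nu = net.nunits;
  std::vector<double> extT((size_t)nu * np), tgtT((size_t)nu * np);
  for (int u = 0; u < nu; ++u)
    for (int p = 0; p < np; ++p) {
      extT[(size_t)u * np + p] = ext(p, u);
      tgtT[(size_t)u * np + p] = targets(p, u);
    }
  std::mt19937 rng(seed);
  ForwardLog fl;
  forward(net, W.begin(), bias.begin(), extT.data(), tgtT.data(), true, tau,
          n_sweeps, stop_tol, rng, fl);
  double L = loss_of(net, fl, tgtT.data(), loss_scale);
  NumericVector dW(net.nweights), dbias(nu);
  backward(net, fl, W.begin(), bias.begin(), tgtT.data(), tau, loss_scale,
           dW.begin(), dbias.begin());
  return List::create(_["loss"] = L, _["dW"] = dW, _["dbias"] = dbias,
                      _["sweeps_run"] = fl.sweeps_run);
}

// [[Rcpp::export]]
List cpp_train(IntegerVector layer_sizes, IntegerVector conn_from,
               IntegerVector conn_to, IntegerVector io_layers,
               NumericVector W, NumericVector bias, NumericMatrix ext,
               NumericMatrix targets, double tau, int n_sweeps,
               double stop_tol, int seed, double loss_scale, int epochs,
               double lr, double momentum) {
  Net net;
  net.build(layer_sizes, conn_from, conn_to, io_layers);
  net.npat = ext.nrow();
  const int np = net.npat, nu = net.nunits;
  std::vector<double> extT((size_t)nu * np), tgtT((size_t)nu * np);
  for (int u = 0; u < nu; ++u)
    for (int p = 0; p < np; ++p) {
      extT[(size_t)u * np + p] = ext(p, u);
      tgtT[(size_t)u * np + p] = targets(p, u);
    }
  std::vector<double> Wv(W.begin(), W.end()), bv(bias.begin(), bias.end());
  std::vector<double> dW(net.nweights), db(nu);
  std::vector<double> vW(net.nweights, 0.0), vb(nu, 0.0);
  NumericVector losses(epochs);
  std::mt19937 rng(seed);
  ForwardLog fl;
  for (int e = 0; e < epochs; ++e) {
    forward(net, Wv.data(), bv.data(), extT.data(), tgtT.data(), true, tau,
            n_sweeps, stop_tol, rng, fl);
    double L = loss_of(net, fl, tgtT.data(), loss_scale);
    losses[e] = L;
    if (!std::isfinite(L)) stop("training loss diverged (non-finite) at epoch %d", e + 1);
    std::fill(dW.begin(), dW.end(), 0.0);
    std::fill(db.begin(), db.end(), 0.0);
    backward(net, fl, Wv.data(), bv.data(), tgtT.data(), tau, loss_scale,
             dW.data(), db.data());
    for (int k = 0; k < net.nweights; ++k) {
      vW[k] = momentum * vW[k] - lr * dW[k];
      Wv[k] += vW[k];
    }
    for (int u = 0; u < nu; ++u)
      if (net.bias_trainable[u]) { vb[u] = momentum * vb[u] - lr * db[u]; bv[u] += vb[u]; }
    if ((e & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["W"] = NumericVector(Wv.begin(), Wv.end()),
                      _["bias"] = NumericVector(bv.begin(), bv.end()),
                      _["loss"] = losses);
}
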