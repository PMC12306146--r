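#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// xoshiro256++ (public domain construction), seeded via splitmix64.
// Used instead of R's RNG so that spike tensors are reproducible from a single
// integer seed independently of R's RNG state, and cheap enough to draw the
// ~3e8 Bernoulli variates per training epoch.
struct Xoshiro {
  uint64_t s0, s1, s2, s3;
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (uint64_t* p : {&s0, &s1, &s2, &s3}) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t ^= t >> 30; t *= 0xbf58476d1ce4e5b9ULL;
      t ^= t >> 27; t *= 0x94d049bb133111ebULL;
      t ^= t >> 31;
      *p = t;
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s0 + s3, 23) + s0;
    const uint64_t t = s1 << 17;
    s2 ^= s0; s3 ^= s1; s1 ^= s2; s0 ^= s3; s2 ^= t;
    s3 = rotl(s3, 45);
    return result;
  }
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

inline arma::mat row_softmax(const arma::mat& v) {
  arma::vec m = arma::max(v, 1);
  arma::mat e = arma::exp(v.each_col() - m);
  arma::vec s = arma::sum(e, 1);
  e.each_col() /= s;
  return e;
}

// Spike generation into a pre-allocated (B*T) x C matrix (column-major, row
// index b + t*B), which is the same memory layout as a (B, T, C) cube.
void gen_spikes_mat(arma::mat& X, const arma::vec& ipd, double f,
                    const arma::vec& psi, double rate_max, double dt,
                    int n_bins, uint64_t seed) {
  const int B = ipd.n_elem, n_psi = psi.n_elem;
  Xoshiro rng(seed);
  arma::vec sphi(n_bins), cphi(n_bins), sc(B), cc(B);
  for (int t = 0; t < n_bins; ++t) {
    const double ph = 2.0 * M_PI * f * t * dt;
    sphi[t] = std::sin(ph);
    cphi[t] = std::cos(ph);
  }
  const double pmax = rate_max * dt;
  for (int ear = 0; ear < 2; ++ear) {
    for (int j = 0; j < n_psi; ++j) {
      const int ch = ear * n_psi + j;
      for (int b = 0; b < B; ++b) {
        const double cj = (ear == 1 ? ipd[b] : 0.0) + psi[j];
        sc[b] = std::sin(cj);
        cc[b] = std::cos(cj);
      }
      double* col = X.colptr(ch);
      for (int t = 0; t < n_bins; ++t) {
        const double sp = sphi[t], cp = cphi[t];
        double* out = col + static_cast<size_t>(t) * B;
        for (int b = 0; b < B; ++b) {
          // sin(2*pi*f*t*dt + off_b + psi_j), expanded to avoid per-bin sin()
          const double q = 0.5 * (1.0 + sp * cc[b] + cp * sc[b]);
          out[b] = (rng.unif() < pmax * q * q) ? 1.0 : 0.0;
        }
      }
    }
  }
}

}  // namespace

// Poisson (per-bin Bernoulli) spike batch for the binaural IPD task.
// Channel layout: [ear0 neurons 0..n_psi-1, ear1 neurons 0..n_psi-1]; ear 1
// carries the IPD alpha. Returned cube has dims (trials, bins, channels).
// [[Rcpp::export]]
arma::cube cpp_spike_batch(const arma::vec& ipd, double f, const arma::vec& psi,
                           double rate_max, double dt, int n_bins, double seed) {
  const int B = ipd.n_elem;
  const int C = 2 * static_cast<int>(psi.n_elem);
  arma::cube X(B, n_bins, C);
  arma::mat alias(X.memptr(), static_cast<size_t>(B) * n_bins, C, false, true);
  gen_spikes_mat(alias, ipd, f, psi, rate_max, dt, n_bins,
                 static_cast<uint64_t>(seed));
  return X;
}

// Deterministic rate tensor R_ij(t) = rate_max * ((1 + sin theta)/2)^2 for one
// IPD; dims (bins, channels). Shared with the rate-based analysis path.
// [[Rcpp::export]]
arma::mat cpp_input_rates(double ipd, double f, const arma::vec& psi,
                          double rate_max, double dt, int n_bins) {
  const int n_psi = psi.n_elem;
  arma::mat R(n_bins, 2 * n_psi);
  for (int ear = 0; ear < 2; ++ear) {
    const double off = (ear == 1) ? ipd : 0.0;
    for (int j = 0; j < n_psi; ++j) {
      for (int t = 0; t < n_bins; ++t) {
        const double th = 2.0 * M_PI * f * t * dt + off + psi[j];
        const double q = 0.5 * (1.0 + std::sin(th));
        R(t, ear * n_psi + j) = rate_max * q * q;
      }
    }
  }
  return R;
}

// Fused forward/backward pass through the LIF hidden layer + leaky non-spiking
// readout. `I` is the hidden input current as a (B*T) x Nh matrix with row
// index b + t*B (trial-major within each time block). Per step:
//   v <- v*exp(-dt/tau) + I_t ; s = step(v - 1) ; v <- v*(1 - s)
//   u <- u*exp(-dt/tau_o) + s*Who ; vbar = mean_t u
// Loss = cross-entropy(log_softmax(vbar), y) + firing-rate regularizer.
// Backward uses the fast-sigmoid surrogate derivative beta/(beta*|v-1|+1)^2 in
// place of the step, with the reset factor (1-s) treated as constant.
// When soft=true the step is replaced by the smooth sigmoid
// s = (1 + beta*x/(1+beta*|x|))/2 and the pass is exactly differentiable
// (reset included), which is what the finite-difference gradient checks use.
// [[Rcpp::export]]
List cpp_snn_pass(const arma::mat& I, int B, int T, const arma::mat& Who,
                  double tau_h, double tau_o, double dt, double beta,
                  const arma::ivec& y, double r_minus, double r_plus,
                  double c_reg, bool want_grad, bool want_spikes, bool soft) {
  const int Nh = I.n_cols;
  const int Nc = Who.n_cols;
  if (!I.is_finite() || !Who.is_finite())
    stop("non-finite values in network input or weights");
  const double a_h = std::exp(-dt / tau_h);
  const double a_o = std::exp(-dt / tau_o);
  const double duration = T * dt;

  arma::cube S(B, Nh, T), Vpre(B, Nh, T);
  arma::mat v(B, Nh, arma::fill::zeros);
  arma::mat u(B, Nc, arma::fill::zeros);
  arma::mat vbar(B, Nc, arma::fill::zeros);

  for (int t = 0; t < T; ++t) {
    v = a_h * v + I.rows(t * B, (t + 1) * B - 1);
    Vpre.slice(t) = v;
    arma::mat s(B, Nh);
    if (soft) {
      arma::mat x = v - 1.0;
      s = 0.5 * (1.0 + beta * x / (1.0 + beta * arma::abs(x)));
    } else {
      s = arma::conv_to<arma::mat>::from(v >= 1.0);
    }
    S.slice(t) = s;
    v = v % (1.0 - s);
    u = a_o * u + s * Who;
    vbar += u;
  }
  vbar /= T;

  // per-neuron batch-averaged firing rates (sp/s)
  arma::mat counts(B, Nh, arma::fill::zeros);
  for (int t = 0; t < T; ++t) counts += S.slice(t);
  arma::rowvec rates = arma::mean(counts, 0) / duration;

  double loss_ce = NA_REAL, loss_reg = 0.0;
  arma::rowvec Lm(Nh, arma::fill::zeros), dLm(Nh, arma::fill::zeros);
  const double denom = r_plus - r_minus;
  for (int m = 0; m < Nh; ++m) {
    if (rates[m] > r_minus) {
      const double z = (rates[m] - r_minus) / denom;
      Lm[m] = z * z;
      dLm[m] = 2.0 * z / denom;
    }
  }
  loss_reg = c_reg * arma::accu(Lm) / Nh;

  const bool have_y = (static_cast<int>(y.n_elem) == B);
  arma::mat g;  // dL_ce/dvbar
  if (have_y) {
    arma::mat p = row_softmax(vbar);
    double acc = 0.0;
    for (int b = 0; b < B; ++b) {
      const int k = y[b];
      acc += std::log(std::max(p(b, k), 1e-300));
    }
    loss_ce = -acc / B;
    g = p / B;
    for (int b = 0; b < B; ++b) g(b, y[b]) -= 1.0 / B;
  }

  List out = List::create(
      _["vbar"] = vbar, _["loss_ce"] = loss_ce, _["loss_reg"] = loss_reg,
      _["rates"] = arma::vec(rates.t()), _["counts"] = counts);
  if (want_spikes) out["spikes"] = S;  // dims (B, Nh, T)

  if (want_grad && have_y) {
    // dL_reg/ds is constant over (b, t) for each neuron
    arma::rowvec reg_ds = (c_reg / Nh) * dLm / (B * duration);
    arma::mat lam(B, Nc, arma::fill::zeros);
    arma::mat dWho(Nh, Nc, arma::fill::zeros);
    arma::mat dnext(B, Nh, arma::fill::zeros);  // dL/dv_pre(t+1)
    arma::mat dI(B * T, Nh);
    for (int t = T - 1; t >= 0; --t) {
      lam = g / T + a_o * lam;
      const arma::mat& s = S.slice(t);
      const arma::mat& vp = Vpre.slice(t);
      dWho += s.t() * lam;
      arma::mat ds = lam * Who.t();
      ds.each_row() += reg_ds;
      arma::mat dpost = a_h * dnext;
      arma::mat x = vp - 1.0;
      arma::mat sder;
      if (soft) {
        arma::mat q = 1.0 + beta * arma::abs(x);
        sder = 0.5 * beta / (q % q);
      } else {
        arma::mat q = beta * arma::abs(x) + 1.0;
        sder = beta / (q % q);
      }
      arma::mat dpre = ds % sder + dpost % (1.0 - s);
      if (soft) dpre -= (dpost % vp) % sder;  // reset path through s
      dI.rows(t * B, (t + 1) * B - 1) = dpre;
      dnext = dpre;
    }
    out["dI"] = dI;
    out["dWho"] = dWho;
  }
  return out;
}

namespace {
// Normalized Gaussian interpolation kernel over integer lags 0..D-1 for one
// synapse: taps within 4*sigma of the (clamped) position, rescaled so the taps
// sum to 1. Writes taps into g (length D, zeroed first); returns sum of raw
// Gaussian for the derivative computation via dgdp.
void dcls_kernel(double p, double sigma, int D, arma::vec& g) {
  g.zeros();
  const double pc = std::min(std::max(p, 0.0), static_cast<double>(D - 1));
  const int lo = std::max(0, static_cast<int>(std::floor(pc - 4.0 * sigma)));
  const int hi = std::min(D - 1, static_cast<int>(std::ceil(pc + 4.0 * sigma)));
  double tot = 0.0;
  for (int d = lo; d <= hi; ++d) {
    const double z = (d - pc) / sigma;
    g[d] = std::exp(-0.5 * z * z);
    tot += g[d];
  }
  if (tot <= 0.0) { g[static_cast<int>(std::round(pc))] = 1.0; tot = 1.0; }
  g /= tot;
}
}  // namespace

// Temporal convolution whose per-synapse kernel is a single continuously
// positioned element (training mode: Gaussian interpolation bump of width
// sigma; inference mode: one tap at round(position)). X is (B*T) x Nin with
// the same row layout as cpp_snn_pass; returns I = (B*T) x Nh.
// [[Rcpp::export]]
arma::mat cpp_dcls_conv(const arma::mat& X, int B, int T, const arma::mat& w,
                        const arma::mat& pos, double sigma, int D,
                        bool inference) {
  const int Nin = w.n_rows, Nh = w.n_cols;
  arma::mat I(B * T, Nh, arma::fill::zeros);
  // effective kernel K_d (Nin x Nh) per integer lag d
  arma::cube K(Nin, Nh, D, arma::fill::zeros);
  arma::vec g(D);
  for (int i = 0; i < Nin; ++i) {
    for (int h = 0; h < Nh; ++h) {
      if (inference) {
        const double pc = std::min(std::max(pos(i, h), 0.0),
                                   static_cast<double>(D - 1));
        K(i, h, static_cast<int>(std::round(pc))) += w(i, h);
      } else {
        dcls_kernel(pos(i, h), sigma, D, g);
        for (int d = 0; d < D; ++d)
          if (g[d] != 0.0) K(i, h, d) = w(i, h) * g[d];
      }
    }
  }
  for (int d = 0; d < D; ++d) {
    if (!arma::any(arma::vectorise(K.slice(d)) != 0.0)) continue;
    arma::mat Cd = X.rows(0, (T - d) * B - 1) * K.slice(d);
    I.rows(d * B, T * B - 1) += Cd;
  }
  return I;
}

// Gradient of the DCLS convolution wrt per-synapse weight and position,
// given dL/dI. The kernel is the weight-scaled normalized Gaussian, so
// d k_d / dp = k_d * ((d-p)/sigma^2 - sum_e ghat_e (e-p)/sigma^2).
// [[Rcpp::export]]
List cpp_dcls_conv_grad(const arma::mat& X, int B, int T, const arma::mat& dI,
                        const arma::mat& w, const arma::mat& pos, double sigma,
                        int D) {
  const int Nin = w.n_rows, Nh = w.n_cols;
  arma::cube dK(Nin, Nh, D, arma::fill::zeros);
  for (int d = 0; d < D; ++d) {
    dK.slice(d) = X.rows(0, (T - d) * B - 1).t() * dI.rows(d * B, T * B - 1);
  }
  arma::mat dw(Nin, Nh, arma::fill::zeros), dpos(Nin, Nh, arma::fill::zeros);
  arma::vec g(D);
  const double inv_s2 = 1.0 / (sigma * sigma);
  for (int i = 0; i < Nin; ++i) {
    for (int h = 0; h < Nh; ++h) {
      const double pc = std::min(std::max(pos(i, h), 0.0),
                                 static_cast<double>(D - 1));
      dcls_kernel(pos(i, h), sigma, D, g);
      double mu = 0.0;  // sum_e ghat_e * (e - p)/sigma^2
      for (int d = 0; d < D; ++d)
        if (g[d] != 0.0) mu += g[d] * (d - pc) * inv_s2;
      double gw = 0.0, gp = 0.0;
      for (int d = 0; d < D; ++d) {
        if (g[d] == 0.0 && dK(i, h, d) == 0.0) continue;
        gw += dK(i, h, d) * g[d];
        gp += dK(i, h, d) * w(i, h) * g[d] * ((d - pc) * inv_s2 - mu);
      }
      dw(i, h) = gw;
      dpos(i, h) = gp;
    }
  }
  return List::create(_["dw"] = dw, _["dpos"] = dpos);
}

// Uniform variates from the package's counter-based stream (used by the
// R-level samplers so that every stochastic stage keys off one integer seed).
// [[Rcpp::export]]
arma::vec cpp_runif_stream(int n, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  arma::vec out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.unif();
  return out;
}

// Fused training/evaluation batch for the base model: generates the spike
// tensor, computes hidden currents I = X * Wih, runs the LIF + readout pass
// (hard threshold, surrogate backward), and returns the loss pieces plus
// gradients wrt both weight matrices. Keeping the 20 MB spike tensor on the
// C++ side avoids two full copies per batch.
// [[Rcpp::export]]
List cpp_train_batch(const arma::vec& ipd, double f, const arma::vec& psi,
                     double rate_max, double dt, int n_bins, double seed,
                     const arma::mat& Wih, const arma::mat& Who, double tau_h,
                     double tau_o, double beta, const arma::ivec& y,
                     double r_minus, double r_plus, double c_reg,
                     bool want_grad) {
  const int B = ipd.n_elem;
  const int C = 2 * psi.n_elem;
  arma::mat X(B * n_bins, C);
  gen_spikes_mat(X, ipd, f, psi, rate_max, dt, n_bins,
                 static_cast<uint64_t>(seed));
  arma::mat I = X * Wih;
  List res = cpp_snn_pass(I, B, n_bins, Who, tau_h, tau_o, dt, beta, y,
                          r_minus, r_plus, c_reg, want_grad, false, false);
  if (want_grad && static_cast<int>(y.n_elem) == B) {
    arma::mat dI = res["dI"];
    res["dWih"] = arma::mat(X.t() * dI);
    res["dI"] = R_NilValue;
  }
  return res;
}
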