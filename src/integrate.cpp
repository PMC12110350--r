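#include <Rcpp.h>
using namespace Rcpp;

// Coupled excitatory/inhibitory populations with calcium-gated astrocytic
// glutamate feedback, integrated on a fixed output grid of `nst` steps of
// size `dt`.  Within each output step the state advances in `n_sub` equal
// substeps: Ex, Glu and h by forward Euler, In by an exact exponential
// relaxation update toward its instantaneous steady state.  The stimulus is
// held constant across the substeps of one output step, matching a sample-
// and-hold device driven at the output rate.
//
// Per-node equations (f = logistic with base eps):
//   dEx/dt  = tau_ex*(h_ex - Ex + C1 f[Ex] - C2 f[In]
//             + c_net * sum_j a_ij f[Ex_j] + Cu f[I_astro]) + S(t)
//   I_astro = 10 lambda [Glu]
//   dIn/dt  = (h_in - In + C3 Ex) / tau_in
//   Ca      = k_ca f[Ex];  Z = max(0, Ca - ca_th)
//   dGlu/dt = (-Glu + Z - kappa h) / mu
//   dh/dt   = (-h + Glu) / eta
//
// Inactive (resected) nodes are frozen at zero and contribute nothing.

static inline double sig_eps(double x, double logeps) {
  return 1.0 / (1.0 + std::exp(-logeps * x));
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix A, List pars, NumericMatrix S,
              LogicalVector active, NumericVector init_ex,
              NumericVector init_in, NumericVector init_glu,
              NumericVector init_h, int nst, double dt, int n_sub,
              double eps) {
  const int N = A.nrow();
  NumericVector tau_ex = pars["tau_ex"], tau_in = pars["tau_in"];
  NumericVector h_ex = pars["h_ex"], h_in = pars["h_in"];
  NumericVector C1 = pars["C1"], C2 = pars["C2"], C3 = pars["C3"],
                Cu = pars["Cu"];
  NumericVector lambda_a = pars["lambda_a"], k_ca = pars["k_ca"],
                ca_th = pars["ca_th"], kappa = pars["kappa"],
                mu_glu = pars["mu_glu"], eta_h = pars["eta_h"],
                c_net = pars["c_net"];

  const double logeps = std::log(eps);
  const double dts = dt / n_sub;

  std::vector<double> Ex(init_ex.begin(), init_ex.end());
  std::vector<double> In(init_in.begin(), init_in.end());
  std::vector<double> Glu(init_glu.begin(), init_glu.end());
  std::vector<double> h(init_h.begin(), init_h.end());
  std::vector<double> fE(N);
  std::vector<double> a_in(N);
  for (int i = 0; i < N; ++i) {
    a_in[i] = std::exp(-dts / tau_in[i]);
    if (!active[i]) Ex[i] = In[i] = Glu[i] = h[i] = 0.0;
  }

  NumericMatrix oE(nst + 1, N), oI(nst + 1, N), oG(nst + 1, N),
      oH(nst + 1, N);
  for (int i = 0; i < N; ++i) {
    oE(0, i) = Ex[i]; oI(0, i) = In[i]; oG(0, i) = Glu[i]; oH(0, i) = h[i];
  }

  // adjacency as per-node neighbour lists (sparse; degrees are small)
  std::vector<std::vector<int>> nb(N);
  for (int i = 0; i < N; ++i) {
    if (!active[i]) continue;
    for (int j = 0; j < N; ++j)
      if (active[j] && A(i, j) != 0.0) nb[i].push_back(j);
  }

  for (int s = 0; s < nst; ++s) {
    for (int ss = 0; ss < n_sub; ++ss) {
      for (int i = 0; i < N; ++i) fE[i] = sig_eps(Ex[i], logeps);
      for (int i = 0; i < N; ++i) {
        if (!active[i]) continue;
        double in_inf = h_in[i] + C3[i] * Ex[i];
        In[i] = in_inf + (In[i] - in_inf) * a_in[i];
        double coup = 0.0;
        for (size_t q = 0; q < nb[i].size(); ++q) coup += fE[nb[i][q]];
        double iastro = 10.0 * lambda_a[i] * Glu[i];
        double dE = tau_ex[i] * (h_ex[i] - Ex[i] + C1[i] * fE[i] -
                                 C2[i] * sig_eps(In[i], logeps) +
                                 c_net[i] * coup +
                                 Cu[i] * sig_eps(iastro, logeps)) +
                    S(s, i);
        double Z = k_ca[i] * fE[i] - ca_th[i];
        if (Z < 0.0) Z = 0.0;
        double dG = (-Glu[i] + Z - kappa[i] * h[i]) / mu_glu[i];
        double dH = (-h[i] + Glu[i]) / eta_h[i];
        Ex[i] += dts * dE;
        Glu[i] += dts * dG;
        h[i] += dts * dH;
      }
    }
    bool bad = false;
    for (int i = 0; i < N; ++i) {
      oE(s + 1, i) = Ex[i]; oI(s + 1, i) = In[i];
      oG(s + 1, i) = Glu[i]; oH(s + 1, i) = h[i];
      if (active[i] && !std::isfinite(Ex[i])) bad = true;
    }
    if (bad)
      stop("state became non-finite at step %d (t = %g)", s + 1,
           (s + 1) * dt);
  }
  return List::create(_["Ex"] = oE, _["In"] = oI, _["Glu"] = oG,
                      _["h"] = oH);
}
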