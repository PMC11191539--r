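#include <Rcpp.h>
using namespace Rcpp;

// One epoch of the coupled neural-mass network: transient_len settling
// samples plus epoch_len retained samples.  Must stay step-for-step
// identical to the R reference stepper step_network() (asserted in the test
// suite).  Noise is drawn from the R RNG, one N-vector per 2-ms sample,
// held fixed across integration substeps.  The activity-dependent
// degeneration update runs once per sample when enabled.
// [[Rcpp::export]]
List run_epoch_cpp(NumericMatrix adj, List par, List co, List state,
                   List syn, bool add_enabled) {
  const int n = adj.nrow();
  const double Pt = par["Pt"], noiselevel = par["noiselevel"],
               sigma0 = par["sigma0"], g = par["g"], q = par["q"],
               Vd1 = par["Vd1"], Vd2 = par["Vd2"], C1 = par["C1"],
               C2 = par["C2"], S = par["S"], d_eff = par["d_eff"],
               floorv = par["strength_floor"];
  const int substeps = par["substeps"], transient = par["transient_len"],
            retain = par["epoch_len"];
  const double K1 = co["K1"], K2 = co["K2"], d1a = co["d1a"],
               d1b = co["d1b"], d2a = co["d2a"], d2b = co["d2b"],
               h = co["h"];

  NumericVector u1 = clone(as<NumericVector>(state["u1"]));
  NumericVector v1 = clone(as<NumericVector>(state["v1"]));
  NumericVector u2 = clone(as<NumericVector>(state["u2"]));
  NumericVector v2 = clone(as<NumericVector>(state["v2"]));
  NumericVector u3 = clone(as<NumericVector>(state["u3"]));
  NumericVector v3 = clone(as<NumericVector>(state["v3"]));
  NumericVector E  = clone(as<NumericVector>(state["E"]));
  NumericVector I  = clone(as<NumericVector>(state["I"]));
  NumericVector Ve = clone(as<NumericVector>(state["Ve"]));
  NumericVector Vi = clone(as<NumericVector>(state["Vi"]));

  NumericVector s_ei = clone(as<NumericVector>(syn["s_ei"]));
  NumericVector s_ie = clone(as<NumericVector>(syn["s_ie"]));
  NumericVector s_thal = clone(as<NumericVector>(syn["s_thal"]));
  NumericVector s_edge = clone(as<NumericVector>(syn["s_edge"]));

  // rolling 20-sample excitatory rate window (ring buffer)
  NumericMatrix hist_in = syn["rate_history"];
  const int W = 20;
  NumericMatrix hist(n, W);
  int hlen = hist_in.ncol() < W ? hist_in.ncol() : W;
  for (int j = 0; j < hlen; ++j)
    for (int i = 0; i < n; ++i)
      hist(i, j) = hist_in(i, hist_in.ncol() - hlen + j);
  int hpos = hlen % W;  // next slot (valid when hlen == W: overwrite oldest)

  // compressed neighbor lists (the adjacency is sparse and symmetric)
  std::vector<int> nb_start(n + 1, 0), nb;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j)
      if (adj(j, i) != 0.0) nb.push_back(j);
    nb_start[i + 1] = (int)nb.size();
  }

  NumericMatrix signals(n, retain), e_rates(n, retain), i_rates(n, retain);
  std::vector<double> xe(n), wE(n);
  double *pu1 = u1.begin(), *pv1 = v1.begin(), *pu2 = u2.begin(),
         *pv2 = v2.begin(), *pu3 = u3.begin(), *pv3 = v3.begin(),
         *pE = E.begin(), *pI = I.begin(), *pVe = Ve.begin(),
         *pVi = Vi.begin();
  const int total = transient + retain;

  for (int t = 0; t < total; ++t) {
    NumericVector noise = rnorm(n);
    for (int i = 0; i < n; ++i) {
      double P = Pt + noiselevel * sigma0 * noise[i];
      xe[i] = P > 0.0 ? P : 0.0;
    }
    for (int s = 0; s < substeps; ++s) {
      for (int i = 0; i < n; ++i) wE[i] = s_edge[i] * pE[i];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = nb_start[i]; k < nb_start[i + 1]; ++k)
          acc += wE[nb[k]];
        double in_e = s_thal[i] * xe[i] + S * s_edge[i] * acc;
        pu1[i] = d1a * pu1[i] + in_e;
        pv1[i] = d1b * pv1[i] + in_e;
        double in_h = C2 * s_ie[i] * pI[i];
        pu2[i] = d2a * pu2[i] + in_h;
        pv2[i] = d2b * pv2[i] + in_h;
        double in_i = C1 * s_ei[i] * pE[i];
        pu3[i] = d1a * pu3[i] + in_i;
        pv3[i] = d1b * pv3[i] + in_i;
      }
      for (int i = 0; i < n; ++i) {
        pVe[i] = K1 * h * (pu1[i] - pv1[i]) - K2 * h * (pu2[i] - pv2[i]);
        pVi[i] = K1 * h * (pu3[i] - pv3[i]);
        if (!R_finite(pVe[i]) || !R_finite(pVi[i]))
          stop("numeric overflow in mass %d at sample %d", i + 1, t + 1);
        pE[i] = 2.0 * g / (1.0 + std::exp(q * (Vd1 - pVe[i])));
        pI[i] = 2.0 * g / (1.0 + std::exp(q * (Vd2 - pVi[i])));
      }
    }
    // per-sample rate history + degeneration
    for (int i = 0; i < n; ++i) hist(i, hpos) = E[i];
    hpos = (hpos + 1) % W;
    if (hlen < W) ++hlen;
    if (add_enabled && d_eff > 0.0) {
      for (int i = 0; i < n; ++i) {
        double mx = 0.0;
        for (int j = 0; j < hlen; ++j)
          if (hist(i, j) > mx) mx = hist(i, j);
        double loss = std::exp(-d_eff * mx);
        s_ei[i] = std::max(floorv, s_ei[i] * loss);
        s_ie[i] = std::max(floorv, s_ie[i] * loss);
        s_thal[i] = std::max(floorv, s_thal[i] * loss);
        s_edge[i] = std::max(floorv, s_edge[i] * loss);
      }
    }
    if (t >= transient) {
      int k = t - transient;
      for (int i = 0; i < n; ++i) {
        signals(i, k) = Ve[i];
        e_rates(i, k) = E[i];
        i_rates(i, k) = I[i];
      }
    }
  }

  // export history in chronological order
  NumericMatrix hist_out(n, hlen);
  for (int j = 0; j < hlen; ++j) {
    int src = (hlen == W) ? (hpos + j) % W : j;
    for (int i = 0; i < n; ++i) hist_out(i, j) = hist(i, src);
  }

  return List::create(
      _["signals"] = signals, _["e_rates"] = e_rates, _["i_rates"] = i_rates,
      _["state"] = List::create(_["u1"] = u1, _["v1"] = v1, _["u2"] = u2,
                                _["v2"] = v2, _["u3"] = u3, _["v3"] = v3,
                                _["E"] = E, _["I"] = I, _["Ve"] = Ve,
                                _["Vi"] = Vi),
      _["synapses"] = List::create(_["s_ei"] = s_ei, _["s_ie"] = s_ie,
                                   _["s_thal"] = s_thal,
                                   _["s_edge"] = s_edge,
                                   _["rate_history"] = hist_out));
}
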