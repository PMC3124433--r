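// Sparse Bayesian kernel regression: fast marginal-likelihood optimisation.
// Bases are added, deleted, or have their precision re-estimated one at a
// time, always choosing the action with the largest increase in the marginal
// likelihood; once the basis set is stable at the current noise level, the
// noise variance is re-estimated, and the two steps alternate to joint
// convergence.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::export]]
Rcpp::List rvm_fast_fit(const arma::mat& PHI, const arma::vec& t,
                        double sigma2_init, double tol, int max_iter,
                        bool update_sigma2, double beta_max_factor = 1e6) {
  const uword N = PHI.n_rows, Mall = PHI.n_cols;
  vec g(Mall);                       // squared column norms
  for (uword m = 0; m < Mall; ++m) g(m) = dot(PHI.col(m), PHI.col(m));
  const vec PHIt = PHI.t() * t;
  const double var_t = var(t);
  const double beta_max = beta_max_factor / std::max(var_t, 1e-300);
  double beta = 1.0 / std::max(sigma2_init, 1e-12);

  // initial basis: largest normalised projection onto the target
  uword m0 = 0; double best = -1.0;
  for (uword m = 0; m < Mall; ++m) {
    if (g(m) <= 0) continue;
    double v = PHIt(m) * PHIt(m) / g(m);
    if (v > best) { best = v; m0 = m; }
  }
  double denom0 = PHIt(m0) * PHIt(m0) / g(m0) - 1.0 / beta;
  double alpha0 = (denom0 > 1e-12) ? g(m0) / denom0 : 1.0;

  std::vector<uword> act;  act.push_back(m0);
  std::vector<double> alv; alv.push_back(alpha0);
  mat C(Mall, 1);                    // PHI' * Phi_A, one column per basis
  C.col(0) = PHI.t() * PHI.col(m0);

  mat Sigma;
  vec mu;
  std::vector<int> add_count(Mall, 0);  // guards against add/delete cycling
  std::vector<char> frozen(Mall, 0);    // bases with stagnant re-estimation
  std::vector<int> reest_count(Mall, 0);
  bool converged = false;
  double L_acc = 0.0;                // accumulated marginal-likelihood gain
  int it = 0;

  for (it = 0; it < max_iter; ++it) {
    const uword M = act.size();
    uvec ia(M); for (uword i = 0; i < M; ++i) ia(i) = act[i];
    vec alpha(M); for (uword i = 0; i < M; ++i) alpha(i) = alv[i];

    mat Gaa = C.rows(ia);            // Phi_A' Phi_A
    mat H = beta * Gaa; H.diag() += alpha;
    H = 0.5 * (H + H.t());
    bool ok = inv_sympd(Sigma, H);
    if (!ok) { Sigma = pinv(H); }
    vec tA = PHIt.elem(ia);
    mu = beta * (Sigma * tA);

    // sparsity/quality factors for every candidate basis
    mat W = C * Sigma;               // Mall x M
    vec S = beta * g - beta * beta * sum(W % C, 1);
    vec Q = beta * (PHIt - C * mu);

    std::vector<int> inact_pos(Mall, -1);
    for (uword i = 0; i < M; ++i) inact_pos[act[i]] = int(i);

    double best_dl = 0.0;
    int best_m = -1, best_kind = 0;   // 1 add, 2 delete, 3 update
    double best_alpha_new = 0.0;

    for (uword m = 0; m < Mall; ++m) {
      double Sm = S(m), Qm = Q(m);
      int pos = inact_pos[m];
      if (pos < 0) {                  // candidate addition: s = S, q = Q
        if (g(m) <= 0 || Sm <= 0 || add_count[m] >= 4) continue;
        double th = Qm * Qm - Sm;
        if (th <= 0) continue;
        // alignment guard: adding a basis nearly collinear with an active
        // one makes the posterior numerically singular
        bool aligned = false;
        for (uword j = 0; j < M; ++j) {
          double r = std::fabs(C(m, j)) / std::sqrt(g(m) * g(act[j]));
          if (r > 0.999) { aligned = true; break; }
        }
        if (aligned) continue;
        double dl = 0.5 * ((Qm * Qm - Sm) / Sm + std::log(Sm / (Qm * Qm)));
        if (dl > best_dl) {
          best_dl = dl; best_m = int(m); best_kind = 1;
          best_alpha_new = Sm * Sm / th;
        }
      } else {
        double a = alv[pos];
        double den = a - Sm;
        if (std::abs(den) < 1e-12) den = (den < 0 ? -1e-12 : 1e-12);
        double sm = a * Sm / den, qm = a * Qm / den;
        double th = qm * qm - sm;
        if (th > 0) {                 // re-estimate precision
          if (frozen[m]) continue;
          double a_new = sm * sm / th;
          if (!(a_new > 0) || !std::isfinite(a_new)) continue;
          double d = 1.0 / a_new - 1.0 / a;
          if (std::abs(d) < 1e-300) continue;
          double one_p = 1.0 + Sm * d;
          if (one_p <= 0) continue;
          double dl = 0.5 * (Qm * Qm / (Sm + 1.0 / d) - std::log(one_p));
          if (dl > best_dl) {
            best_dl = dl; best_m = int(m); best_kind = 3;
            best_alpha_new = a_new;
          }
        } else if (act.size() > 1) {  // delete
          double dl;
          if (a - Sm <= 0) dl = 1e6;  // degenerate basis: force removal
          else dl = 0.5 * (Qm * Qm / (Sm - a) - std::log(1.0 - Sm / a));
          if (dl > best_dl) { best_dl = dl; best_m = int(m); best_kind = 2; }
        }
      }
    }

    const double tol_eff = tol * std::max(1.0, std::fabs(L_acc));
    if (best_m < 0 || best_dl < tol_eff) {
      // basis set converged at the current noise level; re-estimate the
      // noise and continue until it, too, is stable (alternating scheme —
      // re-estimating too early absorbs unexplained signal into the noise)
      if (update_sigma2) {
        mat PhiA = PHI.cols(ia);
        vec resid = t - PhiA * mu;
        double gam = double(M) - dot(alpha, Sigma.diag());
        double beta_new = (double(N) - gam) /
          std::max(dot(resid, resid), 1e-12);
        if (beta_new > 0 && std::isfinite(beta_new)) {
          beta_new = std::min(beta_new, beta_max);
          if (std::fabs(std::log(beta_new / beta)) > 1e-3) {
            beta = beta_new;
            std::fill(frozen.begin(), frozen.end(), 0);
            std::fill(reest_count.begin(), reest_count.end(), 0);
            continue;
          }
        }
      }
      converged = true;
      break;
    }

    if (best_kind == 3 && ++reest_count[best_m] > 10) {
      frozen[best_m] = 1;             // numerically stagnant: stop revisiting
      continue;
    }
    L_acc += best_dl;
    if (best_kind != 3) {
      std::fill(frozen.begin(), frozen.end(), 0);
      std::fill(reest_count.begin(), reest_count.end(), 0);
    }
    if (best_kind == 1) {
      ++add_count[best_m];
      act.push_back(uword(best_m));
      alv.push_back(best_alpha_new);
      C.insert_cols(C.n_cols, PHI.t() * PHI.col(uword(best_m)));
    } else if (best_kind == 2) {
      int pos = inact_pos[best_m];
      act.erase(act.begin() + pos);
      alv.erase(alv.begin() + pos);
      C.shed_col(uword(pos));
    } else {
      alv[inact_pos[best_m]] = best_alpha_new;
    }
  }

  // final posterior and marginal likelihood for the final active set
  double logML;
  {
    const uword M = act.size();
    uvec ia(M); for (uword i = 0; i < M; ++i) ia(i) = act[i];
    vec alpha(M); for (uword i = 0; i < M; ++i) alpha(i) = alv[i];
    mat Gaa = C.rows(ia);
    mat H = beta * Gaa; H.diag() += alpha;
    H = 0.5 * (H + H.t());
    if (!inv_sympd(Sigma, H)) Sigma = pinv(H);
    mu = beta * (Sigma * PHIt.elem(ia));
    // log |C| = -N log beta + log|H| - sum log alpha  (Woodbury), and
    // t' C^-1 t = beta t't - t_A' mu
    double ld_H, sign;
    log_det(ld_H, sign, H);
    double ld_C = -double(N) * std::log(beta) + ld_H - accu(log(alpha));
    double quad = beta * (dot(t, t) - dot(PHIt.elem(ia), mu));
    logML = -0.5 * (double(N) * std::log(2.0 * M_PI) + ld_C + quad);
  }

  std::vector<double> alpha_out(alv);
  std::vector<unsigned int> act1(act.size());
  for (size_t i = 0; i < act.size(); ++i) act1[i] = (unsigned int)(act[i] + 1);

  return Rcpp::List::create(
    Rcpp::Named("active") = act1,
    Rcpp::Named("alpha") = alpha_out,
    Rcpp::Named("mu") = mu,
    Rcpp::Named("Sigma") = Sigma,
    Rcpp::Named("sigma2") = 1.0 / beta,
    Rcpp::Named("logML") = logML,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
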