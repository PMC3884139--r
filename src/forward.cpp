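#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Matrix exponential of Q * dt (scaling-and-squaring Pade, via Armadillo).
// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double dt) {
  return arma::expmat(Q * dt);
}

// Batch transition matrices: P[,,k] = expm(Q[,,pat[k]] * dt[k]).
// pat is 1-based into the slices of Q.
// [[Rcpp::export]]
arma::cube cpp_expm_cube(const arma::cube& Q, const arma::ivec& pat,
                         const arma::vec& dt) {
  const arma::uword nkey = pat.n_elem;
  arma::cube P(Q.n_rows, Q.n_cols, nkey);
  for (arma::uword k = 0; k < nkey; ++k) {
    P.slice(k) = arma::expmat(Q.slice(pat(k) - 1) * dt(k));
  }
  return P;
}

// Scaled forward recursion over all subjects of a panel.
//
// P          : cube of transition matrices over unique (pattern, dt) keys
// Q          : cube of raw intensity matrices (per covariate pattern), used
//              for exact-transition contributions
// seg_key    : 1-based key (slice of P) per segment, segments stored
//              gap-by-gap in subject/time order
// seg_pat    : 1-based pattern (slice of Q) per segment
// gap_nseg   : number of segments per gap (gaps in subject/time order)
// n_visits   : visits per subject
// init       : n_state x n_subject matrix of initial weights at the first
//              visit (before the first visit's emission weight)
// E          : n_state x n_visit_total matrix of emission / indicator
//              weights, one column per visit
// seg_dt     : segment lengths (for the sojourn-survival terms)
// gap_exact  : per gap, 1 = traverse with no-intermediate-jump (sojourn
//              survival) semantics: continuous observation up to the gap's
//              end (exact transition records, or meta$exact_times data)
// exact_state: per visit, 0 or the 1-based state entered at an exactly
//              observed transition time (the visit's E column is ignored)
// cond_visits : condition the likelihood on the first cond_visits visits
//              (0 = none; 1 = standard conditioning on the state at the
//              first observation; 2 = delayed-entry models with a pseudo
//              visit at the time origin)
//
// Returns per-subject log-likelihood contributions; a zero-probability
// observation sequence yields -Inf.
// [[Rcpp::export]]
arma::vec cpp_forward(const arma::cube& P, const arma::cube& Q,
                      const arma::ivec& seg_key, const arma::ivec& seg_pat,
                      const arma::vec& seg_dt, const arma::ivec& gap_exact,
                      const arma::ivec& gap_nseg, const arma::ivec& n_visits,
                      const arma::mat& init, const arma::mat& E,
                      const arma::ivec& exact_state,
                      const int cond_visits) {
  const arma::uword n_subj = n_visits.n_elem;
  const arma::uword ns = init.n_rows;
  arma::vec ll(n_subj, arma::fill::zeros);
  arma::uword visit = 0, gap = 0, seg = 0;

  for (arma::uword i = 0; i < n_subj; ++i) {
    arma::vec alpha = init.col(i);
    double logl = 0.0;
    bool dead_path = false;

    // first visit
    alpha %= E.col(visit);
    double s = arma::accu(alpha);
    if (!(s > 0.0) || !std::isfinite(s)) { dead_path = true; }
    else { logl += std::log(s); alpha /= s; }
    if (cond_visits == 1) logl = 0.0;
    ++visit;

    const int ng = n_visits(i) - 1;
    for (int g = 0; g < ng; ++g, ++gap) {
      int nseg = gap_nseg(gap);
      int last_pat = 0;
      const bool exact_gap = gap_exact(gap) > 0;
      for (int q = 0; q < nseg; ++q, ++seg) {
        if (!dead_path) {
          if (exact_gap) {
            // state constant up to the recorded transition time
            const arma::mat& Qs = Q.slice(seg_pat(seg) - 1);
            for (arma::uword j = 0; j < ns; ++j)
              alpha(j) *= std::exp(Qs(j, j) * seg_dt(seg));
          } else {
            alpha = P.slice(seg_key(seg) - 1).t() * alpha;
          }
        }
        last_pat = seg_pat(seg);
      }
      if (!dead_path) {
        const int ex = exact_state(visit);
        if (ex > 0) {
          // density of an exactly observed entry into state ex
          const arma::uword k = static_cast<arma::uword>(ex - 1);
          double val = 0.0;
          const arma::mat& Qg = Q.slice(last_pat - 1);
          for (arma::uword j = 0; j < ns; ++j)
            if (j != k) val += alpha(j) * Qg(j, k);
          alpha.zeros();
          alpha(k) = val;
        } else {
          alpha %= E.col(visit);
        }
        s = arma::accu(alpha);
        if (!(s > 0.0) || !std::isfinite(s)) dead_path = true;
        else { logl += std::log(s); alpha /= s; }
        if (g + 2 == cond_visits) logl = 0.0;
      }
      ++visit;
    }
    ll(i) = dead_path ? -arma::datum::inf : logl;
  }
  return ll;
}
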