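// Adaptive Metropolis-within-Gibbs sampler for the Poisson log-linear
// model with offset and Leroux CAR random effects:
//   O_i ~ Poisson(E_i exp(x_i' beta + phi_i))
//   phi ~ MVN(0, tau2 * Q(rho, W)^{-1}),  Q = rho (diag(w+) - W) + (1-rho) I
//   beta_j ~ N(0, vBeta),  tau2 ~ IG(aTau, bTau),  rho ~ U[0, 1)
//
// Updates: block random-walk Metropolis for beta (target acceptance 0.23),
// single-site random-walk for each phi_i using the Leroux full conditional
// (target 0.40), conjugate inverse-gamma Gibbs for tau2, random-walk on
// logit(rho) with the eigenvalue form of log det Q (target 0.40). Proposal
// scales adapt in batches of 50 during burn-in and are frozen afterwards.
// phi is recentred to mean zero every sweep, the mean moving into the
// intercept (column 0 of X must be the constant 1).
//
// All randomness comes from R's RNG, so set.seed() in R makes chains
// bit-reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double logitinv(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
List leroux_mcmc_cpp(const arma::vec& O, const arma::vec& E,
                     const arma::mat& X, const List& nbr,
                     const arma::vec& lambda,
                     const arma::vec& betaInit, const arma::mat& propChol,
                     int nIter, int nBurnin, int thin, int phiEvery,
                     double vBeta, double aTau, double bTau,
                     bool sampleRho, double rhoInit, double tau2Init) {
    const int n = O.n_elem, p = X.n_cols;
    if ((int)E.n_elem != n || (int)X.n_rows != n)
        stop("dimension mismatch");

    std::vector<std::vector<int>> nb(n);
    arma::vec deg(n);
    for (int i = 0; i < n; ++i) {
        IntegerVector v = nbr[i];
        nb[i].assign(v.begin(), v.end());   // 0-based indices
        deg[i] = nb[i].size();
    }

    arma::vec beta = betaInit;
    arma::vec phi(n, arma::fill::zeros);
    double tau2 = tau2Init;
    double rho = rhoInit;

    arma::vec Xb = X * beta;

    // proposal scales + adaptation bookkeeping
    double sBeta = 1.0, sRho = 0.5;   // sBeta scales the preconditioned step
    arma::vec sPhi(n); sPhi.fill(0.5);
    const int batch = 50;
    int accB = 0, accR = 0, batchNum = 0;
    arma::ivec accP(n, arma::fill::zeros);
    long keptAccB = 0, keptAccR = 0, keptAccP = 0, keptTries = 0;

    const int nKeep = (nIter - nBurnin) / thin;
    const int nKeepPhi = (nKeep + phiEvery - 1) / phiEvery;
    arma::mat betaS(nKeep, p), phiS(nKeepPhi, n);
    arma::vec tau2S(nKeep), rhoS(nKeep);
    IntegerVector phiIdx(nKeepPhi);

    int kept = 0, keptPhi = 0;
    RNGScope scope;

    for (int it = 1; it <= nIter; ++it) {
        // ---- beta block update (proposal preconditioned by the GLM
        //      Fisher-information Cholesky supplied from R)
        arma::vec z(p);
        for (int j = 0; j < p; ++j) z[j] = norm_rand();
        arma::vec prop = beta + sBeta * (propChol * z);
        arma::vec Xbp = X * prop;
        double d = 0.0;
        for (int i = 0; i < n; ++i)
            d += O[i] * (Xbp[i] - Xb[i])
               - E[i] * std::exp(phi[i]) * (std::exp(Xbp[i]) - std::exp(Xb[i]));
        d -= (arma::dot(prop, prop) - arma::dot(beta, beta)) / (2.0 * vBeta);
        if (!std::isfinite(d))
            stop("non-finite log-posterior in beta update at iteration %d", it);
        if (std::log(unif_rand()) < d) {
            beta = prop; Xb = Xbp; ++accB;
            if (it > nBurnin) ++keptAccB;
        }

        // ---- phi single-site updates
        for (int i = 0; i < n; ++i) {
            double sumNb = 0.0;
            for (int j : nb[i]) sumNb += phi[j];
            double denom = rho * deg[i] + 1.0 - rho;
            double m = rho * sumNb / denom;
            double prec = denom / tau2;
            double cur = phi[i];
            double pr = cur + sPhi[i] * norm_rand();
            double Ei = E[i] * std::exp(Xb[i]);
            double dd = O[i] * (pr - cur) - Ei * (std::exp(pr) - std::exp(cur))
                      - 0.5 * prec * ((pr - m) * (pr - m) - (cur - m) * (cur - m));
            if (!std::isfinite(dd))
                stop("non-finite log-posterior in phi update at iteration %d", it);
            if (std::log(unif_rand()) < dd) {
                phi[i] = pr; accP[i]++;
                if (it > nBurnin) ++keptAccP;
            }
            if (it > nBurnin) ++keptTries;
        }

        // ---- recentre phi (identifiability): mean into the intercept
        double mphi = arma::mean(phi);
        phi -= mphi;
        beta[0] += mphi;
        Xb += mphi;

        // ---- tau2 Gibbs (conjugate inverse gamma)
        double ssEdge = 0.0;
        for (int i = 0; i < n; ++i)
            for (int j : nb[i])
                if (j > i) { double e = phi[i] - phi[j]; ssEdge += e * e; }
        double ssPhi = arma::dot(phi, phi);
        double quad = rho * ssEdge + (1.0 - rho) * ssPhi;
        tau2 = 1.0 / R::rgamma(aTau + n / 2.0, 1.0 / (bTau + quad / 2.0));

        // ---- rho random walk on the logit scale
        if (sampleRho) {
            double theta = std::log(rho / (1.0 - rho));
            double thp = theta + sRho * norm_rand();
            double rhp = logitinv(thp);
            double ldCur = 0.0, ldProp = 0.0;
            for (int k = 0; k < n; ++k) {
                ldCur  += std::log(rho * lambda[k] + 1.0 - rho);
                ldProp += std::log(rhp * lambda[k] + 1.0 - rhp);
            }
            double qCur  = rho * ssEdge + (1.0 - rho) * ssPhi;
            double qProp = rhp * ssEdge + (1.0 - rhp) * ssPhi;
            double dr = 0.5 * (ldProp - ldCur) - (qProp - qCur) / (2.0 * tau2)
                      + std::log(rhp * (1.0 - rhp)) - std::log(rho * (1.0 - rho));
            if (!std::isfinite(dr))
                stop("non-finite log-posterior in rho update at iteration %d", it);
            if (std::log(unif_rand()) < dr) {
                rho = rhp; ++accR;
                if (it > nBurnin) ++keptAccR;
            }
        }

        // ---- adaptation during burn-in only
        if (it <= nBurnin && it % batch == 0) {
            ++batchNum;
            double step = std::min(0.05, 1.0 / std::sqrt((double)batchNum));
            sBeta *= std::exp(((double)accB / batch > 0.23 ? 1 : -1) * step);
            for (int i = 0; i < n; ++i)
                sPhi[i] *= std::exp(((double)accP[i] / batch > 0.40 ? 1 : -1) * step);
            if (sampleRho)
                sRho *= std::exp(((double)accR / batch > 0.40 ? 1 : -1) * step);
            accB = accR = 0; accP.zeros();
        }

        // ---- storage
        if (it > nBurnin && (it - nBurnin) % thin == 0) {
            betaS.row(kept) = beta.t();
            tau2S[kept] = tau2;
            rhoS[kept] = rho;
            if (kept % phiEvery == 0) {
                phiS.row(keptPhi) = phi.t();
                phiIdx[keptPhi] = kept + 1;   // 1-based index into kept draws
                ++keptPhi;
            }
            ++kept;
        }
        if (it % 5000 == 0) Rcpp::checkUserInterrupt();
    }

    double nPost = nIter - nBurnin;
    return List::create(
        _["beta"] = betaS, _["tau2"] = tau2S, _["rho"] = rhoS,
        _["phi"] = phiS, _["phiIdx"] = phiIdx,
        _["accept"] = NumericVector::create(
            _["beta"] = keptAccB / nPost,
            _["phi"] = keptTries > 0 ? (double)keptAccP / keptTries : NA_REAL,
            _["rho"] = sampleRho ? keptAccR / nPost : NA_REAL),
        _["scales"] = List::create(_["beta"] = sBeta, _["rho"] = sRho));
}
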