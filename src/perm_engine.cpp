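// Freedman-Lane permutation engine for the block enrichment statistics.
//
// Per replicate: reconstruct Y* = fitW + P resW (one subject relabeling
// applied brain-wide), refit the full model through the shared QR pieces,
// and evaluate the requested block statistics for each screening channel.
// The tested columns (SA, RRB) are the last two design columns, so their
// coefficients come from a 2x2 back-substitution and the joint partial F
// from the last two orthogonal components.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// ORA: fraction of block members beyond the critical value
void block_ora(const arma::rowvec& stat, bool twosided, double crit,
               const arma::ivec& blk, int nb, const arma::vec& kvec,
               double* out) {
  std::vector<int> cnt(nb, 0);
  for (arma::uword j = 0; j < stat.n_elem; ++j) {
    double v = twosided ? std::fabs(stat[j]) : stat[j];
    if (v > crit) cnt[blk[j]]++;
  }
  for (int g = 0; g < nb; ++g)
    out[g] = kvec[g] > 0 ? cnt[g] / kvec[g] : NA_REAL;
}

// max-mean: one-sided means over the block size (ET) or signed difference
void block_maxmean(const arma::rowvec& stat, bool et,
                   const arma::ivec& blk, int nb, const arma::vec& kvec,
                   double* out) {
  std::vector<double> pos(nb, 0.0), neg(nb, 0.0);
  for (arma::uword j = 0; j < stat.n_elem; ++j) {
    double v = stat[j];
    if (v > 0) pos[blk[j]] += v; else neg[blk[j]] -= v;
  }
  for (int g = 0; g < nb; ++g) {
    if (kvec[g] <= 0) { out[g] = NA_REAL; continue; }
    out[g] = et ? std::max(pos[g], neg[g]) / kvec[g]
                : (pos[g] - neg[g]) / kvec[g];
  }
}

// GSEA running-sum enrichment score for every block in one ranked pass
void block_gsea(const arma::rowvec& stat, bool use_abs, double weight,
                const arma::ivec& blk, int nb, const arma::vec& kvec,
                double* out) {
  arma::uword P = stat.n_elem;
  arma::vec key(P);
  for (arma::uword j = 0; j < P; ++j)
    key[j] = use_abs ? std::fabs(stat[j]) : stat[j];
  arma::vec w(P);
  if (weight == 1.0) w = key;
  else if (weight == 0.0) w.ones();
  else for (arma::uword j = 0; j < P; ++j) w[j] = std::pow(key[j], weight);

  std::vector<double> sw(nb, 0.0);
  for (arma::uword j = 0; j < P; ++j) sw[blk[j]] += w[j];

  arma::uvec ord = arma::sort_index(key, "descend");
  std::vector<double> cw(nb, 0.0), es(nb, 0.0);
  std::vector<int> cnt(nb, 0);
  for (arma::uword t = 0; t < P; ++t) {
    int g = blk[ord[t]];
    cw[g] += w[ord[t]];
    cnt[g] += 1;
    if (sw[g] > 0 && kvec[g] < (double)P) {
      double dev = cw[g] / sw[g] -
        ((double)(t + 1) - cnt[g]) / ((double)P - kvec[g]);
      if (dev > es[g]) es[g] = dev;
    }
  }
  for (int g = 0; g < nb; ++g)
    out[g] = (kvec[g] > 0 && sw[g] > 0 && kvec[g] < (double)P)
      ? es[g] : NA_REAL;
}

} // namespace

// The Freedman-Lane reconstruction Y* = fitW + P resW has fitW inside the
// span of the first p-2 Q columns (the tested columns are last in the QR),
// so every statistic depends on the permuted data only through
// U = Q' P resW = (P' Q)' resW: the tiny Q factor is row-permuted instead
// of the large residual matrix, which stays stationary in the product.
// Residual SSE: ||M_X Y*||^2 = ||P resW||^2 - ||U||^2, and ||P resW||^2
// per pair is permutation-invariant (precomputed column sums of resW^2).

// [[Rcpp::export(name = ".perm_engine_fl")]]
List perm_engine_fl(const arma::mat& resW, const arma::rowvec& resW_sqcs,
                    const arma::mat& Q, const arma::mat& R,
                    double xinv_sa, double xinv_rrb, double df,
                    const IntegerMatrix& perms,
                    const IntegerVector& pair_block, int nb,
                    const NumericVector& kvec_in,
                    bool do_sa, bool do_rrb, bool do_f,
                    bool do_ora, bool do_maxmean, bool do_gsea,
                    double crit_t, double crit_f, bool maxmean_et,
                    double gsea_weight) {
  const int B = perms.nrow();
  const arma::uword n = resW.n_rows, P = resW.n_cols;
  const arma::uword p = Q.n_cols;
  const double Rpp = R(p - 1, p - 1), Rqq = R(p - 2, p - 2),
    Rqp = R(p - 2, p - 1);

  arma::ivec blk(P);
  for (arma::uword j = 0; j < P; ++j) blk[j] = pair_block[j] - 1;
  arma::vec kvec(nb);
  for (int g = 0; g < nb; ++g) kvec[g] = kvec_in[g];

  // output matrices, keyed "<channel>.<statistic>"
  List out;
  std::vector<std::string> chans;
  if (do_sa) chans.push_back("t_sa");
  if (do_rrb) chans.push_back("t_rrb");
  if (do_f) chans.push_back("f_joint");
  for (const auto& ch : chans) {
    if (do_ora) out[ch + ".ora"] = NumericMatrix(B, nb);
    if (do_maxmean && ch != "f_joint")
      out[ch + ".maxmean"] = NumericMatrix(B, nb);
    if (do_gsea) out[ch + ".gsea"] = NumericMatrix(B, nb);
  }

  arma::mat Qp(n, p), U(p, P);
  arma::rowvec t_sa(P), t_rrb(P), f_joint(P);
  arma::uvec inv(n);

  for (int b = 0; b < B; ++b) {
    for (arma::uword i = 0; i < n; ++i) inv[perms(b, i) - 1] = i;
    Qp = Q.rows(inv);
    U = Qp.t() * resW;
    arma::rowvec sse = resW_sqcs - arma::sum(arma::square(U), 0);
    sse.transform([](double v) { return v < 0 ? 0.0 : v; });
    arma::rowvec sigma2 = sse / df;
    arma::rowvec qp = U.row(p - 1), qq = U.row(p - 2);
    if (do_sa || do_rrb) {
      arma::rowvec b_rrb = qp / Rpp;
      if (do_rrb) t_rrb = b_rrb / arma::sqrt(sigma2 * xinv_rrb);
      if (do_sa) t_sa = ((qq - Rqp * b_rrb) / Rqq) /
        arma::sqrt(sigma2 * xinv_sa);
    }
    if (do_f)
      f_joint = ((arma::square(qp) + arma::square(qq)) / 2.0) / sigma2;

    for (const auto& ch : chans) {
      const arma::rowvec& s = (ch == "t_sa") ? t_sa :
        (ch == "t_rrb") ? t_rrb : f_joint;
      bool is_t = (ch != "f_joint");
      if (do_ora) {
        NumericMatrix m = out[ch + ".ora"];
        std::vector<double> row(nb);
        block_ora(s, is_t, is_t ? crit_t : crit_f, blk, nb, kvec, row.data());
        for (int g = 0; g < nb; ++g) m(b, g) = row[g];
      }
      if (do_maxmean && is_t) {
        NumericMatrix m = out[ch + ".maxmean"];
        std::vector<double> row(nb);
        block_maxmean(s, maxmean_et, blk, nb, kvec, row.data());
        for (int g = 0; g < nb; ++g) m(b, g) = row[g];
      }
      if (do_gsea) {
        NumericMatrix m = out[ch + ".gsea"];
        std::vector<double> row(nb);
        block_gsea(s, is_t, gsea_weight, blk, nb, kvec, row.data());
        for (int g = 0; g < nb; ++g) m(b, g) = row[g];
      }
    }
    if (b % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
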