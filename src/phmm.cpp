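// Local-alignment forward and Viterbi dynamic programming for profile HMMs.
//
// Model (unihit local alignment, log-odds against a geometric background
// null): entry B->M_k with probability 2(M-k+1)/(M(M+1)); exit M_k->E with
// probability 1/(M-k+1) carved out of match state k's outgoing mass;
// D_M -> E with probability 1; N/C flanking states emit background residues
// with self-loop probability p = L/(L+2), matching the null model's length
// distribution so flank residues contribute zero log-odds. All computations
// in natural-log space; scores are converted to bits in R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// Parameters passed from R (all natural log):
//   lodds: M x 20 matrix, log(e_k(a)/q(a)); columns AMINO_ACIDS order
//   liodds: length-20 vector, log insert emission odds
//   lentry: length M, log entry probabilities
//   leps: length M, log exit probabilities (eps_k = 1/(M-k+1))
//   l1meps: length M, log(1 - eps_k) (l1meps[M-1] = -Inf)
//   lmm, lmi, lmd, lim, lii, ldm, ldd: length M, core transition logs
//     (index k is the 0-based state k+1; entries beyond their valid range
//     are -Inf)
//   seq: integer vector, residues coded 0..19, ambiguous = -1

struct HmmPar {
  int M;
  NumericMatrix lodds;
  NumericVector liodds, lentry, leps, l1meps, lmm, lmi, lmd, lim, lii, ldm, ldd;
};

static inline double match_odds(const HmmPar& P, int k, int a) {
  return a < 0 ? 0.0 : P.lodds(k, a);
}

static inline double ins_odds(const HmmPar& P, int a) {
  return a < 0 ? 0.0 : P.liodds[a];
}

static HmmPar unpack(List par) {
  HmmPar P;
  P.M = as<int>(par["M"]);
  P.lodds = as<NumericMatrix>(par["lodds"]);
  P.liodds = as<NumericVector>(par["liodds"]);
  P.lentry = as<NumericVector>(par["lentry"]);
  P.leps = as<NumericVector>(par["leps"]);
  P.l1meps = as<NumericVector>(par["l1meps"]);
  P.lmm = as<NumericVector>(par["lmm"]);
  P.lmi = as<NumericVector>(par["lmi"]);
  P.lmd = as<NumericVector>(par["lmd"]);
  P.lim = as<NumericVector>(par["lim"]);
  P.lii = as<NumericVector>(par["lii"]);
  P.ldm = as<NumericVector>(par["ldm"]);
  P.ldd = as<NumericVector>(par["ldd"]);
  return P;
}

// Forward log-odds (natural log) of one integer-coded sequence.
static double forward_one(const HmmPar& P, const IntegerVector& seq) {
  const int M = P.M, L = seq.size();
  if (L == 0) return NEG_INF;
  const double lp = std::log((double)L / (L + 2.0));
  const double l1mp = std::log(2.0 / (L + 2.0));
  std::vector<double> Mprev(M, NEG_INF), Iprev(M, NEG_INF), Dprev(M, NEG_INF);
  std::vector<double> Mcur(M), Icur(M), Dcur(M);
  double lE = NEG_INF;  // logsumexp over i of E(i)
  for (int i = 0; i < L; ++i) {
    const int a = seq[i];
    for (int k = 0; k < M; ++k) {
      // into M_k emitting residue i: from B (flank value 0), or from
      // M_{k-1}/I_{k-1}/D_{k-1} at residue i-1
      double acc = P.lentry[k];
      if (k > 0) {
        acc = lse2(acc, lse3(
          Mprev[k - 1] + P.l1meps[k - 1] + P.lmm[k - 1],
          Iprev[k - 1] + P.lim[k - 1],
          Dprev[k - 1] + P.ldm[k - 1]));
      }
      Mcur[k] = acc + match_odds(P, k, a) - lp;
      // D_k at residue i: from M_{k-1} (same i) or D_{k-1} (same i)
      if (k > 0) {
        Dcur[k] = lse2(Mcur[k - 1] + P.l1meps[k - 1] + P.lmd[k - 1],
                       Dcur[k - 1] + P.ldd[k - 1]);
      } else {
        Dcur[k] = NEG_INF;
      }
      // I_k emitting residue i: from M_k or I_k at residue i-1
      double ia = lse2(Mprev[k] + P.l1meps[k] + P.lmi[k],
                       Iprev[k] + P.lii[k]);
      Icur[k] = ia == NEG_INF ? NEG_INF : ia + ins_odds(P, a) - lp;
    }
    // exits after residue i: from any match state, or through trailing
    // deletes ending at D_M -> E
    double e = NEG_INF;
    for (int k = 0; k < M; ++k) e = lse2(e, Mcur[k] + P.leps[k]);
    if (M > 1) e = lse2(e, Dcur[M - 1]);
    lE = lse2(lE, e);
    std::swap(Mprev, Mcur);
    std::swap(Iprev, Icur);
    std::swap(Dprev, Dcur);
  }
  return lE + l1mp;
}

// [[Rcpp::export(name = ".phmm_forward")]]
double phmm_forward(List par, IntegerVector seq) {
  HmmPar P = unpack(par);
  return forward_one(P, seq);
}

// [[Rcpp::export(name = ".phmm_forward_many")]]
NumericVector phmm_forward_many(List par, List seqs) {
  HmmPar P = unpack(par);
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    out[i] = forward_one(P, s);
  }
  return out;
}

// Viterbi with traceback. State coding in the path matrix: 1 = match,
// 2 = insert, 3 = delete; rows give (state, profile position k [1-based],
// residue index [1-based, 0 for deletes]).
// [[Rcpp::export(name = ".phmm_viterbi")]]
List phmm_viterbi(List par, IntegerVector seq) {
  HmmPar P = unpack(par);
  const int M = P.M, L = seq.size();
  if (L == 0) {
    return List::create(_["log_odds"] = NEG_INF,
                        _["path"] = IntegerMatrix(0, 3),
                        _["span"] = IntegerVector::create(NA_INTEGER, NA_INTEGER));
  }
  const double lp = std::log((double)L / (L + 2.0));
  const double l1mp = std::log(2.0 / (L + 2.0));
  // DP tables (L+1) x M ; i indexes residues 1..L
  std::vector<std::vector<double>> Mv(L + 1, std::vector<double>(M, NEG_INF));
  std::vector<std::vector<double>> Iv(L + 1, std::vector<double>(M, NEG_INF));
  std::vector<std::vector<double>> Dv(L + 1, std::vector<double>(M, NEG_INF));
  // backpointers: 0 = entry, 1 = from M, 2 = from I, 3 = from D
  std::vector<std::vector<int>> Mb(L + 1, std::vector<int>(M, -1));
  std::vector<std::vector<int>> Ib(L + 1, std::vector<int>(M, -1));
  std::vector<std::vector<int>> Db(L + 1, std::vector<int>(M, -1));
  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    for (int k = 0; k < M; ++k) {
      double best = P.lentry[k];
      int arg = 0;
      if (k > 0) {
        double fm = Mv[i - 1][k - 1] + P.l1meps[k - 1] + P.lmm[k - 1];
        double fi = Iv[i - 1][k - 1] + P.lim[k - 1];
        double fd = Dv[i - 1][k - 1] + P.ldm[k - 1];
        if (fm > best) { best = fm; arg = 1; }
        if (fi > best) { best = fi; arg = 2; }
        if (fd > best) { best = fd; arg = 3; }
      }
      Mv[i][k] = best + match_odds(P, k, a) - lp;
      Mb[i][k] = arg;
      if (k > 0) {
        double fm = Mv[i][k - 1] + P.l1meps[k - 1] + P.lmd[k - 1];
        double fd = Dv[i][k - 1] + P.ldd[k - 1];
        if (fm >= fd) { Dv[i][k] = fm; Db[i][k] = 1; }
        else { Dv[i][k] = fd; Db[i][k] = 3; }
      }
      double fm = Mv[i - 1][k] + P.l1meps[k] + P.lmi[k];
      double fi = Iv[i - 1][k] + P.lii[k];
      double ia = fm >= fi ? fm : fi;
      if (ia > NEG_INF) {
        Iv[i][k] = ia + ins_odds(P, a) - lp;
        Ib[i][k] = fm >= fi ? 1 : 2;
      }
    }
  }
  // best exit
  double best = NEG_INF;
  int bi = -1, bk = -1, bstate = 1;  // state at exit: 1 = match, 3 = D_M
  for (int i = 1; i <= L; ++i) {
    for (int k = 0; k < M; ++k) {
      double v = Mv[i][k] + P.leps[k];
      if (v > best) { best = v; bi = i; bk = k; bstate = 1; }
    }
    if (M > 1) {
      double v = Dv[i][M - 1];
      if (v > best) { best = v; bi = i; bk = M - 1; bstate = 3; }
    }
  }
  if (best == NEG_INF) {
    return List::create(_["log_odds"] = NEG_INF,
                        _["path"] = IntegerMatrix(0, 3),
                        _["span"] = IntegerVector::create(NA_INTEGER, NA_INTEGER));
  }
  // traceback
  std::vector<int> st, kk, ri;
  int i = bi, k = bk, state = bstate;
  while (true) {
    st.push_back(state);
    kk.push_back(k + 1);
    ri.push_back(state == 3 ? 0 : i);
    int back;
    if (state == 1) back = Mb[i][k];
    else if (state == 2) back = Ib[i][k];
    else back = Db[i][k];
    if (state == 1) {
      if (back == 0) break;
      // predecessor emitted residue i-1 (M or I) or is D at i-1
      i -= 1;
      k -= 1;
      state = back;
    } else if (state == 2) {
      i -= 1;
      state = back;  // same k
    } else {  // delete: predecessor at same residue count
      k -= 1;
      state = back;
    }
  }
  const int n = st.size();
  IntegerMatrix path(n, 3);
  int first_res = 0, last_res = 0;
  for (int j = 0; j < n; ++j) {
    // reverse order
    path(j, 0) = st[n - 1 - j];
    path(j, 1) = kk[n - 1 - j];
    path(j, 2) = ri[n - 1 - j];
    if (path(j, 0) == 1) {
      if (first_res == 0) first_res = path(j, 2);
      last_res = path(j, 2);
    }
  }
  return List::create(_["log_odds"] = best + l1mp,
                      _["path"] = path,
                      _["span"] = IntegerVector::create(first_res, last_res));
}
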