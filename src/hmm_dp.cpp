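// Forward and Viterbi dynamic programming for profile HMMs, in natural-log
// odds space (log P(path)/P(null)). Nodes j = 0..M; node 0 carries the begin
// state (used in glocal mode) and the N-terminal insert I_0. States per node:
// match M_j (j >= 1), insert I_j (j >= 0), delete D_j (j >= 1). The full
// architecture is used: M/I/D each transition to {M, I, D} of the next node
// (I self-loops at its own node), so every state path observable in a
// training alignment is representable. Transition vectors are indexed by the
// source node j; entries at j = M point to the end state E.
//
// Local mode follows a uniform-fragment model: entry/exit is a uniform
// distribution over ordered match-state pairs (j1 <= j2), probability
// 2/(M(M+1)); flanking residues are emitted at background and contribute 0
// to the log-odds. Residue code 20 ("X") scores 0 (background) everywhere.

#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_INF = R_NegInf;

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// emission log-odds with X handled as background
static inline double emit(const NumericMatrix& le, int row, int x) {
  return (x >= 20) ? 0.0 : le(row, x);
}

// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix le_m, NumericMatrix le_i,
                       NumericVector ltMM, NumericVector ltMI,
                       NumericVector ltMD, NumericVector ltIM,
                       NumericVector ltII, NumericVector ltID,
                       NumericVector ltDM, NumericVector ltDD,
                       NumericVector ltDI, IntegerVector seq, int mode) {
  const int M = le_m.nrow();
  const int L = seq.size();
  const bool local = (mode == 1);
  const double lentry = local ? std::log(2.0 / (double(M) * (M + 1))) : NEG_INF;

  std::vector<double> fm(M + 1, NEG_INF), fi(M + 1, NEG_INF),
      fd(M + 1, NEG_INF), nm(M + 1), ni(M + 1), nd(M + 1);
  double local_total = NEG_INF;

  if (!local) {
    fm[0] = 0.0;  // begin state, no residues emitted yet
    for (int j = 1; j <= M; ++j)
      fd[j] = lse2(fm[j - 1] + ltMD[j - 1], fd[j - 1] + ltDD[j - 1]);
  }

  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    nm[0] = NEG_INF;
    for (int j = 1; j <= M; ++j) {
      double s = lse3(fm[j - 1] + ltMM[j - 1], fi[j - 1] + ltIM[j - 1],
                      fd[j - 1] + ltDM[j - 1]);
      if (local) s = lse2(s, lentry);
      nm[j] = (s == NEG_INF) ? NEG_INF : emit(le_m, j - 1, x) + s;
    }
    for (int j = 0; j <= M; ++j) {
      double s = lse3(fm[j] + ltMI[j], fi[j] + ltII[j], fd[j] + ltDI[j]);
      ni[j] = (s == NEG_INF) ? NEG_INF : emit(le_i, j, x) + s;
    }
    nd[0] = NEG_INF;
    for (int j = 1; j <= M; ++j)
      nd[j] = lse3(nm[j - 1] + ltMD[j - 1], nd[j - 1] + ltDD[j - 1],
                   ni[j - 1] + ltID[j - 1]);
    fm.swap(nm); fi.swap(ni); fd.swap(nd);
    if (local)
      for (int j = 1; j <= M; ++j) local_total = lse2(local_total, fm[j]);
  }

  if (local) return local_total;
  return lse3(fm[M] + ltMM[M], fi[M] + ltIM[M], fd[M] + ltDM[M]);
}

// [[Rcpp::export]]
List hmm_viterbi_cpp(NumericMatrix le_m, NumericMatrix le_i,
                     NumericVector ltMM, NumericVector ltMI,
                     NumericVector ltMD, NumericVector ltIM,
                     NumericVector ltII, NumericVector ltID,
                     NumericVector ltDM, NumericVector ltDD,
                     NumericVector ltDI, IntegerVector seq, int mode) {
  const int M = le_m.nrow();
  const int L = seq.size();
  const bool local = (mode == 1);
  const double lentry = local ? std::log(2.0 / (double(M) * (M + 1))) : NEG_INF;
  const int W = M + 1;

  // DP matrices (L+1) x (M+1); predecessor codes for traceback with the
  // tie order match > delete > insert: 0 = M, 1 = D, 2 = I, 3 = entry/begin.
  std::vector<double> vm((L + 1) * W, NEG_INF), vi((L + 1) * W, NEG_INF),
      vd((L + 1) * W, NEG_INF);
  std::vector<int> pm((L + 1) * W, -1), pi((L + 1) * W, -1),
      pd((L + 1) * W, -1);
  auto at = [W](int i, int j) { return i * W + j; };
  auto pick = [](const double* cand, int n, double& best, int& arg) {
    best = cand[0]; arg = 0;
    for (int k = 1; k < n; ++k)
      if (cand[k] > best) { best = cand[k]; arg = k; }
  };

  if (!local) {
    vm[at(0, 0)] = 0.0;
    for (int j = 1; j <= M; ++j) {
      double cand[2] = {vm[at(0, j - 1)] + ltMD[j - 1],
                        vd[at(0, j - 1)] + ltDD[j - 1]};
      double b; int a; pick(cand, 2, b, a);
      if (b > NEG_INF) { vd[at(0, j)] = b; pd[at(0, j)] = a; }
    }
  }

  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    for (int j = 1; j <= M; ++j) {
      double cand[4] = {vm[at(i - 1, j - 1)] + ltMM[j - 1],
                        vd[at(i - 1, j - 1)] + ltDM[j - 1],
                        vi[at(i - 1, j - 1)] + ltIM[j - 1],
                        local ? lentry : NEG_INF};
      double b; int a; pick(cand, 4, b, a);
      if (b > NEG_INF) { vm[at(i, j)] = emit(le_m, j - 1, x) + b; pm[at(i, j)] = a; }
    }
    for (int j = 0; j <= M; ++j) {
      double cand[3] = {vm[at(i - 1, j)] + ltMI[j],
                        vd[at(i - 1, j)] + ltDI[j],
                        vi[at(i - 1, j)] + ltII[j]};
      double b; int a; pick(cand, 3, b, a);
      if (b > NEG_INF) { vi[at(i, j)] = emit(le_i, j, x) + b; pi[at(i, j)] = a; }
    }
    for (int j = 1; j <= M; ++j) {
      double cand[3] = {vm[at(i, j - 1)] + ltMD[j - 1],
                        vd[at(i, j - 1)] + ltDD[j - 1],
                        vi[at(i, j - 1)] + ltID[j - 1]};
      double b; int a; pick(cand, 3, b, a);
      if (b > NEG_INF) { vd[at(i, j)] = b; pd[at(i, j)] = a; }
    }
  }

  double score = NEG_INF;
  int end_i = -1, end_j = -1;
  char end_state = 'M';
  if (local) {
    for (int i = 1; i <= L; ++i)
      for (int j = 1; j <= M; ++j)
        if (vm[at(i, j)] > score) { score = vm[at(i, j)]; end_i = i; end_j = j; }
  } else {
    double cand[3] = {vm[at(L, M)] + ltMM[M], vd[at(L, M)] + ltDM[M],
                      vi[at(L, M)] + ltIM[M]};
    double b; int a; pick(cand, 3, b, a);
    score = b; end_state = (a == 0) ? 'M' : (a == 1) ? 'D' : 'I';
    end_i = L; end_j = M;
  }
  if (score == NEG_INF || end_i < 0)
    return List::create(_["logodds"] = NEG_INF,
                        _["path"] = CharacterVector(0));

  // traceback; predecessors of M_j live at (i-1, j-1), of I_j at (i-1, j)
  // except D_j -> I_j which also lives at (i-1, j), and of D_j at (i, j-1).
  // The glocal begin state is M at (0, 0); it is not emitted into the path.
  std::vector<std::string> rev;
  int i = end_i, j = end_j;
  char st = end_state;
  while (true) {
    rev.push_back(std::string(1, st) + std::to_string(j));
    char nxt;
    if (st == 'M') {
      int p = pm[at(i, j)];
      if (p == 3) break;  // local entry: path starts at this match state
      nxt = (p == 0) ? 'M' : (p == 1) ? 'D' : 'I';
      --i; --j;
    } else if (st == 'I') {
      int p = pi[at(i, j)];
      nxt = (p == 0) ? 'M' : (p == 1) ? 'D' : 'I';
      --i;
    } else {  // D
      int p = pd[at(i, j)];
      nxt = (p == 0) ? 'M' : (p == 1) ? 'D' : 'I';
      --j;
    }
    if (!local && nxt == 'M' && i == 0 && j == 0) break;  // reached begin
    st = nxt;
  }
  std::reverse(rev.begin(), rev.end());
  CharacterVector path(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) path[k] = rev[k];
  return List::create(_["logodds"] = score, _["path"] = path);
}
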