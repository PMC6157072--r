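// Mating-plan decoding and penalized objective evaluation.
//
// A chromosome is a real vector: one contribution gene per candidate per role,
// followed by mate-permutation keys (M keys in gendered mode, 2M in generic
// mode) and, when editing is enabled, one edit-rank gene per editable
// candidate. Decoding is rank/positive-part based, so the evaluator is
// scale-invariant and total: every real vector maps to a plan.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Role {
  std::vector<int> idx;  // candidate indices (0-based), candidate-file order
  int T;                 // required total contributions for this role
  int minc, maxc, maxp;
};

struct Problem {
  int n, M;
  bool gendered, allow_selfing;
  Role role1, role2;  // generic mode uses role1 only
  NumericMatrix K;
  NumericVector a, a_edit;
  int mode;  // 0 max_gain, 1 min_coancestry, 2 min_inbreeding, 3 target
  double Cstar, span, w;
  int edit_budget;
  std::vector<int> editable;  // candidate indices, 0-based
  int n_mate;                 // number of mate keys
  int dim;                    // expected chromosome length
};

std::vector<int> as_idx0(SEXP s) {
  IntegerVector v(s);
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1;
  return out;
}

Problem unpack(List d) {
  Problem P;
  P.n = as<int>(d["n"]);
  P.M = as<int>(d["M"]);
  P.gendered = as<bool>(d["gendered"]);
  P.allow_selfing = as<bool>(d["allow_selfing"]);
  P.role1.idx = as_idx0(d["role1_idx"]);
  P.role1.T = as<int>(d["role1_T"]);
  P.role1.minc = as<int>(d["role1_min"]);
  P.role1.maxc = as<int>(d["role1_max"]);
  P.role1.maxp = as<int>(d["role1_maxp"]);
  if (P.gendered) {
    P.role2.idx = as_idx0(d["role2_idx"]);
    P.role2.T = as<int>(d["role2_T"]);
    P.role2.minc = as<int>(d["role2_min"]);
    P.role2.maxc = as<int>(d["role2_max"]);
    P.role2.maxp = as<int>(d["role2_maxp"]);
  }
  P.K = as<NumericMatrix>(d["K"]);
  P.a = as<NumericVector>(d["a"]);
  P.a_edit = as<NumericVector>(d["a_edit"]);
  P.mode = as<int>(d["mode"]);
  P.Cstar = as<double>(d["Cstar"]);
  P.span = as<double>(d["span"]);
  P.w = as<double>(d["w"]);
  P.edit_budget = as<int>(d["edit_budget"]);
  P.editable = as_idx0(d["editable"]);
  P.n_mate = P.gendered ? P.M : 2 * P.M;
  P.dim = (int)P.role1.idx.size() + (P.gendered ? (int)P.role2.idx.size() : 0) +
          P.n_mate + (P.edit_budget > 0 ? (int)P.editable.size() : 0);
  return P;
}

// Rank candidates by gene (desc, ties by index asc), keep a feasible head,
// convert positive parts to shares, clamp share*T to [minc, maxc], then
// largest-remainder integerize to sum exactly T. Breaches forced by
// infeasible gene patterns are counted in viol rather than thrown.
void integerize_core(const double* genes, int ncand, int T, int minc, int maxc,
                     int maxp, int* out, double& viol) {
  std::vector<int> ord(ncand);
  for (int i = 0; i < ncand; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return genes[a] > genes[b]; });
  int keep = std::min(maxp, ncand);
  if (minc > 0) keep = std::min(keep, T / minc);
  if (keep < 1) keep = 1;

  std::vector<double> u(keep);
  double s = 0.0;
  for (int k = 0; k < keep; ++k) {
    u[k] = std::max(genes[ord[k]], 0.0);
    s += u[k];
  }
  if (s <= 0.0) {
    for (int k = 0; k < keep; ++k) u[k] = 1.0 / keep;
  } else {
    for (int k = 0; k < keep; ++k) u[k] /= s;
  }

  std::vector<double> t(keep);
  std::vector<int> cnt(keep);
  int S = 0;
  for (int k = 0; k < keep; ++k) {
    double tk = u[k] * T;
    if (tk < minc) tk = minc;
    if (tk > maxc) tk = maxc;
    t[k] = tk;
    int c = (int)std::floor(tk + 1e-9);
    if (c < minc) c = minc;
    if (c > maxc) c = maxc;
    cnt[k] = c;
    S += c;
  }

  if (S < T) {
    std::vector<int> pri(keep);
    for (int k = 0; k < keep; ++k) pri[k] = k;
    std::stable_sort(pri.begin(), pri.end(), [&](int a, int b) {
      return (t[a] - cnt[a]) > (t[b] - cnt[b]);
    });
    int need = T - S;
    while (need > 0) {
      bool prog = false;
      for (int k : pri) {
        if (need == 0) break;
        if (cnt[k] < maxc) { cnt[k]++; need--; prog = true; }
      }
      if (!prog) {  // everyone at max: exceed and count the breach
        for (int k = 0; k < keep && need > 0; ++k) { cnt[k]++; need--; viol += 1.0; }
      }
    }
  } else if (S > T) {
    std::vector<int> pri(keep);
    for (int k = 0; k < keep; ++k) pri[k] = k;
    // smallest remainder loses first; ties strip the lowest-ranked candidate
    std::stable_sort(pri.begin(), pri.end(), [&](int a, int b) {
      double ra = t[a] - cnt[a], rb = t[b] - cnt[b];
      if (ra != rb) return ra < rb;
      return a > b;
    });
    int excess = S - T;
    while (excess > 0) {
      bool prog = false;
      for (int k : pri) {
        if (excess == 0) break;
        if (cnt[k] > minc) { cnt[k]--; excess--; prog = true; }
      }
      if (!prog) {
        for (int k = keep - 1; k >= 0 && excess > 0; --k)
          if (cnt[k] > 0) { cnt[k]--; excess--; viol += 1.0; }
      }
    }
  }

  for (int i = 0; i < ncand; ++i) out[i] = 0;
  for (int k = 0; k < keep; ++k) out[ord[k]] = cnt[k];
}

std::vector<int> argsort_stable(const double* v, int n) {
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  std::stable_sort(p.begin(), p.end(), [&](int a, int b) { return v[a] < v[b]; });
  return p;
}

struct PlanBuf {
  std::vector<int> nc;       // contributions per candidate (global index)
  std::vector<int> p1, p2;   // matings (candidate indices)
  std::vector<int> edited;
  double viol;
  double gain, coa, inb, penalty, scalar;
};

void decode_eval(const double* z, const Problem& P, PlanBuf& B) {
  B.viol = 0.0;
  B.nc.assign(P.n, 0);
  int n1 = (int)P.role1.idx.size();
  std::vector<int> c1(n1);
  integerize_core(z, n1, P.role1.T, P.role1.minc, P.role1.maxc, P.role1.maxp,
                  c1.data(), B.viol);
  for (int k = 0; k < n1; ++k) B.nc[P.role1.idx[k]] += c1[k];
  int off = n1;
  std::vector<int> c2;
  if (P.gendered) {
    int n2 = (int)P.role2.idx.size();
    c2.resize(n2);
    integerize_core(z + off, n2, P.role2.T, P.role2.minc, P.role2.maxc,
                    P.role2.maxp, c2.data(), B.viol);
    for (int k = 0; k < n2; ++k) B.nc[P.role2.idx[k]] += c2[k];
    off += n2;
  }

  // slot lists in candidate-file order, then mate-key permutation
  B.p1.assign(P.M, -1);
  B.p2.assign(P.M, -1);
  if (P.gendered) {
    std::vector<int> ms, fs;
    ms.reserve(P.M);
    fs.reserve(P.M);
    for (size_t k = 0; k < P.role1.idx.size(); ++k)
      for (int r = 0; r < c1[k]; ++r) ms.push_back(P.role1.idx[k]);
    for (size_t k = 0; k < P.role2.idx.size(); ++k)
      for (int r = 0; r < c2[k]; ++r) fs.push_back(P.role2.idx[k]);
    std::vector<int> pi = argsort_stable(z + off, P.M);
    for (int k = 0; k < P.M; ++k) {
      B.p1[k] = ms[k];
      B.p2[k] = fs[pi[k]];
    }
  } else {
    std::vector<int> sl;
    sl.reserve(2 * P.M);
    for (size_t k = 0; k < P.role1.idx.size(); ++k)
      for (int r = 0; r < c1[k]; ++r) sl.push_back(P.role1.idx[k]);
    std::vector<int> pi = argsort_stable(z + off, 2 * P.M);
    for (int k = 0; k < P.M; ++k) {
      B.p1[k] = sl[pi[2 * k]];
      B.p2[k] = sl[pi[2 * k + 1]];
    }
    if (!P.allow_selfing) {
      for (int k = 0; k < P.M; ++k) {
        if (B.p1[k] != B.p2[k]) continue;
        int i = B.p1[k];
        bool fixed = false;
        for (int tshift = 1; tshift < P.M; ++tshift) {
          int j = (k + tshift) % P.M;
          if (B.p1[j] != i && B.p2[j] != i) {
            std::swap(B.p2[k], B.p2[j]);
            fixed = true;
            break;
          }
        }
        if (!fixed) B.viol += 1.0;
      }
    }
  }
  off += P.n_mate;

  // edit decoding: among SELECTED editable candidates, take the budget with
  // the highest edit-rank genes (ties by candidate index)
  B.edited.clear();
  if (P.edit_budget > 0 && !P.editable.empty()) {
    std::vector<int> sel;
    for (size_t e = 0; e < P.editable.size(); ++e)
      if (B.nc[P.editable[e]] > 0) sel.push_back((int)e);
    std::stable_sort(sel.begin(), sel.end(),
                     [&](int a, int b) { return z[off + a] > z[off + b]; });
    int k = std::min((int)sel.size(), P.edit_budget);
    for (int e = 0; e < k; ++e) B.edited.push_back(P.editable[sel[e]]);
    std::sort(B.edited.begin(), B.edited.end());
  }

  // objective components
  double twoM = 2.0 * P.M;
  double gain = 0.0, coa = 0.0, inb = 0.0;
  std::vector<int> selc;
  for (int i = 0; i < P.n; ++i)
    if (B.nc[i] > 0) selc.push_back(i);
  for (int i : selc) {
    double m = P.a[i];
    for (int e : B.edited)
      if (e == i) { m = P.a_edit[i]; break; }
    gain += (B.nc[i] / twoM) * m;
  }
  for (size_t ai = 0; ai < selc.size(); ++ai)
    for (size_t bi = 0; bi < selc.size(); ++bi) {
      int i = selc[ai], j = selc[bi];
      coa += (B.nc[i] / twoM) * (B.nc[j] / twoM) * P.K(i, j);
    }
  for (int k = 0; k < P.M; ++k) inb += P.K(B.p1[k], B.p2[k]);
  inb /= P.M;

  double pen = P.w * B.viol / P.M;
  if (P.mode == 3 && P.span > 0)
    pen += P.w * std::max(0.0, coa - P.Cstar) / P.span;
  double base;
  switch (P.mode) {
    case 0: base = gain; break;
    case 1: base = -coa; break;
    case 2: base = -inb; break;
    default: base = gain;
  }
  B.gain = gain;
  B.coa = coa;
  B.inb = inb;
  B.penalty = pen;
  B.scalar = base - pen;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_eval_population(NumericMatrix X, List data) {
  Problem P = unpack(data);
  if (X.nrow() != P.dim) stop("chromosome length %d does not match problem dimension %d",
                              X.nrow(), P.dim);
  int NP = X.ncol();
  NumericVector out(NP);
  PlanBuf B;
  for (int j = 0; j < NP; ++j) {
    decode_eval(&X(0, j), P, B);
    out[j] = B.scalar;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_decode_plan(NumericVector z, List data) {
  Problem P = unpack(data);
  if (z.size() != P.dim) stop("chromosome length %d does not match problem dimension %d",
                              (int)z.size(), P.dim);
  PlanBuf B;
  decode_eval(z.begin(), P, B);
  IntegerMatrix mat(P.M, 2);
  for (int k = 0; k < P.M; ++k) {
    mat(k, 0) = B.p1[k] + 1;
    mat(k, 1) = B.p2[k] + 1;
  }
  IntegerVector nc(B.nc.begin(), B.nc.end());
  IntegerVector ed(B.edited.size());
  for (size_t e = 0; e < B.edited.size(); ++e) ed[e] = B.edited[e] + 1;
  return List::create(
      _["matings"] = mat, _["n_contrib"] = nc, _["violations"] = B.viol,
      _["edited"] = ed, _["gain"] = B.gain, _["coancestry"] = B.coa,
      _["inbreeding"] = B.inb, _["penalty"] = B.penalty, _["scalar"] = B.scalar);
}

// [[Rcpp::export]]
List cpp_integerize(NumericVector genes, int total, int minc, int maxc, int maxp) {
  std::vector<int> out(genes.size());
  double viol = 0.0;
  integerize_core(genes.begin(), genes.size(), total, minc, maxc, maxp,
                  out.data(), viol);
  return List::create(_["n"] = IntegerVector(out.begin(), out.end()),
                      _["violations"] = viol);
}
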