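#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Inheritance-vector engine for small pedigrees.
//
// States are inheritance vectors v in {0,1}^B, B = 2 * (number of
// non-founders); bit 2j-1 (1-based) is the paternal meiosis of the j-th
// non-founder, bit 2j the maternal one.  Bit 0 = parent transmitted the
// allele on their own paternal haplotype.  State index = sum_k b_k 2^(k-1),
// 0-based; "lexicographically smallest" tie-breaks mean smallest index.
//
// Founder-allele slots: founder k (k-th founder within the family) owns
// slots 2k-1 and 2k (1-based).  slotP/slotM matrices map (state, person)
// to the founder slot each of the person's two alleles descends from.

// union-find with parity (must-differ constraints between biallelic
// founder alleles implied by heterozygous genotypes)
static int uf_find(int x, std::vector<int> &par, std::vector<signed char> &parity,
                   int &par_out) {
  int p = 0;
  int r = x;
  while (par[r] != r) {
    p ^= parity[r];
    r = par[r];
  }
  // path compression with parity update
  int cur = x, cp = p;
  while (par[cur] != cur) {
    int nxt = par[cur];
    signed char np = parity[cur];
    par[cur] = r;
    parity[cur] = (signed char) cp;
    cp ^= np;
    cur = nxt;
  }
  par_out = p;
  return r;
}

// Likelihood P(observed genotypes at marker m | v) for every inheritance
// vector v, for every marker.  geno codes: 0 missing, 1 = 1/1, 2 = 1/2,
// 3 = 2/2.  freq = frequency of allele 1 per marker.
// [[Rcpp::export]]
NumericMatrix cl_marker_liks(IntegerMatrix slotP, IntegerMatrix slotM,
                             IntegerMatrix geno, NumericVector freq,
                             int nslots) {
  const int V = slotP.nrow();
  const int n = slotP.ncol();
  const int M = geno.ncol();
  if (geno.nrow() != n) stop("genotype/slot dimension mismatch");
  NumericMatrix out(V, M);

  std::vector<signed char> assign(nslots);
  std::vector<int> e1(n), e2(n);
  std::vector<int> par(nslots);
  std::vector<signed char> parity(nslots);
  std::vector<signed char> used(nslots);
  std::vector<double> wA(nslots), wB(nslots);
  std::vector<signed char> seen(nslots);
  std::vector<int> typed;
  typed.reserve(n);

  for (int m = 0; m < M; ++m) {
    typed.clear();
    for (int i = 0; i < n; ++i)
      if (geno(i, m) != 0) typed.push_back(i);
    const double p = freq[m], q = 1.0 - p;
    if (typed.empty()) {
      for (int v = 0; v < V; ++v) out(v, m) = 1.0;
      continue;
    }
    for (int v = 0; v < V; ++v) {
      bool ok = true;
      int ne = 0;
      std::fill(assign.begin(), assign.end(), 0);
      for (size_t t = 0; t < typed.size() && ok; ++t) {
        const int i = typed[t];
        const int s1 = slotP(v, i) - 1, s2 = slotM(v, i) - 1;
        const int g = geno(i, m);
        if (g == 2) {
          if (s1 == s2) { ok = false; break; }
          e1[ne] = s1; e2[ne] = s2; ++ne;
        } else {
          const signed char a = (g == 1) ? 1 : 2;
          if (assign[s1] && assign[s1] != a) { ok = false; break; }
          assign[s1] = a;
          if (assign[s2] && assign[s2] != a) { ok = false; break; }
          assign[s2] = a;
        }
      }
      // propagate known alleles through must-differ edges to a fixpoint
      bool changed = ok && ne > 0;
      while (changed && ok) {
        changed = false;
        for (int e = 0; e < ne; ++e) {
          const signed char a1 = assign[e1[e]], a2 = assign[e2[e]];
          if (a1 && a2) {
            if (a1 == a2) { ok = false; break; }
          } else if (a1) {
            assign[e2[e]] = (signed char) (3 - a1); changed = true;
          } else if (a2) {
            assign[e1[e]] = (signed char) (3 - a2); changed = true;
          }
        }
      }
      if (!ok) { out(v, m) = 0.0; continue; }
      // residual unresolved edges: 2-colourable components
      for (int s = 0; s < nslots; ++s) { par[s] = s; parity[s] = 0; used[s] = 0; }
      for (int e = 0; e < ne && ok; ++e) {
        if (assign[e1[e]]) continue; // fully assigned edge already verified
        int p1, p2;
        const int r1 = uf_find(e1[e], par, parity, p1);
        const int r2 = uf_find(e2[e], par, parity, p2);
        used[e1[e]] = used[e2[e]] = 1;
        if (r1 == r2) {
          if (p1 == p2) ok = false; // odd cycle
        } else {
          par[r1] = r2;
          parity[r1] = (signed char) (p1 ^ p2 ^ 1);
        }
      }
      if (!ok) { out(v, m) = 0.0; continue; }
      double lik = 1.0;
      for (int s = 0; s < nslots; ++s)
        if (assign[s]) lik *= (assign[s] == 1) ? p : q;
      // per-component two colourings
      std::fill(wA.begin(), wA.end(), 1.0);
      std::fill(wB.begin(), wB.end(), 1.0);
      std::fill(seen.begin(), seen.end(), 0);
      for (int s = 0; s < nslots; ++s) {
        if (!used[s]) continue;
        int ps;
        const int r = uf_find(s, par, parity, ps);
        seen[r] = 1;
        wA[r] *= ps ? q : p;
        wB[r] *= ps ? p : q;
      }
      for (int s = 0; s < nslots; ++s)
        if (seen[s]) lik *= wA[s] + wB[s];
      out(v, m) = lik;
    }
  }
  return out;
}

// in-place symmetric per-bit transition: each meiosis bit flips
// independently with probability theta
static void mix_bits(std::vector<double> &x, int B, double theta) {
  const int V = (int) x.size();
  const double s = 1.0 - theta;
  if (theta == 0.0) return;
  for (int b = 0; b < B; ++b) {
    const int mask = 1 << b;
    for (int v = 0; v < V; ++v) {
      if (v & mask) continue;
      const int w = v | mask;
      const double a = x[v], c = x[w];
      x[v] = s * a + theta * c;
      x[w] = s * c + theta * a;
    }
  }
}

// Forward-backward posterior over inheritance vectors at every marker.
// lik: V x M singlepoint likelihoods; theta: M-1 recombination fractions.
// Returns list(post = V x M posterior, loglik = log P(data)).
// [[Rcpp::export]]
List cl_forward_backward(NumericMatrix lik, NumericVector theta) {
  const int V = lik.nrow(), M = lik.ncol();
  int B = 0;
  while ((1 << B) < V) ++B;
  if ((1 << B) != V) stop("state count is not a power of two");
  if (theta.size() != M - 1) stop("need one theta per adjacent marker pair");

  NumericMatrix fwd(V, M);
  std::vector<double> cur(V);
  double loglik = -B * std::log(2.0); // uniform prior over vectors
  for (int v = 0; v < V; ++v) cur[v] = lik(v, 0);
  for (int m = 0; m < M; ++m) {
    if (m > 0) {
      mix_bits(cur, B, theta[m - 1]);
      for (int v = 0; v < V; ++v) cur[v] *= lik(v, m);
    }
    double sc = 0.0;
    for (int v = 0; v < V; ++v) sc += cur[v];
    if (sc <= 0.0) stop("zero forward likelihood (inconsistent data not screened)");
    loglik += std::log(sc);
    for (int v = 0; v < V; ++v) {
      cur[v] /= sc;
      fwd(v, m) = cur[v];
    }
  }
  // backward pass, posterior overwrites fwd
  std::vector<double> bwd(V, 1.0);
  for (int m = M - 2; m >= 0; --m) {
    for (int v = 0; v < V; ++v) bwd[v] *= lik(v, m + 1);
    mix_bits(bwd, B, theta[m]);
    double sc = 0.0;
    for (int v = 0; v < V; ++v) sc += bwd[v];
    for (int v = 0; v < V; ++v) bwd[v] /= sc;
    double tot = 0.0;
    for (int v = 0; v < V; ++v) tot += fwd(v, m) * bwd[v];
    for (int v = 0; v < V; ++v) fwd(v, m) = fwd(v, m) * bwd[v] / tot;
  }
  return List::create(_["post"] = fwd, _["loglik"] = loglik);
}

// Max-product (Viterbi) decoding of the inheritance path, exact under the
// factorized per-bit transition kernel; ties broken toward the smallest
// state index.  Returns 1-based state indices per marker.
// [[Rcpp::export]]
IntegerVector cl_viterbi(NumericMatrix lik, NumericVector theta) {
  const int V = lik.nrow(), M = lik.ncol();
  int B = 0;
  while ((1 << B) < V) ++B;
  if ((1 << B) != V) stop("state count is not a power of two");

  std::vector<double> val(V), nval(V);
  std::vector<int> pred(V), npred(V);
  IntegerMatrix preds(V, std::max(M - 1, 0));
  for (int v = 0; v < V; ++v)
    val[v] = lik(v, 0) > 0 ? std::log(lik(v, 0)) : R_NegInf;
  for (int m = 1; m < M; ++m) {
    const double th = theta[m - 1];
    const double lt = th > 0 ? std::log(th) : R_NegInf;
    const double ls = th < 1 ? std::log(1.0 - th) : R_NegInf;
    for (int v = 0; v < V; ++v) pred[v] = v;
    for (int b = 0; b < B; ++b) {
      const int mask = 1 << b;
      for (int v = 0; v < V; ++v) {
        if (v & mask) continue;
        const int w = v | mask;
        const double stay_v = val[v] + ls, cross_v = val[w] + lt;
        const double stay_w = val[w] + ls, cross_w = val[v] + lt;
        if (cross_v > stay_v ||
            (cross_v == stay_v && pred[w] < pred[v])) {
          nval[v] = cross_v; npred[v] = pred[w];
        } else {
          nval[v] = stay_v; npred[v] = pred[v];
        }
        if (cross_w > stay_w ||
            (cross_w == stay_w && pred[v] < pred[w])) {
          nval[w] = cross_w; npred[w] = pred[v];
        } else {
          nval[w] = stay_w; npred[w] = pred[w];
        }
      }
      std::swap(val, nval);
      std::swap(pred, npred);
    }
    for (int v = 0; v < V; ++v) {
      preds(v, m - 1) = pred[v];
      val[v] += lik(v, m) > 0 ? std::log(lik(v, m)) : R_NegInf;
    }
  }
  int best = 0;
  for (int v = 1; v < V; ++v)
    if (val[v] > val[best]) best = v;
  IntegerVector path(M);
  path[M - 1] = best + 1;
  for (int m = M - 2; m >= 0; --m) {
    best = preds(best, m);
    path[m] = best + 1;
  }
  return path;
}

// Whittemore-Halpern S_all for every inheritance vector.
// affected: 1-based indices of affected individuals.
// S_all(v) = 2^(-a) * sum over the 2^a ways of picking one allele from each
// affected of prod over founder alleles of (multiplicity!).
// [[Rcpp::export]]
NumericVector cl_sall(IntegerMatrix slotP, IntegerMatrix slotM,
                      IntegerVector affected, int nslots) {
  const int V = slotP.nrow();
  const int a = affected.size();
  if (a > 24) stop("too many affected individuals for S_all enumeration");
  const int H = 1 << a;
  NumericVector out(V);
  std::vector<int> counts(nslots);
  std::vector<int> touched(a);
  for (int v = 0; v < V; ++v) {
    double tot = 0.0;
    for (int h = 0; h < H; ++h) {
      double prod = 1.0;
      for (int j = 0; j < a; ++j) {
        const int i = affected[j] - 1;
        const int s = ((h >> j) & 1) ? slotM(v, i) - 1 : slotP(v, i) - 1;
        ++counts[s];
        prod *= counts[s]; // running product of multiplicities = prod b!
        touched[j] = s;
      }
      tot += prod;
      for (int j = 0; j < a; ++j) counts[touched[j]] = 0;
    }
    out[v] = tot / (double) H;
  }
  return out;
}

// P(phenotypes | v, disease model) for every inheritance vector, summing
// founder disease-allele configurations at frequency q with penetrances f.
// phen: 0 unknown (factor 1), 1 unaffected, 2 affected.
// [[Rcpp::export]]
NumericVector cl_phen_lik(IntegerMatrix slotP, IntegerMatrix slotM,
                          IntegerVector phen, LogicalVector is_founder,
                          double q, NumericVector f, int nslots) {
  const int V = slotP.nrow();
  const int n = slotP.ncol();
  if ((double) V * std::ldexp(1.0, nslots) > 4e9)
    stop("pedigree too large for phenotype-likelihood enumeration");
  const int C = 1 << nslots;
  NumericVector out(V);
  std::vector<int> nf;
  std::vector<int> fo;
  for (int i = 0; i < n; ++i)
    (is_founder[i] ? fo : nf).push_back(i);
  std::vector<double> pen(3 * 3); // [phen * 3 + g]
  for (int g = 0; g < 3; ++g) {
    pen[0 * 3 + g] = 1.0;
    pen[1 * 3 + g] = 1.0 - f[g];
    pen[2 * 3 + g] = f[g];
  }
  for (int cfg = 0; cfg < C; ++cfg) {
    double base = 1.0;
    for (int s = 0; s < nslots; ++s)
      base *= ((cfg >> s) & 1) ? q : (1.0 - q);
    for (size_t k = 0; k < fo.size() && base > 0; ++k) {
      const int i = fo[k];
      const int g = ((cfg >> (slotP(0, i) - 1)) & 1) +
                    ((cfg >> (slotM(0, i) - 1)) & 1);
      base *= pen[phen[i] * 3 + g];
    }
    if (base == 0.0) continue;
    for (int v = 0; v < V; ++v) {
      double prod = base;
      for (size_t k = 0; k < nf.size() && prod > 0; ++k) {
        const int i = nf[k];
        const int g = ((cfg >> (slotP(v, i) - 1)) & 1) +
                      ((cfg >> (slotM(v, i) - 1)) & 1);
        prod *= pen[phen[i] * 3 + g];
      }
      out[v] += prod;
    }
  }
  return out;
}

// Gene dropping: founder haplotypes drawn independently per marker from the
// allele-1 frequencies, then propagated through the pedigree with Haldane
// recombination (each meiosis bit flips with probability theta between
// adjacent markers).  Individuals must be ordered parents-before-children;
// fa/mo are 1-based positions within the family (0 = founder).
// Returns genotype codes plus founder-slot descent matrices.
// [[Rcpp::export]]
List cl_gene_drop(IntegerVector fa, IntegerVector mo, NumericVector freq,
                  NumericVector theta) {
  const int n = fa.size();
  const int M = freq.size();
  int F = 0;
  for (int i = 0; i < n; ++i) if (fa[i] == 0) ++F;
  IntegerMatrix slotP(n, M), slotM(n, M), geno(n, M);
  // founder haplotype alleles: slot s (0-based), marker m
  std::vector<signed char> H((size_t) 2 * F * M);
  for (int s = 0; s < 2 * F; ++s)
    for (int m = 0; m < M; ++m)
      H[(size_t) s * M + m] = (R::unif_rand() < freq[m]) ? 1 : 2;
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (fa[i] == 0) {
      for (int m = 0; m < M; ++m) {
        slotP(i, m) = 2 * k + 1;
        slotM(i, m) = 2 * k + 2;
      }
      ++k;
    } else {
      const int pf = fa[i] - 1, pm = mo[i] - 1;
      if (pf >= i || pm >= i) stop("individuals must be ordered parents first");
      int bp = R::unif_rand() < 0.5 ? 0 : 1;
      int bm = R::unif_rand() < 0.5 ? 0 : 1;
      for (int m = 0; m < M; ++m) {
        if (m > 0) {
          if (R::unif_rand() < theta[m - 1]) bp ^= 1;
          if (R::unif_rand() < theta[m - 1]) bm ^= 1;
        }
        slotP(i, m) = bp == 0 ? slotP(pf, m) : slotM(pf, m);
        slotM(i, m) = bm == 0 ? slotP(pm, m) : slotM(pm, m);
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < M; ++m) {
      const int a = H[(size_t) (slotP(i, m) - 1) * M + m];
      const int b = H[(size_t) (slotM(i, m) - 1) * M + m];
      geno(i, m) = (a == b) ? (a == 1 ? 1 : 3) : 2;
    }
  return List::create(_["geno"] = geno, _["slotP"] = slotP,
                      _["slotM"] = slotM);
}
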