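// Coalescent-history dynamic program for the probability of a rooted gene
// tree topology given a species tree with branch lengths (coalescent units)
// under the multispecies coalescent, allowing several sampled individuals
// per species.
//
// The computation sums, over all coalescent histories, the product over
// species-tree branches b of g_{i_b j_b}(T_b) * w_b / d_b, where w_b counts
// orderings of the coalescences placed on b that are consistent with the
// gene tree (hook-length formula for forest posets) and d_b is the number
// of distinct sequences of i_b - j_b coalescences among i_b lineages.
// Rather than expanding histories, the builder records, per species-tree
// branch, transitions between sets of gene lineages entering and leaving
// the branch; the evaluator then runs a numeric pass with the g_{ij}(T)
// values supplied from R. The transition structure depends only on the
// topologies and the taxon map, so it is cached R-side and re-evaluated
// cheaply when branch lengths change.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <vector>

using namespace Rcpp;

typedef uint64_t mask_t;

static inline int popcount64(mask_t x) {
  int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
}

// number of distinct sequences of i-j coalescences among i lineages
static double seq_count(int i, int j) {
  double d = 1.0;
  for (int k = j + 1; k <= i; ++k) d *= k * (k - 1) / 2.0;
  return d;
}

// linear extensions of the ancestry poset restricted to the node set A
// (a forest): |A|! / prod over a in A of (#descendants of a within A).
static double lin_ext(const std::vector<int>& A, const IntegerVector& parent) {
  if (A.empty()) return 1.0;
  const int m = (int)A.size();
  double w = 1.0;
  for (int k = 2; k <= m; ++k) w *= k;
  for (int ai = 0; ai < m; ++ai) {
    int a = A[ai], desc = 0;
    for (int bi = 0; bi < m; ++bi) {
      int x = A[bi];
      while (x != 0) {
        if (x == a) { ++desc; break; }
        x = parent[x - 1];
      }
    }
    w /= desc;
  }
  return w;
}

struct Trans {
  int s1, s2, out, i, j;
};

struct TransKeyLess {
  bool operator()(const Trans& a, const Trans& b) const {
    if (a.s1 != b.s1) return a.s1 < b.s1;
    if (a.s2 != b.s2) return a.s2 < b.s2;
    if (a.out != b.out) return a.out < b.out;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  }
};

// [[Rcpp::export]]
List coal_build_structure(int g_ntip, int g_nnode,
                          IntegerMatrix g_kids,   // g_nnode x 2, node ids
                          IntegerVector g_parent, // length g_ntip+g_nnode, 0 = root
                          int s_ntip,
                          List s_kids,            // per species node, child ids
                          IntegerVector s_postorder,
                          int s_root,
                          IntegerVector tip_species) { // per gene tip, species tip id
  const int gn = g_ntip + g_nnode;
  if (gn > 62) stop("gene trees with more than 31 tips are not supported");
  const int sn = s_postorder.size();

  // child mask of each gene internal node
  std::vector<mask_t> kidmask(gn + 1, 0);
  for (int n = 0; n < g_nnode; ++n) {
    int id = g_ntip + 1 + n;
    kidmask[id] = (mask_t(1) << (g_kids(n, 0) - 1)) | (mask_t(1) << (g_kids(n, 1) - 1));
  }

  int s_nodes_total = s_kids.size();
  std::vector<std::vector<mask_t> > states(s_nodes_total + 1);
  List trans_out(s_nodes_total);
  IntegerVector nstates(s_nodes_total);
  int max_i = 0;

  for (int pi = 0; pi < sn; ++pi) {
    int v = s_postorder[pi];
    bool isroot = (v == s_root);
    bool istip = (v <= s_ntip);

    std::vector<mask_t> enter_masks;
    std::vector<std::pair<int, int> > enter_src; // indices into child state lists
    int c1 = 0, c2 = 0;
    if (istip) {
      mask_t E = 0;
      for (int t = 0; t < g_ntip; ++t)
        if (tip_species[t] == v) E |= (mask_t(1) << t);
      enter_masks.push_back(E);
      enter_src.push_back(std::make_pair(0, 0));
    } else {
      IntegerVector ch = s_kids[v - 1];
      if (ch.size() != 2) stop("species tree must be binary");
      c1 = ch[0]; c2 = ch[1];
      const std::vector<mask_t>& st1 = states[c1];
      const std::vector<mask_t>& st2 = states[c2];
      for (size_t a1 = 0; a1 < st1.size(); ++a1)
        for (size_t a2 = 0; a2 < st2.size(); ++a2) {
          enter_masks.push_back(st1[a1] | st2[a2]);
          enter_src.push_back(std::make_pair((int)a1 + 1, (int)a2 + 1));
        }
    }

    std::map<mask_t, int> state_idx;
    std::vector<mask_t> st_v;
    std::map<Trans, double, TransKeyLess> agg;

    for (size_t es = 0; es < enter_masks.size(); ++es) {
      mask_t E = enter_masks[es];
      int i_in = popcount64(E);
      if (i_in == 0) {
        // no lineages in this population: identity transition
        if (isroot) stop("no lineages reach the species-tree root");
        int out;
        std::map<mask_t, int>::iterator it = state_idx.find(E);
        if (it == state_idx.end()) {
          st_v.push_back(E);
          out = (int)st_v.size();
          state_idx[E] = out;
        } else out = it->second;
        Trans tr; tr.s1 = enter_src[es].first; tr.s2 = enter_src[es].second;
        tr.out = out; tr.i = 0; tr.j = 0;
        agg[tr] += 1.0;
        continue;
      }
      if (i_in > max_i) max_i = i_in;

      // eligible internal nodes: closure of "both children present"
      std::vector<int> elig;
      mask_t pres = E, eligmask = 0;
      bool added = true;
      while (added) {
        added = false;
        for (int n = 0; n < g_nnode; ++n) {
          int id = g_ntip + 1 + n;
          mask_t bit = mask_t(1) << (id - 1);
          if (eligmask & bit) continue;
          if ((kidmask[id] & pres) == kidmask[id]) {
            elig.push_back(id);
            eligmask |= bit;
            pres |= bit;
            added = true;
          }
        }
      }
      const int k = (int)elig.size();
      if (k > 25) stop("too many eligible coalescences on one branch");
      // per eligible node: mask of its eligible children (as subset bitmask)
      std::vector<uint32_t> kid_sub(k, 0);
      for (int a = 0; a < k; ++a)
        for (int b = 0; b < k; ++b)
          if (kidmask[elig[a]] & (mask_t(1) << (elig[b] - 1)))
            kid_sub[a] |= (uint32_t(1) << b);

      // enumerate down-closed subsets directly: eligible nodes are listed
      // in discovery order, which puts children before parents, so a DFS
      // deciding nodes in order never visits an invalid candidate
      std::vector<uint32_t> subsets;
      if (isroot) {
        subsets.push_back((k >= 32) ? ~uint32_t(0) : ((uint32_t(1) << k) - 1));
      } else {
        std::vector<uint32_t> stack_m;
        std::vector<int> stack_i;
        stack_m.push_back(0); stack_i.push_back(0);
        while (!stack_m.empty()) {
          uint32_t m = stack_m.back(); stack_m.pop_back();
          int a = stack_i.back(); stack_i.pop_back();
          while (a < k) {
            if ((kid_sub[a] & m) == kid_sub[a]) {
              // including a stays down-closed: branch
              stack_m.push_back(m | (uint32_t(1) << a));
              stack_i.push_back(a + 1);
            }
            ++a;
          }
          subsets.push_back(m);
        }
      }

      for (size_t si = 0; si < subsets.size(); ++si) {
        uint32_t m = subsets[si];
        std::vector<int> A;
        mask_t Amask = 0;
        for (int a = 0; a < k; ++a)
          if ((m >> a) & 1u) { A.push_back(elig[a]); Amask |= (mask_t(1) << (elig[a] - 1)); }
        int j = i_in - (int)A.size();
        if (isroot && j != 1) stop("root coalescence bookkeeping failed");

        // exit lineages: present nodes whose parent did not coalesce here
        mask_t present = E | Amask, exitmask = 0;
        for (int id = 1; id <= gn; ++id) {
          mask_t bit = mask_t(1) << (id - 1);
          if (!(present & bit)) continue;
          int p = g_parent[id - 1];
          if (p == 0 || !(Amask & (mask_t(1) << (p - 1)))) exitmask |= bit;
        }

        double w = lin_ext(A, g_parent) / seq_count(i_in, j);

        int out;
        std::map<mask_t, int>::iterator it = state_idx.find(exitmask);
        if (it == state_idx.end()) {
          st_v.push_back(exitmask);
          out = (int)st_v.size();
          state_idx[exitmask] = out;
        } else out = it->second;

        Trans tr; tr.s1 = enter_src[es].first; tr.s2 = enter_src[es].second;
        tr.out = out; tr.i = i_in; tr.j = j;
        agg[tr] += w;
      }
    }

    states[v] = st_v;
    nstates[v - 1] = (int)st_v.size();

    const int nr = (int)agg.size();
    IntegerMatrix tm(nr, 5);
    NumericVector wv(nr);
    int r = 0;
    for (std::map<Trans, double, TransKeyLess>::iterator it = agg.begin();
         it != agg.end(); ++it, ++r) {
      tm(r, 0) = it->first.s1;
      tm(r, 1) = it->first.s2;
      tm(r, 2) = it->first.out;
      tm(r, 3) = it->first.i;
      tm(r, 4) = it->first.j;
      wv[r] = it->second;
    }
    trans_out[v - 1] = List::create(_["t"] = tm, _["w"] = wv);
  }

  // flatten: transitions for the postorder nodes concatenated, with row
  // offsets per postorder position, so evaluation touches two flat arrays
  int total = 0;
  for (int pi = 0; pi < sn; ++pi) {
    List tv = trans_out[s_postorder[pi] - 1];
    IntegerMatrix tm = tv["t"];
    total += tm.nrow();
  }
  IntegerMatrix flat(total, 5);
  NumericVector wflat(total);
  IntegerVector off(sn + 1);
  int r0 = 0;
  for (int pi = 0; pi < sn; ++pi) {
    off[pi] = r0;
    List tv = trans_out[s_postorder[pi] - 1];
    IntegerMatrix tm = tv["t"];
    NumericVector wv = tv["w"];
    for (int r = 0; r < tm.nrow(); ++r, ++r0) {
      for (int c = 0; c < 5; ++c) flat(r0, c) = tm(r, c);
      wflat[r0] = wv[r];
    }
  }
  off[sn] = r0;

  return List::create(_["tm"] = flat,
                      _["w"] = wflat,
                      _["off"] = off,
                      _["nstates"] = nstates,
                      _["postorder"] = s_postorder,
                      _["root"] = s_root,
                      _["s_ntip"] = s_ntip,
                      _["max_i"] = max_i);
}

static double eval_flat(List& str, std::vector<const double*>& Gp, int Gdim,
                        std::vector<int>& kid1, std::vector<int>& kid2,
                        std::vector<std::vector<double> >& vals) {
  // field order fixed by coal_build_structure:
  // 0 tm, 1 w, 2 off, 3 nstates, 4 postorder, 5 root, 6 s_ntip, 7 max_i
  IntegerMatrix tm = str[0];
  NumericVector w = str[1];
  IntegerVector off = str[2];
  IntegerVector nstates = str[3];
  IntegerVector postorder = str[4];
  int s_root = as<int>(str[5]);
  int s_ntip = as<int>(str[6]);

  const int *ps1 = &tm(0, 0), *ps2 = &tm(0, 1), *pout = &tm(0, 2),
            *pi_ = &tm(0, 3), *pj = &tm(0, 4);
  const double *pw = w.begin();
  double result = 0.0;

  for (int pi = 0; pi < postorder.size(); ++pi) {
    int v = postorder[pi];
    bool isroot = (v == s_root);
    bool istip = (v <= s_ntip);
    const double *Gv = Gp[v - 1];
    std::vector<double>& acc = vals[v];
    acc.assign(nstates[v - 1], 0.0);
    const double *v1 = 0, *v2 = 0;
    if (!istip) {
      v1 = vals[kid1[v - 1]].data();
      v2 = vals[kid2[v - 1]].data();
    }
    for (int r = off[pi]; r < off[pi + 1]; ++r) {
      int i = pi_[r], j = pj[r];
      double g = (i == 0) ? 1.0 : Gv[(j - 1) * Gdim + (i - 1)];
      double x = pw[r] * g;
      if (!istip) x *= v1[ps1[r] - 1] * v2[ps2[r] - 1];
      if (isroot) result += x; else acc[pout[r] - 1] += x;
    }
  }
  return result;
}

// [[Rcpp::export]]
NumericVector coal_eval_many(List strs, List G, List s_kids) {
  const int n = strs.size();
  const int nn = s_kids.size();
  NumericVector out(n);
  std::vector<const double*> Gp(nn, (const double*)0);
  int Gdim = 0;
  for (int v = 0; v < nn; ++v) {
    NumericMatrix Gv = G[v];
    Gp[v] = Gv.begin();
    Gdim = Gv.nrow();
  }
  std::vector<int> kid1(nn, 0), kid2(nn, 0);
  for (int v = 0; v < nn; ++v) {
    IntegerVector ch = s_kids[v];
    if (ch.size() == 2) { kid1[v] = ch[0]; kid2[v] = ch[1]; }
  }
  std::vector<std::vector<double> > vals(nn + 1);
  for (int k = 0; k < n; ++k) {
    List s = strs[k];
    out[k] = eval_flat(s, Gp, Gdim, kid1, kid2, vals);
  }
  return out;
}

// [[Rcpp::export]]
double coal_eval_structure(List str, List G, List s_kids) {
  List strs = List::create(str);
  NumericVector out = coal_eval_many(strs, G, s_kids);
  return out[0];
}

// weighted per-gene sums over resolution-class structures in one call
// [[Rcpp::export]]
NumericVector coal_eval_batch(List strs, IntegerVector gene_of, NumericVector wt,
                              List G, List s_kids, int ngenes) {
  const int n = strs.size();
  const int nn = s_kids.size();
  NumericVector out(ngenes);
  std::vector<const double*> Gp(nn, (const double*)0);
  int Gdim = 0;
  for (int v = 0; v < nn; ++v) {
    NumericMatrix Gv = G[v];
    Gp[v] = Gv.begin();
    Gdim = Gv.nrow();
  }
  std::vector<int> kid1(nn, 0), kid2(nn, 0);
  for (int v = 0; v < nn; ++v) {
    IntegerVector ch = s_kids[v];
    if (ch.size() == 2) { kid1[v] = ch[0]; kid2[v] = ch[1]; }
  }
  std::vector<std::vector<double> > vals(nn + 1);
  for (int k = 0; k < n; ++k) {
    List s = strs[k];
    out[gene_of[k] - 1] += wt[k] * eval_flat(s, Gp, Gdim, kid1, kid2, vals);
  }
  return out;
}
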