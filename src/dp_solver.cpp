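// Exact minimization of a separable integer objective on the
// interval-adjacency graph subject to the copy-number balance constraints.
//
// The solver sweeps the vertices in a fixed linear order and keeps, for every
// combination of multiplicities of the edges crossing the current cut, the
// cheapest way to realize it (a "cut" dynamic program).  Because the
// objective is tabulated at every integer multiplicity, the optimum is the
// exact discrete optimum -- no piecewise-linear approximation error.  The
// state space is the product of the domains of the open edges, so the
// algorithm is exponential only in the cut width of the vertex order; for
// chromosome-ordered graphs whose variant edges rarely cross, the width
// stays small.  A guard aborts cleanly when the width is too large.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

struct Incidence {
  int edge;
  int coef;  // +1 interval edge, -1 reference, -mult for variant (loop: -2)
};

}  // namespace

// [[Rcpp::export(name = ".dp_solve_cpp")]]
List dp_solve_cpp(IntegerVector v1, IntegerVector v2, CharacterVector type,
                  IntegerVector lo, IntegerVector hi, List cost,
                  IntegerVector order, LogicalVector telomeric,
                  double max_states) {
  const int ne = v1.size();
  const int nv = telomeric.size();
  if (order.size() != nv) stop("order must enumerate every vertex");

  std::vector<int> pos(nv, -1);
  for (int t = 0; t < nv; ++t) pos[order[t]] = t;
  for (int v = 0; v < nv; ++v)
    if (pos[v] < 0) stop("order must be a permutation of the vertices");

  std::vector<std::vector<double> > costs(ne);
  for (int e = 0; e < ne; ++e) {
    NumericVector ce = cost[e];
    if ((int)ce.size() < hi[e] + 1) stop("cost table shorter than domain");
    costs[e].assign(ce.begin(), ce.end());
    if (lo[e] < 0 || hi[e] < lo[e]) stop("invalid edge domain");
  }

  // per-vertex incidences for the balance constraint
  std::vector<std::vector<Incidence> > inc(nv);
  for (int e = 0; e < ne; ++e) {
    char ty = CHAR(STRING_ELT(type, e))[0];
    int a = v1[e], b = v2[e];
    if (a == b) {  // self-junction: counted twice in the variant sum
      if (ty != 'V') stop("only variant edges may be loops");
      inc[a].push_back({e, -2});
    } else {
      int coef = (ty == 'I') ? 1 : -1;
      inc[a].push_back({e, coef});
      inc[b].push_back({e, coef});
    }
  }

  // per-step bookkeeping: edges newly assigned at a step (first endpoint
  // reached, loops included) and edges leaving the open set
  std::vector<std::vector<int> > newe(nv), closing(nv);
  for (int e = 0; e < ne; ++e) {
    int pa = pos[v1[e]], pb = pos[v2[e]];
    int first = pa < pb ? pa : pb, last = pa < pb ? pb : pa;
    newe[first].push_back(e);
    if (first != last) closing[last].push_back(e);
  }

  // DP over cut states --------------------------------------------------
  typedef std::map<uint64_t, std::pair<double, int64_t> > StateMap;
  StateMap cur;
  cur[0] = std::make_pair(0.0, (int64_t)-1);

  // backtracking arena: parent record + values assigned at that step
  std::vector<int64_t> rec_parent;
  std::vector<std::vector<std::pair<int, int> > > rec_assign;

  std::vector<int> open;            // ordered list of open edge indices

  for (int t = 0; t < nv; ++t) {
    const int v = order[t];
    const bool balanced = !telomeric[v];

    // edges opened here that stay open past this vertex
    std::vector<int> opening;
    for (size_t i = 0; i < newe[t].size(); ++i)
      if (v1[newe[t][i]] != v2[newe[t][i]]) opening.push_back(newe[t][i]);

    // next open set = open - closing + opening (order preserved)
    std::vector<bool> closes(ne, false);
    for (size_t i = 0; i < closing[t].size(); ++i) closes[closing[t][i]] = true;
    std::vector<int> nopen;
    for (size_t i = 0; i < open.size(); ++i)
      if (!closes[open[i]]) nopen.push_back(open[i]);
    for (size_t i = 0; i < opening.size(); ++i) nopen.push_back(opening[i]);

    double width = 1.0;
    for (size_t i = 0; i < nopen.size(); ++i)
      width *= (double)(hi[nopen[i]] - lo[nopen[i]] + 1);
    if (width > max_states)
      stop("cut width of the vertex order is too large for exact solving "
           "(state space %.3g > %.3g)", width, max_states);




    // radices for current and next keys
    std::vector<uint64_t> radix(open.size()), nradix(nopen.size());
    for (size_t i = 0; i < open.size(); ++i)
      radix[i] = (uint64_t)(hi[open[i]] - lo[open[i]] + 1);
    for (size_t i = 0; i < nopen.size(); ++i)
      nradix[i] = (uint64_t)(hi[nopen[i]] - lo[nopen[i]] + 1);

    const std::vector<int>& nw = newe[t];
    const size_t k = nw.size();

    StateMap next;
    std::vector<int> digits(open.size());
    std::vector<int> val(ne, -1);

    for (StateMap::const_iterator it = cur.begin(); it != cur.end(); ++it) {
      // decode open-edge values
      uint64_t key = it->first;
      for (size_t i = 0; i < open.size(); ++i) {
        digits[i] = (int)(key % radix[i]);
        key /= radix[i];
        val[open[i]] = lo[open[i]] + digits[i];
      }
      const double base_cost = it->second.first;
      const int64_t parent = it->second.second;

      // odometer over the values of the newly assigned edges
      std::vector<int> w(k);
      for (size_t i = 0; i < k; ++i) { w[i] = lo[nw[i]]; val[nw[i]] = w[i]; }
      bool done = (k == 0);
      bool first_pass = true;
      while (first_pass || !done) {
        first_pass = false;
        // balance at v
        bool ok = true;
        if (balanced) {
          int bal = 0;
          for (size_t i = 0; i < inc[v].size(); ++i)
            bal += inc[v][i].coef * val[inc[v][i].edge];
          ok = (bal == 0);
        }
        if (ok) {
          double c = base_cost;
          for (size_t i = 0; i < k; ++i) c += costs[nw[i]][val[nw[i]]];
          uint64_t nkey = 0;
          for (size_t i = nopen.size(); i-- > 0;)
            nkey = nkey * nradix[i] + (uint64_t)(val[nopen[i]] - lo[nopen[i]]);
          StateMap::iterator f = next.find(nkey);
          if (f == next.end() || c < f->second.first) {
            int64_t rec = (int64_t)rec_parent.size();
            rec_parent.push_back(parent);
            std::vector<std::pair<int, int> > as(k);
            for (size_t i = 0; i < k; ++i)
              as[i] = std::make_pair(nw[i], val[nw[i]]);
            rec_assign.push_back(as);
            if (f == next.end())
              next[nkey] = std::make_pair(c, rec);
            else
              f->second = std::make_pair(c, rec);
          }
        }
        // advance odometer
        if (k == 0) break;
        size_t i = 0;
        for (; i < k; ++i) {
          if (w[i] < hi[nw[i]]) { ++w[i]; val[nw[i]] = w[i]; break; }
          w[i] = lo[nw[i]]; val[nw[i]] = w[i];
        }
        if (i == k) done = true;
      }
    }

    cur.swap(next);
    open.swap(nopen);

    if (cur.empty()) {
      return List::create(_["status"] = "infeasible",
                          _["mu"] = IntegerVector(0),
                          _["objective"] = NA_REAL);
    }
  }

  // open set is empty now; the single surviving state is the optimum
  StateMap::const_iterator best = cur.begin();
  IntegerVector mu(ne, NA_INTEGER);
  int64_t rec = best->second.second;
  while (rec >= 0) {
    const std::vector<std::pair<int, int> >& as = rec_assign[(size_t)rec];
    for (size_t i = 0; i < as.size(); ++i) mu[as[i].first] = as[i].second;
    rec = rec_parent[(size_t)rec];
  }
  return List::create(_["status"] = "optimal", _["mu"] = mu,
                      _["objective"] = best->second.first);
}
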