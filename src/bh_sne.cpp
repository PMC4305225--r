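// Barnes-Hut approximation of the t-SNE gradient: quadtree-summarized
// repulsive forces plus sparse attractive forces, as in the reference
// BH-SNE implementation. theta = 0 degenerates to the exact O(n^2) sum.

#include <Rcpp.h>
#include <cfloat>
#include <vector>
#ifdef _OPENMP
#include <omp.h>
#endif

using namespace Rcpp;

namespace {

const int MAXDEPTH = 48; // beyond this, coincident points share a leaf

struct Node {
  double cx = 0, cy = 0, hw = 0;   // cell center, half width
  double comx = 0, comy = 0;       // center of mass
  int cumSize = 0;
  bool leaf = true;
  std::vector<int> idx;            // point indices stored at a leaf
  int kids[4] = {-1, -1, -1, -1};
};

class QuadTree {
public:
  std::vector<Node> nodes;
  std::vector<double> xs, ys;

  explicit QuadTree(const NumericMatrix &Y) {
    int n = Y.nrow();
    xs.resize(n);
    ys.resize(n);
    double minx = R_PosInf, maxx = R_NegInf, miny = R_PosInf, maxy = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xs[i] = Y(i, 0);
      ys[i] = Y(i, 1);
      minx = std::min(minx, xs[i]);
      maxx = std::max(maxx, xs[i]);
      miny = std::min(miny, ys[i]);
      maxy = std::max(maxy, ys[i]);
    }
    nodes.reserve(4 * (size_t)n + 8);
    double hw = std::max(maxx - minx, maxy - miny) / 2.0 + 1e-5;
    newNode((minx + maxx) / 2.0, (miny + maxy) / 2.0, hw);
    for (int i = 0; i < n; ++i) insert(0, i, 0);
  }

  int newNode(double cx, double cy, double hw) {
    nodes.emplace_back();
    Node &nd = nodes.back();
    nd.cx = cx;
    nd.cy = cy;
    nd.hw = hw;
    return (int)nodes.size() - 1;
  }

  int childFor(int nd, double px, double py) {
    int q = (px >= nodes[nd].cx ? 1 : 0) + (py >= nodes[nd].cy ? 2 : 0);
    if (nodes[nd].kids[q] < 0) {
      double hw = nodes[nd].hw / 2.0;
      double cx = nodes[nd].cx + (px >= nodes[nd].cx ? hw : -hw);
      double cy = nodes[nd].cy + (py >= nodes[nd].cy ? hw : -hw);
      int c = newNode(cx, cy, hw); // may reallocate: re-index below
      nodes[nd].kids[q] = c;
    }
    return nodes[nd].kids[q];
  }

  void insert(int nd, int i, int depth) {
    double px = xs[i], py = ys[i];
    {
      Node &node = nodes[nd];
      node.cumSize++;
      node.comx += (px - node.comx) / node.cumSize;
      node.comy += (py - node.comy) / node.cumSize;
    }
    if (nodes[nd].leaf) {
      if (nodes[nd].idx.empty() || depth >= MAXDEPTH) {
        nodes[nd].idx.push_back(i);
        return;
      }
      std::vector<int> old;
      old.swap(nodes[nd].idx);
      nodes[nd].leaf = false;
      for (int j : old) insert(childFor(nd, xs[j], ys[j]), j, depth + 1);
      insert(childFor(nd, px, py), i, depth + 1);
      return;
    }
    insert(childFor(nd, px, py), i, depth + 1);
  }

  // Accumulate the repulsive (negative) force on point i and its share
  // of the normalization sum Z = sum_{k != l} (1 + d^2)^-1.
  void repulsion(int nd, int i, double theta2, double &negx, double &negy,
                 double &sumQ) const {
    const Node &node = nodes[nd];
    if (node.cumSize == 0) return;
    double dx = xs[i] - node.comx, dy = ys[i] - node.comy;
    double d2 = dx * dx + dy * dy;
    double w = 2.0 * node.hw;
    if (node.leaf) {
      for (int j : node.idx) {
        if (j == i) continue;
        double ddx = xs[i] - xs[j], ddy = ys[i] - ys[j];
        double q = 1.0 / (1.0 + ddx * ddx + ddy * ddy);
        sumQ += q;
        double m = q * q;
        negx += m * ddx;
        negy += m * ddy;
      }
      return;
    }
    if (w * w < theta2 * d2) { // summarize: w / dist < theta
      double q = 1.0 / (1.0 + d2);
      double mult = node.cumSize * q;
      sumQ += mult;
      mult *= q;
      negx += mult * dx;
      negy += mult * dy;
      return;
    }
    for (int k = 0; k < 4; ++k)
      if (node.kids[k] >= 0) repulsion(node.kids[k], i, theta2, negx, negy, sumQ);
  }
};

} // namespace

// [[Rcpp::export]]
NumericMatrix bh_gradient_cpp(NumericMatrix Y, IntegerVector Pp,
                              IntegerVector Pi_, NumericVector Px,
                              double theta, int nThreads) {
  int n = Y.nrow();
  QuadTree tree(Y);
  std::vector<double> negx(n, 0.0), negy(n, 0.0), posx(n, 0.0), posy(n, 0.0);
  std::vector<double> sq_i(n, 0.0); // summed serially: thread-count invariant
  double theta2 = theta * theta;

#ifdef _OPENMP
#pragma omp parallel for schedule(static) num_threads(nThreads)
#endif
  for (int i = 0; i < n; ++i) {
    double nx = 0, ny = 0, sq = 0;
    tree.repulsion(0, i, theta2, nx, ny, sq);
    negx[i] = nx;
    negy[i] = ny;
    sq_i[i] = sq;
    double px = 0, py = 0;
    for (int k = Pp[i]; k < Pp[i + 1]; ++k) {
      int j = Pi_[k];
      double ddx = Y(i, 0) - Y(j, 0), ddy = Y(i, 1) - Y(j, 1);
      double q = 1.0 / (1.0 + ddx * ddx + ddy * ddy);
      px += Px[k] * q * ddx;
      py += Px[k] * q * ddy;
    }
    posx[i] = px;
    posy[i] = py;
  }

  double sumQ = 0.0;
  for (int i = 0; i < n; ++i) sumQ += sq_i[i];
  if (sumQ <= 0) sumQ = DBL_MIN;
  NumericMatrix grad(n, 2);
  for (int i = 0; i < n; ++i) {
    grad(i, 0) = 4.0 * (posx[i] - negx[i] / sumQ);
    grad(i, 1) = 4.0 * (posy[i] - negy[i] / sumQ);
  }
  return grad;
}

// Diagnostics used by the quadtree invariants tests: total mass at the
// root, root center of mass, and the number of points stored in leaves.
// [[Rcpp::export]]
List quadtree_summary_cpp(NumericMatrix Y) {
  QuadTree tree(Y);
  int leafPoints = 0;
  for (const auto &nd : tree.nodes)
    if (nd.leaf) leafPoints += (int)nd.idx.size();
  return List::create(
      _["rootMass"] = tree.nodes[0].cumSize,
      _["rootCom"] = NumericVector::create(tree.nodes[0].comx,
                                           tree.nodes[0].comy),
      _["leafPoints"] = leafPoints, _["nNodes"] = (int)tree.nodes.size());
}

// Order-m Markov chain over {0,1,2,3} (A,C,G,T). `cumTrans` is the
// 4^m x 4 row-wise cumulative transition matrix, `init` the first m
// symbols, `unif` one U(0,1) draw per emitted symbol (R supplies the RNG
// so results follow R's seed machinery).
// [[Rcpp::export]]
IntegerVector markov_sequence_cpp(int len, int order, NumericMatrix cumTrans,
                                  IntegerVector init, NumericVector unif) {
  IntegerVector out(len);
  int nCtx = cumTrans.nrow();
  int ctx = 0;
  for (int i = 0; i < order; ++i) {
    out[i] = init[i];
    ctx = (ctx * 4 + init[i]) % nCtx;
  }
  for (int i = order; i < len; ++i) {
    double u = unif[i];
    int s = 0;
    while (s < 3 && u > cumTrans(ctx, s)) ++s;
    out[i] = s;
    ctx = (ctx * 4 + s) % nCtx;
  }
  return out;
}
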