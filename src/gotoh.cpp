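#include <Rcpp.h>
using namespace Rcpp;

// Three-state affine-gap global alignment (Gotoh) over a precomputed
// column-pair score matrix S (rows index profile/sequence A, columns B).
// A gap of length L costs gop + gep*(L-1); terminal gaps are penalized like
// internal ones. Switching directly between the two gap states opens a new
// gap (costs gop).
//
// Tie-breaking is fixed for determinism: on equal scores prefer the match
// state, then a gap in B (consume A), then a gap in A. The traceback
// re-evaluates the same comparisons as the forward pass, so identical
// inputs always yield an identical path.
//
// Returns list(score, path): path is an integer vector of moves from the
// start of the alignment, 1 = match column, 2 = gap in B, 3 = gap in A.

static const double NEG_INF = -1e300;

// [[Rcpp::export]]
List gotoh_align(NumericMatrix S, double gop, double gep) {
  const int la = S.nrow(), lb = S.ncol();
  if (la == 0 || lb == 0) stop("empty profile in alignment");
  NumericMatrix M(la + 1, lb + 1), X(la + 1, lb + 1), Y(la + 1, lb + 1);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= la; ++i) {
    M(i, 0) = Y(i, 0) = NEG_INF;
    X(i, 0) = -(gop + gep * (i - 1));
  }
  for (int j = 1; j <= lb; ++j) {
    M(0, j) = X(0, j) = NEG_INF;
    Y(0, j) = -(gop + gep * (j - 1));
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      double best = dm;
      if (dx > best) best = dx;
      if (dy > best) best = dy;
      M(i, j) = S(i - 1, j - 1) + best;

      double xm = M(i - 1, j) - gop, xx = X(i - 1, j) - gep, xy = Y(i - 1, j) - gop;
      best = xm;
      if (xx > best) best = xx;
      if (xy > best) best = xy;
      X(i, j) = best;

      double ym = M(i, j - 1) - gop, yx = X(i, j - 1) - gop, yy = Y(i, j - 1) - gep;
      best = ym;
      if (yx > best) best = yx;
      if (yy > best) best = yy;
      Y(i, j) = best;
    }
  }

  // final state: prefer M, then X, then Y on ties
  int state;
  double score;
  {
    double m = M(la, lb), x = X(la, lb), y = Y(la, lb);
    if (m >= x && m >= y) { state = 1; score = m; }
    else if (x >= y)      { state = 2; score = x; }
    else                  { state = 3; score = y; }
  }

  // preferred argmax (M > X > Y on ties) — replays the forward-pass choice
  auto pick = [](double m, double x, double y) {
    if (m >= x && m >= y) return 1;
    if (x >= y) return 2;
    return 3;
  };

  std::vector<int> rev;
  rev.reserve(la + lb);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 1) {
      rev.push_back(1);
      state = pick(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1));
      --i; --j;
    } else if (state == 2) {
      rev.push_back(2);
      state = pick(M(i - 1, j) - gop, X(i - 1, j) - gep, Y(i - 1, j) - gop);
      --i;
    } else {
      rev.push_back(3);
      state = pick(M(i, j - 1) - gop, X(i, j - 1) - gop, Y(i, j - 1) - gep);
      --j;
    }
  }

  IntegerVector path(rev.rbegin(), rev.rend());
  return List::create(_["score"] = score, _["path"] = path);
}
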