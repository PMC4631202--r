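// Exact rational arithmetic kernel and bounded-variable primal simplex.
//
// Rationals are stored as int64 numerator/denominator pairs (denominator > 0,
// always gcd-reduced); all intermediate products are taken in __int128 so they
// cannot overflow before reduction.  A denominator of 0 encodes +/- infinity
// (numerator +1/-1) and is only legal in bounds.  Any value whose reduced
// numerator or denominator would exceed 2^62, or which cannot cross the R
// boundary as an exactly-represented double, raises an R error rather than
// silently losing exactness.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

typedef long long ll;
typedef __int128 i128;

static const double DBL_EXACT_MAX = 9007199254740992.0; // 2^53
static const i128 RED_MAX = ((i128)1) << 62;

static inline i128 iabs128(i128 x) { return x < 0 ? -x : x; }

static i128 igcd(i128 a, i128 b) {
  a = iabs128(a); b = iabs128(b);
  while (b) { i128 t = a % b; a = b; b = t; }
  return a;
}

struct Rat {
  ll n, d; // d > 0 finite; d == 0 encodes infinity with n = +/-1
  bool finite() const { return d != 0; }
};

static const Rat R_ZERO = {0, 1};
static const Rat R_ONE  = {1, 1};
static const Rat R_PINF = {1, 0};
static const Rat R_NINF = {-1, 0};

static Rat mkrat(i128 n, i128 d) {
  if (d == 0) stop("exact arithmetic: division by zero");
  if (d < 0) { n = -n; d = -d; }
  if (n == 0) { Rat r; r.n = 0; r.d = 1; return r; }
  i128 g = igcd(n, d);
  if (g > 1) { n /= g; d /= g; }
  if (iabs128(n) >= RED_MAX || d >= RED_MAX)
    stop("exact arithmetic overflow: rational exceeds 64-bit storage");
  Rat r; r.n = (ll)n; r.d = (ll)d;
  return r;
}

static inline int infsign(const Rat& a) { return a.finite() ? 0 : (a.n > 0 ? 1 : -1); }

static Rat radd(const Rat& a, const Rat& b) {
  if (!a.finite() || !b.finite()) {
    int sa = infsign(a), sb = infsign(b);
    if (sa != 0 && sb != 0) {
      if (sa != sb) stop("exact arithmetic: inf - inf is undefined");
      return a;
    }
    return sa != 0 ? a : b;
  }
  return mkrat((i128)a.n * b.d + (i128)b.n * a.d, (i128)a.d * b.d);
}

static Rat rneg(const Rat& a) { Rat r; r.n = -a.n; r.d = a.d; return r; }

static Rat rsub(const Rat& a, const Rat& b) { return radd(a, rneg(b)); }

static Rat rmul(const Rat& a, const Rat& b) {
  if (!a.finite() || !b.finite()) {
    int sa = a.n < 0 ? -1 : (a.n > 0 ? 1 : 0);
    int sb = b.n < 0 ? -1 : (b.n > 0 ? 1 : 0);
    if (sa == 0 || sb == 0) stop("exact arithmetic: 0 * inf is undefined");
    return (sa * sb > 0) ? R_PINF : R_NINF;
  }
  return mkrat((i128)a.n * b.n, (i128)a.d * b.d);
}

static Rat rdiv(const Rat& a, const Rat& b) {
  if (!b.finite()) {
    if (!a.finite()) stop("exact arithmetic: inf / inf is undefined");
    return R_ZERO;
  }
  if (b.n == 0) stop("exact arithmetic: division by zero");
  if (!a.finite()) return (infsign(a) * (b.n > 0 ? 1 : -1) > 0) ? R_PINF : R_NINF;
  return mkrat((i128)a.n * b.d, (i128)a.d * b.n);
}

static int rcmp(const Rat& a, const Rat& b) {
  int sa = infsign(a), sb = infsign(b);
  if (sa != 0 || sb != 0) {
    if (sa < sb) return -1;
    if (sa > sb) return 1;
    return 0; // same infinity
  }
  i128 l = (i128)a.n * b.d, r = (i128)b.n * a.d;
  return l < r ? -1 : (l > r ? 1 : 0);
}

// ---- R <-> C++ conversion ---------------------------------------------------

static ll dbl_to_ll(double x) {
  if (!R_finite(x)) stop("exact arithmetic: non-finite component where integer expected");
  if (std::fabs(x) > 4.6e18) stop("exact arithmetic overflow: integer exceeds 64-bit range");
  ll v = (ll)x;
  if ((double)v != x)
    stop("exact arithmetic: %.17g is not an exactly represented integer", x);
  return v;
}

static Rat rat_in(double n, double d) {
  if (d == 0.0) {
    if (n > 0) return R_PINF;
    if (n < 0) return R_NINF;
    stop("invalid rational 0/0");
  }
  return mkrat((i128)dbl_to_ll(n), (i128)dbl_to_ll(d));
}

static void rat_out(const Rat& r, double& n, double& d) {
  if (!r.finite()) { n = (r.n > 0 ? 1.0 : -1.0); d = 0.0; return; }
  double dn = (double)r.n, dd = (double)r.d;
  if ((ll)dn != r.n || (ll)dd != r.d)
    stop("exact result exceeds the exactly representable double range");
  n = dn; d = dd;
}

static std::vector<Rat> vec_in(const NumericVector& n, const NumericVector& d) {
  if (n.size() != d.size()) stop("rational vector num/den length mismatch");
  std::vector<Rat> v(n.size());
  for (int i = 0; i < n.size(); ++i) v[i] = rat_in(n[i], d[i]);
  return v;
}

static List vec_out(const std::vector<Rat>& v) {
  NumericVector n(v.size()), d(v.size());
  for (size_t i = 0; i < v.size(); ++i) rat_out(v[i], n[i], d[i]);
  return List::create(_["num"] = n, _["den"] = d);
}

// ---- elementwise kernels ----------------------------------------------------

// [[Rcpp::export]]
List cpp_rat_reduce(NumericVector n, NumericVector d) {
  return vec_out(vec_in(n, d));
}

// [[Rcpp::export]]
List cpp_rat_elem(int op, NumericVector n1, NumericVector d1,
                  NumericVector n2, NumericVector d2) {
  std::vector<Rat> a = vec_in(n1, d1), b = vec_in(n2, d2);
  if (a.size() != b.size()) stop("length mismatch in rational arithmetic");
  std::vector<Rat> r(a.size());
  for (size_t i = 0; i < a.size(); ++i) {
    switch (op) {
      case 1: r[i] = radd(a[i], b[i]); break;
      case 2: r[i] = rsub(a[i], b[i]); break;
      case 3: r[i] = rmul(a[i], b[i]); break;
      case 4: r[i] = rdiv(a[i], b[i]); break;
      default: stop("unknown rational op");
    }
  }
  return vec_out(r);
}

// [[Rcpp::export]]
IntegerVector cpp_rat_compare(NumericVector n1, NumericVector d1,
                              NumericVector n2, NumericVector d2) {
  std::vector<Rat> a = vec_in(n1, d1), b = vec_in(n2, d2);
  if (a.size() != b.size()) stop("length mismatch in rational comparison");
  IntegerVector out(a.size());
  for (size_t i = 0; i < a.size(); ++i) out[i] = rcmp(a[i], b[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_rat_sum(NumericVector n, NumericVector d) {
  std::vector<Rat> a = vec_in(n, d);
  Rat s = R_ZERO;
  for (size_t i = 0; i < a.size(); ++i) s = radd(s, a[i]);
  std::vector<Rat> out(1, s);
  return vec_out(out);
}

// y = A x over rationals (A given as num/den matrices)
// [[Rcpp::export]]
List cpp_rat_matvec(NumericMatrix An, NumericMatrix Ad,
                    NumericVector xn, NumericVector xd) {
  int m = An.nrow(), n = An.ncol();
  if (Ad.nrow() != m || Ad.ncol() != n) stop("matrix num/den shape mismatch");
  std::vector<Rat> x = vec_in(xn, xd);
  if ((int)x.size() != n) stop("matvec dimension mismatch");
  std::vector<Rat> y(m, R_ZERO);
  for (int i = 0; i < m; ++i) {
    Rat s = R_ZERO;
    for (int j = 0; j < n; ++j) {
      if (An(i, j) == 0.0) continue;
      s = radd(s, rmul(rat_in(An(i, j), Ad(i, j)), x[j]));
    }
    y[i] = s;
  }
  return vec_out(y);
}

// Exact conversion of an IEEE double to p/q (the float_bits mapping).
// [[Rcpp::export]]
List cpp_float_to_rat(NumericVector x) {
  int n = x.size();
  std::vector<Rat> out(n);
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    if (!R_finite(v)) stop("float_bits rationalization requires finite values");
    int e;
    double m = std::frexp(v, &e); // v = m * 2^e, |m| in [0.5, 1)
    // scale mantissa to an integer (at most 53 doublings)
    int k = 0;
    while (m != std::floor(m)) { m *= 2.0; ++k; }
    i128 num = (i128)(ll)m;
    int ex = e - k;
    i128 den = 1;
    while (ex > 0) { num *= 2; --ex; if (iabs128(num) >= RED_MAX) stop("exact arithmetic overflow in float conversion"); }
    while (ex < 0) { den *= 2; ++ex; if (den >= RED_MAX) stop("exact arithmetic overflow in float conversion"); }
    out[i] = mkrat(num, den);
  }
  return vec_out(out);
}

// ---- reduced row echelon form (exact) --------------------------------------

// [[Rcpp::export]]
List cpp_rat_rref(NumericMatrix An, NumericMatrix Ad) {
  int m = An.nrow(), n = An.ncol();
  std::vector<Rat> T((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) T[(size_t)i * n + j] = rat_in(An(i, j), Ad(i, j));
  std::vector<int> pivots;
  int lead = 0;
  for (int col = 0; col < n && lead < m; ++col) {
    int p = -1;
    for (int i = lead; i < m; ++i)
      if (T[(size_t)i * n + col].n != 0) { p = i; break; }
    if (p < 0) continue;
    if (p != lead)
      for (int j = 0; j < n; ++j) std::swap(T[(size_t)p * n + j], T[(size_t)lead * n + j]);
    Rat piv = T[(size_t)lead * n + col];
    for (int j = 0; j < n; ++j) T[(size_t)lead * n + j] = rdiv(T[(size_t)lead * n + j], piv);
    for (int i = 0; i < m; ++i) {
      if (i == lead) continue;
      Rat f = T[(size_t)i * n + col];
      if (f.n == 0) continue;
      for (int j = 0; j < n; ++j)
        T[(size_t)i * n + j] = rsub(T[(size_t)i * n + j], rmul(f, T[(size_t)lead * n + j]));
    }
    pivots.push_back(col + 1);
    ++lead;
  }
  NumericMatrix Rn(m, n), Rd(m, n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) rat_out(T[(size_t)i * n + j], Rn(i, j), Rd(i, j));
  return List::create(_["num"] = Rn, _["den"] = Rd,
                      _["pivots"] = IntegerVector(pivots.begin(), pivots.end()));
}

// ---- bounded-variable primal simplex, templated on the coefficient field ----

struct FieldRat {
  typedef Rat V;
  static V zero() { return R_ZERO; }
  static V one()  { return R_ONE; }
  static V pinf() { return R_PINF; }
  static V ninf() { return R_NINF; }
  static bool finite(const V& a) { return a.finite(); }
  static V add(const V& a, const V& b) { return radd(a, b); }
  static V sub(const V& a, const V& b) { return rsub(a, b); }
  static V mul(const V& a, const V& b) { return rmul(a, b); }
  static V div(const V& a, const V& b) { return rdiv(a, b); }
  static V neg(const V& a) { return rneg(a); }
  static int sgn(const V& a) { return a.n < 0 ? -1 : (a.n > 0 ? 1 : 0); } // finite only
  static int fsgn(const V& a) { return sgn(a); }
  static int cmp(const V& a, const V& b) { return rcmp(a, b); }
  static bool is_zero(const V& a) { return a.finite() && a.n == 0; }
};

struct FieldDbl {
  typedef double V;
  static double tol;      // sign decisions on reduced costs / pivots
  static double feastol;  // phase-1 feasibility verdict
  static V zero() { return 0.0; }
  static V one()  { return 1.0; }
  static V pinf() { return R_PosInf; }
  static V ninf() { return R_NegInf; }
  static bool finite(const V& a) { return R_finite(a); }
  static V add(V a, V b) { return a + b; }
  static V sub(V a, V b) { return a - b; }
  static V mul(V a, V b) { return a * b; }
  static V div(V a, V b) { return a / b; }
  static V neg(V a) { return -a; }
  static int sgn(V a) { return a > tol ? 1 : (a < -tol ? -1 : 0); }
  static int fsgn(V a) { return a > feastol ? 1 : (a < -feastol ? -1 : 0); }
  static int cmp(V a, V b) { return a < b ? -1 : (a > b ? 1 : 0); }
  static bool is_zero(V a) { return a == 0.0; }
};
double FieldDbl::tol = 1e-9;
double FieldDbl::feastol = 1e-7;

enum VStat { AT_LB = 0, AT_UB = 1, FREE_NB = 2, BASIC = 3 };

template <class F>
struct Simplex {
  typedef typename F::V V;
  int m, n, N; // rows, structural cols, total cols (n + m artificials)
  std::vector<V> T;     // m x N tableau = B^-1 [A | I]
  std::vector<V> xval;  // current value of every variable
  std::vector<V> lb, ub;
  std::vector<V> obj;   // current-phase objective
  std::vector<int> basis;   // row -> column
  std::vector<int> status;  // column -> VStat
  long iters = 0, maxit;

  V& at(int i, int j) { return T[(size_t)i * N + j]; }

  // 0 optimal-for-phase, 2 unbounded, 3 iteration limit
  int iterate() {
    std::vector<V> y(m);
    for (;;) {
      if (iters++ >= maxit) return 3;
      for (int i = 0; i < m; ++i) y[i] = obj[basis[i]];
      int enter = -1, dir = 0;
      for (int j = 0; j < N; ++j) {
        if (status[j] == BASIC) continue;
        if (F::cmp(lb[j], ub[j]) == 0) continue; // fixed
        V z = obj[j];
        for (int i = 0; i < m; ++i) {
          if (F::is_zero(y[i])) continue;
          z = F::sub(z, F::mul(y[i], at(i, j)));
        }
        int s = F::sgn(z);
        if (s > 0 && (status[j] == AT_LB || status[j] == FREE_NB)) { enter = j; dir = 1; break; }
        if (s < 0 && (status[j] == AT_UB || status[j] == FREE_NB)) { enter = j; dir = -1; break; }
      }
      if (enter < 0) return 0; // optimal for this phase

      // ratio test: how far can the entering variable move?
      V tmin;
      bool tmin_inf;
      if (dir > 0) { tmin_inf = !F::finite(ub[enter]); tmin = tmin_inf ? F::pinf() : F::sub(ub[enter], xval[enter]); }
      else         { tmin_inf = !F::finite(lb[enter]); tmin = tmin_inf ? F::pinf() : F::sub(xval[enter], lb[enter]); }
      int leave = -1, leave_bound = AT_LB;
      for (int i = 0; i < m; ++i) {
        V d = at(i, enter);
        int sd = F::sgn(d);
        if (sd == 0) continue;
        int bi = basis[i];
        V lim; int hb;
        if (dir * sd > 0) { // basic variable decreases toward its lower bound
          if (!F::finite(lb[bi])) continue;
          V rate = (dir > 0) ? d : F::neg(d);
          lim = F::div(F::sub(xval[bi], lb[bi]), rate);
          hb = AT_LB;
        } else {            // basic variable increases toward its upper bound
          if (!F::finite(ub[bi])) continue;
          V rate = (dir > 0) ? F::neg(d) : d;
          lim = F::div(F::sub(ub[bi], xval[bi]), rate);
          hb = AT_UB;
        }
        if (F::cmp(lim, F::zero()) < 0) lim = F::zero(); // numerical guard (float path)
        int c = tmin_inf ? -1 : F::cmp(lim, tmin);
        if (c < 0 || (c == 0 && leave >= 0 && bi < basis[leave])) {
          tmin = lim; tmin_inf = false; leave = i; leave_bound = hb;
        }
      }
      if (tmin_inf) return 2; // unbounded

      V t = tmin;
      // update variable values along the edge
      for (int i = 0; i < m; ++i) {
        V d = at(i, enter);
        if (F::is_zero(d)) continue;
        V delta = F::mul(t, d);
        xval[basis[i]] = (dir > 0) ? F::sub(xval[basis[i]], delta) : F::add(xval[basis[i]], delta);
      }
      xval[enter] = (dir > 0) ? F::add(xval[enter], t) : F::sub(xval[enter], t);

      if (leave < 0) { // entering variable flipped to its opposite bound
        status[enter] = (dir > 0) ? AT_UB : AT_LB;
        xval[enter] = (dir > 0) ? ub[enter] : lb[enter]; // snap exactly
        continue;
      }
      int lv = basis[leave];
      status[lv] = leave_bound;
      xval[lv] = (leave_bound == AT_LB) ? lb[lv] : ub[lv]; // snap exactly
      // pivot the tableau on (leave, enter)
      V piv = at(leave, enter);
      for (int j = 0; j < N; ++j) at(leave, j) = F::div(at(leave, j), piv);
      for (int i = 0; i < m; ++i) {
        if (i == leave) continue;
        V f = at(i, enter);
        if (F::is_zero(f)) continue;
        for (int j = 0; j < N; ++j)
          at(i, j) = F::sub(at(i, j), F::mul(f, at(leave, j)));
      }
      basis[leave] = enter;
      status[enter] = BASIC;
    }
  }

  // returns: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
  int solve(const std::vector<V>& A, const std::vector<V>& b, const std::vector<V>& c) {
    N = n + m;
    T.assign((size_t)m * N, F::zero());
    for (int i = 0; i < m; ++i) {
      for (int j = 0; j < n; ++j) at(i, j) = A[(size_t)i * n + j];
      at(i, n + i) = F::one();
    }
    xval.assign(N, F::zero());
    status.assign(N, AT_LB);
    for (int j = 0; j < n; ++j) {
      if (F::finite(lb[j])) { status[j] = AT_LB; xval[j] = lb[j]; }
      else if (F::finite(ub[j])) { status[j] = AT_UB; xval[j] = ub[j]; }
      else { status[j] = FREE_NB; xval[j] = F::zero(); }
    }
    // artificial variables pick up the residual of each equality row
    basis.resize(m);
    obj.assign(N, F::zero());
    bool need_phase1 = false;
    for (int i = 0; i < m; ++i) {
      V r = b[i];
      for (int j = 0; j < n; ++j) {
        if (F::is_zero(A[(size_t)i * n + j])) continue;
        r = F::sub(r, F::mul(A[(size_t)i * n + j], xval[j]));
      }
      int k = n + i;
      xval[k] = r;
      if (F::sgn(r) >= 0) { lb[k] = F::zero(); ub[k] = F::pinf(); obj[k] = F::neg(F::one()); }
      else                { lb[k] = F::ninf(); ub[k] = F::zero(); obj[k] = F::one(); }
      if (F::sgn(r) != 0) need_phase1 = true;
      basis[i] = k;
      status[k] = BASIC;
    }
    if (need_phase1) {
      int rc = iterate();
      if (rc == 3) return 3;
      if (rc == 2) return 2; // cannot happen for the bounded phase-1 objective; be safe
      V p1 = F::zero();
      for (int k = n; k < N; ++k) p1 = F::add(p1, F::mul(obj[k], xval[k]));
      if (F::fsgn(p1) < 0) return 1; // infeasible
    }
    // lock the artificials at zero and switch to the real objective
    for (int k = n; k < N; ++k) { lb[k] = F::zero(); ub[k] = F::zero(); xval[k] = F::zero(); }
    obj = std::vector<V>(N, F::zero());
    for (int j = 0; j < n; ++j) obj[j] = c[j];
    return iterate();
  }
};

static const char* status_label(int rc) {
  switch (rc) {
    case 0: return "optimal";
    case 1: return "infeasible";
    case 2: return "unbounded";
    default: return "iteration_limit";
  }
}

// [[Rcpp::export]]
List cpp_simplex_rat(NumericMatrix An, NumericMatrix Ad,
                     NumericVector bn, NumericVector bd,
                     NumericVector cn, NumericVector cd,
                     NumericVector ln, NumericVector ld,
                     NumericVector un, NumericVector ud,
                     double maxit) {
  Simplex<FieldRat> S;
  S.m = An.nrow(); S.n = An.ncol();
  S.maxit = (long)maxit;
  std::vector<Rat> A((size_t)S.m * S.n);
  for (int i = 0; i < S.m; ++i)
    for (int j = 0; j < S.n; ++j) A[(size_t)i * S.n + j] = rat_in(An(i, j), Ad(i, j));
  std::vector<Rat> b = vec_in(bn, bd), c = vec_in(cn, cd);
  S.lb = vec_in(ln, ld); S.ub = vec_in(un, ud);
  S.lb.resize(S.n + S.m, R_ZERO); S.ub.resize(S.n + S.m, R_ZERO);
  int rc = S.solve(A, b, c);
  std::vector<Rat> x(S.n, R_ZERO);
  Rat objv = R_ZERO;
  IntegerVector vstat(S.n);
  if (rc == 0) {
    for (int j = 0; j < S.n; ++j) { x[j] = S.xval[j]; objv = radd(objv, rmul(c[j], x[j])); vstat[j] = S.status[j]; }
  }
  List xo = vec_out(x);
  double on, od; rat_out(objv, on, od);
  return List::create(_["status"] = status_label(rc),
                      _["xnum"] = xo["num"], _["xden"] = xo["den"],
                      _["objnum"] = on, _["objden"] = od,
                      _["iterations"] = (double)S.iters,
                      _["vstat"] = vstat);
}

// [[Rcpp::export]]
List cpp_simplex_dbl(NumericMatrix A, NumericVector b, NumericVector c,
                     NumericVector l, NumericVector u, double maxit) {
  Simplex<FieldDbl> S;
  S.m = A.nrow(); S.n = A.ncol();
  S.maxit = (long)maxit;
  std::vector<double> Av((size_t)S.m * S.n);
  for (int i = 0; i < S.m; ++i)
    for (int j = 0; j < S.n; ++j) Av[(size_t)i * S.n + j] = A(i, j);
  std::vector<double> bv(b.begin(), b.end()), cv(c.begin(), c.end());
  S.lb.assign(l.begin(), l.end()); S.ub.assign(u.begin(), u.end());
  S.lb.resize(S.n + S.m, 0.0); S.ub.resize(S.n + S.m, 0.0);
  int rc = S.solve(Av, bv, cv);
  NumericVector x(S.n);
  double objv = 0.0;
  if (rc == 0)
    for (int j = 0; j < S.n; ++j) { x[j] = S.xval[j]; objv += cv[j] * x[j]; }
  return List::create(_["status"] = status_label(rc),
                      _["x"] = x, _["objective"] = objv,
                      _["iterations"] = (double)S.iters);
}
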