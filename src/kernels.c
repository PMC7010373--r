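/* Outwardly rounded interval arithmetic kernels.
 *
 * Endpoint arithmetic for +, -, *, / uses error-free transformations
 * (two-sum, fma residuals) to decide whether the IEEE round-to-nearest
 * result lies on the wrong side of the exact value; only then is the
 * endpoint stepped to the adjacent float.  This gives the tightest
 * representable directed rounding.  pow/exp/log results are widened by two
 * ulps per endpoint, which covers the <= 1 ulp error of any reasonable
 * libm.  Near the subnormal range the residual tricks lose exactness, so a
 * full outward step is taken unconditionally there.
 *
 * An empty interval is encoded as [NA, NA]; kernels propagate it.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <float.h>

#define SUBNORMAL_GUARD (4.0 * DBL_MIN)

static double step_down(double x) { return nextafter(x, -INFINITY); }
static double step_up(double x)   { return nextafter(x,  INFINITY); }

static double add_down(double a, double b)
{
    double s = a + b;
    if (!R_FINITE(s)) {
        if (ISNAN(s)) return s;
        if (s > 0 && R_FINITE(a) && R_FINITE(b)) return DBL_MAX; /* overflow */
        return s;
    }
    double bb = s - a;
    double err = (a - (s - bb)) + (b - bb);   /* exact: two-sum residual */
    return (err < 0) ? step_down(s) : s;
}

static double add_up(double a, double b)
{
    double s = a + b;
    if (!R_FINITE(s)) {
        if (ISNAN(s)) return s;
        if (s < 0 && R_FINITE(a) && R_FINITE(b)) return -DBL_MAX;
        return s;
    }
    double bb = s - a;
    double err = (a - (s - bb)) + (b - bb);
    return (err > 0) ? step_up(s) : s;
}

static double sub_down(double a, double b) { return add_down(a, -b); }
static double sub_up(double a, double b)   { return add_up(a, -b); }

static double mul_down(double a, double b)
{
    if (a == 0.0 || b == 0.0) return 0.0;  /* exact; also fixes 0 * inf */
    double p = a * b;
    if (!R_FINITE(p)) {
        if (ISNAN(p)) return p;
        if (p > 0 && R_FINITE(a) && R_FINITE(b)) return DBL_MAX;
        return p;
    }
    if (fabs(p) < SUBNORMAL_GUARD) return step_down(p);
    double err = fma(a, b, -p);               /* exact for normal p */
    return (err < 0) ? step_down(p) : p;
}

static double mul_up(double a, double b)
{
    if (a == 0.0 || b == 0.0) return 0.0;
    double p = a * b;
    if (!R_FINITE(p)) {
        if (ISNAN(p)) return p;
        if (p < 0 && R_FINITE(a) && R_FINITE(b)) return -DBL_MAX;
        return p;
    }
    if (fabs(p) < SUBNORMAL_GUARD) return step_up(p);
    double err = fma(a, b, -p);
    return (err > 0) ? step_up(p) : p;
}

/* caller guarantees b != 0 */
static double div_down(double a, double b)
{
    if (a == 0.0) return 0.0;
    double q = a / b;
    if (!R_FINITE(q)) {
        if (ISNAN(q)) return q;
        if (q > 0 && R_FINITE(a) && R_FINITE(b)) return DBL_MAX;
        return q;
    }
    if (!R_FINITE(a) || !R_FINITE(b) ||
        fabs(q) < SUBNORMAL_GUARD || fabs(a) < SUBNORMAL_GUARD)
        return step_down(q);
    double r = fma(q, b, -a);                 /* q*b - a, exact */
    if (r == 0.0) return q;
    /* exact - q = -r/b */
    return ((r > 0) == (b > 0)) ? step_down(q) : q;
}

static double div_up(double a, double b)
{
    if (a == 0.0) return 0.0;
    double q = a / b;
    if (!R_FINITE(q)) {
        if (ISNAN(q)) return q;
        if (q < 0 && R_FINITE(a) && R_FINITE(b)) return -DBL_MAX;
        return q;
    }
    if (!R_FINITE(a) || !R_FINITE(b) ||
        fabs(q) < SUBNORMAL_GUARD || fabs(a) < SUBNORMAL_GUARD)
        return step_up(q);
    double r = fma(q, b, -a);
    if (r == 0.0) return q;
    return ((r < 0) == (b > 0)) ? step_up(q) : q;
}

/* point power with y > 0 or x in exact-case list; two-ulp widening */
static double pow_pt_down(double x, double y)
{
    if (y == 0.0 || x == 1.0) return 1.0;
    if (y == 1.0) return x;
    if (x == 0.0) return 0.0;                 /* 0^y = 0 for y > 0 */
    double p = pow(x, y);
    if (!R_FINITE(p)) {
        if (ISNAN(p)) return p;
        return (p > 0) ? DBL_MAX : p;
    }
    p = step_down(step_down(p));
    if (x > 0 && p < 0) p = 0.0;              /* positive base: power > 0 */
    return p;
}

static double pow_pt_up(double x, double y)
{
    if (y == 0.0 || x == 1.0) return 1.0;
    if (y == 1.0) return x;
    if (x == 0.0) return 0.0;
    double p = pow(x, y);
    if (!R_FINITE(p)) {
        if (ISNAN(p)) return p;
        return (p < 0) ? -DBL_MAX : p;
    }
    return step_up(step_up(p));
}

static double exp_down(double x)
{
    if (x == 0.0) return 1.0;
    double e = exp(x);
    if (e == R_PosInf) e = DBL_MAX;
    e = step_down(step_down(e));
    return (e < 0) ? 0.0 : e;
}

static double exp_up(double x)
{
    if (x == 0.0) return 1.0;
    double e = exp(x);
    if (e == R_PosInf) return e;
    return step_up(step_up(e));
}

static double log_down(double x)
{
    if (x == 1.0) return 0.0;
    if (x == R_PosInf) return R_PosInf;
    return step_down(step_down(log(x)));
}

static double log_up(double x)
{
    if (x == 1.0) return 0.0;
    if (x == R_PosInf) return R_PosInf;
    return step_up(step_up(log(x)));
}

/* ------------------------------------------------------------------ */
/* interval layer                                                      */

typedef struct { double lo, hi; } iv;

static iv mk(double lo, double hi) { iv r; r.lo = lo; r.hi = hi; return r; }
static int iv_na(iv x) { return ISNAN(x.lo) || ISNAN(x.hi); }
static iv iv_empty(void) { return mk(NA_REAL, NA_REAL); }

static iv iv_add(iv x, iv y)
{
    if (iv_na(x) || iv_na(y)) return iv_empty();
    return mk(add_down(x.lo, y.lo), add_up(x.hi, y.hi));
}

static iv iv_sub(iv x, iv y)
{
    if (iv_na(x) || iv_na(y)) return iv_empty();
    return mk(sub_down(x.lo, y.hi), sub_up(x.hi, y.lo));
}

static iv iv_neg(iv x)
{
    if (iv_na(x)) return iv_empty();
    return mk(-x.hi, -x.lo);
}

static double min4(double a, double b, double c, double d)
{
    double m = a;
    if (b < m) m = b;
    if (c < m) m = c;
    if (d < m) m = d;
    return m;
}

static double max4(double a, double b, double c, double d)
{
    double m = a;
    if (b > m) m = b;
    if (c > m) m = c;
    if (d > m) m = d;
    return m;
}

static iv iv_mul(iv x, iv y)
{
    if (iv_na(x) || iv_na(y)) return iv_empty();
    double lo = min4(mul_down(x.lo, y.lo), mul_down(x.lo, y.hi),
                     mul_down(x.hi, y.lo), mul_down(x.hi, y.hi));
    double hi = max4(mul_up(x.lo, y.lo), mul_up(x.lo, y.hi),
                     mul_up(x.hi, y.lo), mul_up(x.hi, y.hi));
    return mk(lo, hi);
}

static iv iv_div(iv x, iv y)
{
    if (iv_na(x) || iv_na(y)) return iv_empty();
    if (y.lo <= 0 && y.hi >= 0)
        Rf_error("interval division by an interval containing zero");
    double lo = min4(div_down(x.lo, y.lo), div_down(x.lo, y.hi),
                     div_down(x.hi, y.lo), div_down(x.hi, y.hi));
    double hi = max4(div_up(x.lo, y.lo), div_up(x.lo, y.hi),
                     div_up(x.hi, y.lo), div_up(x.hi, y.hi));
    return mk(lo, hi);
}

/* general power, domain y.lo > 0, x.lo >= 0 (checked by caller) */
static iv iv_pow(iv x, iv y)
{
    if (iv_na(x) || iv_na(y)) return iv_empty();
    double lo = min4(pow_pt_down(x.lo, y.lo), pow_pt_down(x.lo, y.hi),
                     pow_pt_down(x.hi, y.lo), pow_pt_down(x.hi, y.hi));
    double hi = max4(pow_pt_up(x.lo, y.lo), pow_pt_up(x.lo, y.hi),
                     pow_pt_up(x.hi, y.lo), pow_pt_up(x.hi, y.hi));
    return mk(lo, hi);
}

/* directed x^n for x >= 0, integer n >= 2: a multiplication chain keeps
 * exactly representable powers exact; large n falls back to libm pow with
 * two-ulp widening */
static double powi_dir(double x, long n, int up)
{
    if (n > 64) return up ? pow_pt_up(x, (double) n)
                          : pow_pt_down(x, (double) n);
    double r = x;
    for (long k = 1; k < n; k++)
        r = up ? mul_up(r, x) : mul_down(r, x);
    return r;
}

/* x^n for integer n; any sign of x, n >= 0 handled by parity,
 * n < 0 via reciprocal (requires 0 not in x) */
static iv iv_pown(iv x, long n)
{
    if (iv_na(x)) return iv_empty();
    if (n < 0) return iv_div(mk(1.0, 1.0), iv_pown(x, -n));
    if (n == 0) return mk(1.0, 1.0);
    if (n == 1) return x;
    if (n % 2 == 1 || x.lo >= 0.0) {
        /* monotone increasing on the whole line (odd) or on [0,inf) */
        double lo = (x.lo >= 0) ? powi_dir(x.lo, n, 0)
                                : -powi_dir(-x.lo, n, 1);
        double hi = (x.hi >= 0) ? powi_dir(x.hi, n, 1)
                                : -powi_dir(-x.hi, n, 0);
        return mk(lo, hi);
    }
    if (x.hi <= 0.0)    /* even n, negative interval: decreasing */
        return mk(powi_dir(-x.hi, n, 0), powi_dir(-x.lo, n, 1));
    /* even n, straddling zero */
    double m = fmax(-x.lo, x.hi);
    return mk(0.0, powi_dir(m, n, 1));
}

static iv iv_exp(iv x)
{
    if (iv_na(x)) return iv_empty();
    return mk(exp_down(x.lo), exp_up(x.hi));
}

static iv iv_log(iv x)
{
    if (iv_na(x)) return iv_empty();
    if (x.lo <= 0) Rf_error("log of an interval with non-positive lower bound");
    return mk(log_down(x.lo), log_up(x.hi));
}

/* power with real exponent held as an interval; integer point exponents go
 * through the parity rule (valid for bases touching or crossing zero) */
static iv iv_pow_real(iv x, iv a)
{
    if (a.lo == a.hi && a.lo == floor(a.lo) && fabs(a.lo) < 2147483647.0)
        return iv_pown(x, (long) a.lo);
    if (iv_na(x) || iv_na(a)) return iv_empty();
    if (x.lo < 0) Rf_error("general interval power needs a non-negative base");
    if (a.hi < 0) {
        /* x^a = 1 / x^(-a); a base touching zero gives an unbounded bound */
        iv y = iv_pow_real(x, iv_neg(a));
        double lo = (y.hi == R_PosInf) ? 0.0 : div_down(1.0, y.hi);
        double hi = (y.lo > 0.0) ? div_up(1.0, y.lo) : R_PosInf;
        return mk(lo, hi);
    }
    if (a.lo <= 0) Rf_error("general interval power needs an exponent of one sign");
    return iv_pow(x, a);
}

static iv iv_clamp01(iv x)
{
    if (iv_na(x)) return x;
    if (x.lo < 0) x.lo = 0.0;
    if (x.hi > 1) x.hi = 1.0;
    if (x.lo > x.hi) {
        /* can only happen when the enclosure lay entirely outside [0,1],
           which a valid cdf enclosure never does */
        Rf_error("internal error: cdf enclosure outside [0,1]");
    }
    return x;
}

/* ------------------------------------------------------------------ */
/* interval differential numbers (value, first derivative)             */

typedef struct { iv v, d; } di;

static di dmk(iv v, iv d) { di r; r.v = v; r.d = d; return r; }
static di di_const(iv v) { return dmk(v, mk(0.0, 0.0)); }

static di di_add(di f, di g) { return dmk(iv_add(f.v, g.v), iv_add(f.d, g.d)); }
static di di_sub(di f, di g) { return dmk(iv_sub(f.v, g.v), iv_sub(f.d, g.d)); }

static di di_mul(di f, di g)
{
    return dmk(iv_mul(f.v, g.v),
               iv_add(iv_mul(f.d, g.v), iv_mul(f.v, g.d)));
}

static di di_div(di f, di g)
{
    iv v = iv_div(f.v, g.v);
    iv num = iv_sub(iv_mul(f.d, g.v), iv_mul(f.v, g.d));
    return dmk(v, iv_div(num, iv_pown(g.v, 2)));
}

/* f^c with a constant exponent enclosed by the interval c:
 * d = c * f^(c-1) * f' */
static di di_pow_iv(di f, iv c)
{
    iv v = iv_pow_real(f.v, c);
    if (c.lo == 0.0 && c.hi == 0.0) return dmk(v, mk(0.0, 0.0));
    iv w = iv_pow_real(f.v, iv_sub(c, mk(1.0, 1.0)));
    return dmk(v, iv_mul(iv_mul(c, w), f.d));
}

static di di_pow_const(di f, double c) { return di_pow_iv(f, mk(c, c)); }

/* general f^g, f > 0: d = f^g (g' log f + g f'/f) */
static di di_pow_gen(di f, di g)
{
    if (!iv_na(f.v) && f.v.lo <= 0)
        Rf_error("differential power f^g needs f > 0");
    iv v = iv_pow(f.v, g.v);
    iv t = iv_add(iv_mul(g.d, iv_log(f.v)),
                  iv_mul(g.v, iv_div(f.d, f.v)));
    return dmk(v, iv_mul(v, t));
}

static di di_exp(di f)
{
    iv v = iv_exp(f.v);
    return dmk(v, iv_mul(v, f.d));
}

static di di_log(di f)
{
    iv v = iv_log(f.v);
    return dmk(v, iv_div(f.d, f.v));
}

static di di_neg(di f) { return dmk(iv_neg(f.v), iv_neg(f.d)); }

static di di_mul_iv(di f, iv c)   /* constant interval multiple */
{
    return dmk(iv_mul(f.v, c), iv_mul(f.d, c));
}

/* ------------------------------------------------------------------ */
/* closed-form beta cdf evaluators                                     */
/* I_x(a,b) = x^a (1 + sum_{n=1}^{b-1} p_n (1-x)^n),                   */
/*   p_n = p_{n-1} (a+n-1)/n  (incremental, overflow-safe)             */

static iv central_beta_iv(iv x, iv a, int b)
{
    iv one = mk(1.0, 1.0);
    iv u = iv_sub(one, x);
    iv s = one, p = one, q = one;
    for (int n = 1; n < b; n++) {
        iv num = iv_add(a, mk((double)(n - 1), (double)(n - 1)));
        p = iv_div(iv_mul(p, num), mk((double) n, (double) n));
        q = iv_mul(q, u);
        s = iv_add(s, iv_mul(p, q));
    }
    return iv_clamp01(iv_mul(iv_pow_real(x, a), s));
}

/* same, differentiating with respect to x */
static di central_beta_di(di x, iv a, int b)
{
    di one = di_const(mk(1.0, 1.0));
    di u = di_sub(one, x);
    di s = one, q = one;
    iv p = mk(1.0, 1.0);
    for (int n = 1; n < b; n++) {
        iv num = iv_add(a, mk((double)(n - 1), (double)(n - 1)));
        p = iv_div(iv_mul(p, num), mk((double) n, (double) n));
        q = di_mul(q, u);
        s = di_add(s, di_mul_iv(q, p));
    }
    di r = di_mul(di_pow_iv(x, a), s);
    r.v = iv_clamp01(r.v);
    return r;
}

/* I_x(a,b;lambda) = exp(-z) sum_{i=0}^{b-1} (z^i/i!) I_x(a+i, b-i),
 * z = (lambda/2)(1-x); term recurrence t_i = t_{i-1} z / i */
static iv noncentral_beta_iv(iv x, iv a, int b, iv lam)
{
    iv half = mk(0.5, 0.5);
    iv u = iv_sub(mk(1.0, 1.0), x);
    iv z = iv_mul(iv_mul(lam, half), u);
    iv t = mk(1.0, 1.0);
    iv s = central_beta_iv(x, a, b);  /* i = 0 term, no z^0 formed */
    for (int i = 1; i < b; i++) {
        t = iv_div(iv_mul(t, z), mk((double) i, (double) i));
        iv ai = iv_add(a, mk((double) i, (double) i));
        s = iv_add(s, iv_mul(t, central_beta_iv(x, ai, b - i)));
    }
    return iv_clamp01(iv_mul(iv_exp(iv_neg(z)), s));
}

/* noncentral cdf differentiated with respect to lambda (x is a thick
 * constant interval) */
static di noncentral_beta_dlam(di lam, iv x, iv a, int b)
{
    iv half = mk(0.5, 0.5);
    iv u = iv_sub(mk(1.0, 1.0), x);
    di z = di_mul_iv(lam, iv_mul(half, u));
    di t = di_const(mk(1.0, 1.0));
    di s = di_const(central_beta_iv(x, a, b));
    for (int i = 1; i < b; i++) {
        t = di_mul(t, z);
        t = dmk(iv_div(t.v, mk((double) i, (double) i)),
                iv_div(t.d, mk((double) i, (double) i)));
        iv ai = iv_add(a, mk((double) i, (double) i));
        iv ci = central_beta_iv(x, ai, b - i);
        s = di_add(s, di_mul_iv(t, ci));
    }
    di r = di_mul(di_exp(di_neg(z)), s);
    r.v = iv_clamp01(r.v);
    return r;
}

/* ------------------------------------------------------------------ */
/* .Call glue                                                          */

static iv get_iv(SEXP s)
{
    if (TYPEOF(s) != REALSXP || XLENGTH(s) != 2)
        Rf_error("expected a length-2 numeric (interval) argument");
    return mk(REAL(s)[0], REAL(s)[1]);
}

static di get_di(SEXP s)
{
    if (TYPEOF(s) != REALSXP || XLENGTH(s) != 4)
        Rf_error("expected a length-4 numeric (differential interval) argument");
    return dmk(mk(REAL(s)[0], REAL(s)[1]), mk(REAL(s)[2], REAL(s)[3]));
}

static SEXP put_iv(iv x)
{
    SEXP r = PROTECT(Rf_allocVector(REALSXP, 2));
    REAL(r)[0] = x.lo; REAL(r)[1] = x.hi;
    UNPROTECT(1);
    return r;
}

static SEXP put_di(di x)
{
    SEXP r = PROTECT(Rf_allocVector(REALSXP, 4));
    REAL(r)[0] = x.v.lo; REAL(r)[1] = x.v.hi;
    REAL(r)[2] = x.d.lo; REAL(r)[3] = x.d.hi;
    UNPROTECT(1);
    return r;
}

SEXP C_iv_add(SEXP x, SEXP y) { return put_iv(iv_add(get_iv(x), get_iv(y))); }
SEXP C_iv_sub(SEXP x, SEXP y) { return put_iv(iv_sub(get_iv(x), get_iv(y))); }
SEXP C_iv_neg(SEXP x)         { return put_iv(iv_neg(get_iv(x))); }
SEXP C_iv_mul(SEXP x, SEXP y) { return put_iv(iv_mul(get_iv(x), get_iv(y))); }
SEXP C_iv_div(SEXP x, SEXP y) { return put_iv(iv_div(get_iv(x), get_iv(y))); }
SEXP C_iv_exp(SEXP x)         { return put_iv(iv_exp(get_iv(x))); }
SEXP C_iv_log(SEXP x)         { return put_iv(iv_log(get_iv(x))); }

SEXP C_iv_pow(SEXP x, SEXP y)
{
    iv xx = get_iv(x), yy = get_iv(y);
    return put_iv(iv_pow_real(xx, yy));
}

SEXP C_iv_pown(SEXP x, SEXP n)
{
    double nn = Rf_asReal(n);
    if (!R_FINITE(nn) || nn != floor(nn))
        Rf_error("integer power exponent must be integral");
    return put_iv(iv_pown(get_iv(x), (long) nn));
}

SEXP C_di_add(SEXP f, SEXP g) { return put_di(di_add(get_di(f), get_di(g))); }
SEXP C_di_sub(SEXP f, SEXP g) { return put_di(di_sub(get_di(f), get_di(g))); }
SEXP C_di_neg(SEXP f)         { return put_di(di_neg(get_di(f))); }
SEXP C_di_mul(SEXP f, SEXP g) { return put_di(di_mul(get_di(f), get_di(g))); }
SEXP C_di_div(SEXP f, SEXP g) { return put_di(di_div(get_di(f), get_di(g))); }
SEXP C_di_exp(SEXP f)         { return put_di(di_exp(get_di(f))); }
SEXP C_di_log(SEXP f)         { return put_di(di_log(get_di(f))); }

SEXP C_di_pow_const(SEXP f, SEXP c)
{
    return put_di(di_pow_const(get_di(f), Rf_asReal(c)));
}

SEXP C_di_pow_gen(SEXP f, SEXP g)
{
    return put_di(di_pow_gen(get_di(f), get_di(g)));
}

SEXP C_central_beta(SEXP x, SEXP a, SEXP b)
{
    return put_iv(central_beta_iv(get_iv(x), get_iv(a), Rf_asInteger(b)));
}

SEXP C_central_beta_dx(SEXP x, SEXP a, SEXP b)
{
    return put_di(central_beta_di(get_di(x), get_iv(a), Rf_asInteger(b)));
}

SEXP C_noncentral_beta(SEXP x, SEXP a, SEXP b, SEXP lam)
{
    return put_iv(noncentral_beta_iv(get_iv(x), get_iv(a),
                                     Rf_asInteger(b), get_iv(lam)));
}

SEXP C_noncentral_beta_dlam(SEXP lam, SEXP x, SEXP a, SEXP b)
{
    return put_di(noncentral_beta_dlam(get_di(lam), get_iv(x), get_iv(a),
                                       Rf_asInteger(b)));
}

SEXP C_nextafter(SEXP x, SEXP up)
{
    R_xlen_t n = XLENGTH(x);
    int u = Rf_asLogical(up);
    SEXP r = PROTECT(Rf_allocVector(REALSXP, n));
    for (R_xlen_t i = 0; i < n; i++)
        REAL(r)[i] = u ? step_up(REAL(x)[i]) : step_down(REAL(x)[i]);
    UNPROTECT(1);
    return r;
}

static const R_CallMethodDef call_entries[] = {
    {"C_iv_add",  (DL_FUNC) &C_iv_add,  2},
    {"C_iv_sub",  (DL_FUNC) &C_iv_sub,  2},
    {"C_iv_neg",  (DL_FUNC) &C_iv_neg,  1},
    {"C_iv_mul",  (DL_FUNC) &C_iv_mul,  2},
    {"C_iv_div",  (DL_FUNC) &C_iv_div,  2},
    {"C_iv_exp",  (DL_FUNC) &C_iv_exp,  1},
    {"C_iv_log",  (DL_FUNC) &C_iv_log,  1},
    {"C_iv_pow",  (DL_FUNC) &C_iv_pow,  2},
    {"C_iv_pown", (DL_FUNC) &C_iv_pown, 2},
    {"C_di_add",  (DL_FUNC) &C_di_add,  2},
    {"C_di_sub",  (DL_FUNC) &C_di_sub,  2},
    {"C_di_neg",  (DL_FUNC) &C_di_neg,  1},
    {"C_di_mul",  (DL_FUNC) &C_di_mul,  2},
    {"C_di_div",  (DL_FUNC) &C_di_div,  2},
    {"C_di_exp",  (DL_FUNC) &C_di_exp,  1},
    {"C_di_log",  (DL_FUNC) &C_di_log,  1},
    {"C_di_pow_const", (DL_FUNC) &C_di_pow_const, 2},
    {"C_di_pow_gen",   (DL_FUNC) &C_di_pow_gen,   2},
    {"C_central_beta",        (DL_FUNC) &C_central_beta,        3},
    {"C_central_beta_dx",     (DL_FUNC) &C_central_beta_dx,     3},
    {"C_noncentral_beta",     (DL_FUNC) &C_noncentral_beta,     4},
    {"C_noncentral_beta_dlam",(DL_FUNC) &C_noncentral_beta_dlam,4},
    {"C_nextafter", (DL_FUNC) &C_nextafter, 2},
    {NULL, NULL, 0}
};

void R_init_ncfcheck(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
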