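---
title: "Verified enclosures for noncentral beta and F power calculations"
author: "ncfcheck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verified enclosures for noncentral beta and F power calculations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Power calculations for the F test rest on two univariate equations.  With
$a = \nu_1/2$, $b = \nu_2/2$ and the F scale mapped to the beta scale by
$x = \nu_1 w/(\nu_1 w + \nu_2)$, the upper $\alpha$ quantile of the central
beta distribution solves

$$I_x(a,b) = 1-\alpha,$$

and the noncentrality parameter attaining type II error $\beta$ (hence the
minimal detectable effect size) solves

$$I_{x_{1-\alpha}}(a,b;\lambda) = \beta.$$

Both targets are strictly monotone, so root finding is easy; the hard part
is evaluating the cdfs.  Floating-point implementations of the noncentral
beta/F cdf are notorious for overflow, underflow and catastrophic
cancellation, and several published tables contain entries with *no* correct
significant digits while looking perfectly plausible.  `ncfcheck` computes
*guaranteed enclosures* of $x_{1-\alpha}$, $\lambda$ and the cdf values:
intervals that provably contain the exact real-arithmetic results, whatever
rounding occurred along the way.  Its primary use case is cross-checking
other statistical software: a candidate value is inflated into a thin
interval, and the interval Newton method either verifies a unique solution
inside it, proves there is none, or reports that verification failed —
never a silently wrong answer.

## Closed-form cdf evaluation

For integer $b$ the central beta cdf has the finite closed form

$$I_x(a,b) = x^a\Big(1+\sum_{n=1}^{b-1}\Big(\prod_{m=1}^{n}
\tfrac{a+m-1}{m}\Big)(1-x)^n\Big),$$

and the noncentral cdf reduces to the finite mixture

$$I_x(a,b;\lambda) = e^{-z}\sum_{i=0}^{b-1}\frac{z^i}{i!}\,
I_x(a+i,\,b-i),\qquad z = \tfrac{\lambda}{2}(1-x).$$

Only $+,-,\times,\div$, powers and $\exp$ appear, which is what makes a
fully verified evaluation possible.  Numerical choices:

* **Term recurrences.**  The inner product is updated incrementally
  ($p_n = p_{n-1}(a+n-1)/n$) and the mixture terms as $t_i = t_{i-1}z/i$;
  explicit factorials or powers would overflow long before $b = 500$,
  whereas all recurrence intermediates stay far below overflow throughout
  the supported range.  The $i=0$ term is taken as $I_x(a,b)$ directly,
  avoiding $0^0$ at $x=1$ or $\lambda=0$.
* **Powers at the boundary.**  $x^a$ with non-integer $a>0$ is defined as
  $0$ at $x=0$ through monotone endpoint evaluation, so enclosures of
  intervals touching 0 need no logarithms.  Integer exponents use the
  parity rule and directed multiplication chains, which keeps exactly
  representable powers exact.
* **Clamping.**  The final enclosure is intersected with $[0,1]$; the true
  cdf value lies there, so this can only sharpen a valid enclosure (it
  curbs rounding inflation of the long positive sums).
* **Shifted shapes.**  The shapes $a+i$ inside the mixture are accumulated
  in interval arithmetic, so non-representable sums still yield enclosures.

Each $I_x(a+i,b-i)$ is evaluated independently; the cost is
$O(b^2)$ interval operations per noncentral evaluation, which is a few
milliseconds at $b=500$ and deliberately not optimised further — the terms
are evaluated exactly as written.

## Outwardly rounded interval arithmetic

Every operation returns an interval guaranteed to contain the exact result.
For `+`, `-`, `*`, `/` the endpoint is computed in ordinary IEEE arithmetic
and the rounding *direction* is decided exactly with error-free
transformations (two-sum residuals, `fma` product/quotient residuals): the
endpoint is stepped to the adjacent float only when the rounded result is
provably on the wrong side.  This is the tightest representable directed
rounding, and integer-endpoint arithmetic stays exact
(`interval(1,2) + interval(3,4)` is exactly `[4,6]`).  Near the subnormal
range the residual tricks lose exactness, so a guard takes a full outward
step there unconditionally.  `^`, `exp` and `log` rely on libm and are
widened by two ulps per endpoint, covering the documented (≤ 1 ulp)
accuracy of the platform math library — this is the only place where a
property of the environment is assumed rather than proved.

Endpoint overflow widens to $\pm\infty$ (never wraps, never throws), so
loss of precision always *shows* as a wide interval.  The demonstration
`e_enclosure_demo()` makes this visible: evaluating $(1+1/n)^n$ and
$(1-1/n)^{-n}$ at $n = 10^k$ in plain floating point violates
$f(n) < e < g(n)$ badly for $k \ge 9$, while the interval evaluation always
satisfies $\underline f \le e \le \overline g$ and reports the cancellation
for large $k$ through enclosures of width $10^4$ and more.  The tightest
enclosure of $e$ on this path occurs at $k=8$ with width below $10^{-6}$.

The empty interval is a first-class value (intersections produce it,
arithmetic propagates it), division by an interval containing zero and
logarithms of intervals reaching zero are domain errors, and magnitude and
mignitude follow the standard definitions
$|\mathbf x| = \max(|\underline x|,|\overline x|)$,
$\langle\mathbf x\rangle = \min\{|u| : u \in \mathbf x\}$.

## Derivatives and the interval Newton method

Derivative enclosures come from forward-mode differentiation on *interval
differential numbers*: pairs (value enclosure, derivative enclosure) with
the usual sum/product/quotient/power/chain rules executed in interval
arithmetic.  A constant exponent $c$ uses $c\,f^{c-1}f'$ — valid for bases
touching zero — and only a genuinely varying exponent needs the logarithmic
form $f^g(g'\log f + g f'/f)$ with $f>0$.  Only first derivatives exist;
the Newton operator needs nothing more.

The univariate interval Newton operator
$N(f,f';\mathbf x,\tilde x) = \tilde x - f(\tilde x)/f'(\mathbf x)$ drives
the iteration
$\mathbf x^{(k+1)} = \mathbf x^{(k)} \cap N(f,f';\mathbf x^{(k)},\check
x^{(k)})$ with three verified outcomes: an empty intersection proves there
is no zero; an operator image inside the *interior* of its argument proves
existence and uniqueness; anything else is an honest failure.  Numerical
policies, chosen because the underlying theory prescribes none:

* **Stopping.**  Iterate until the relative width falls below `rel_tol`
  (default `1e-13`) or the width stops shrinking; `max_iter` defaults
  to 100.
* **Uniqueness verification.**  Near-point iterates cannot satisfy the
  strict interior test directly, so one operator step is applied to an
  ε-inflated enclosure (relative `1e-10`, plus at least one ulp per side),
  retried once at 100× the inflation.
* **Derivative straddling zero.**  Extended (Kahan) division is not
  implemented; when $0 \in f'(\mathbf x)$ the interval is bisected and both
  halves are processed recursively within a total budget of 64
  subdivisions (the split point is nudged so its function value excludes
  zero, preventing both halves from claiming a shared boundary root).  A
  unique result is reported only when exactly one branch verified a zero
  and all others were proven empty.
* **Unbounded iterates** fail rather than guess.

## The three-step cross-checking algorithm

1. Candidates are inflated multiplicatively:
   $x_0 = [(1-\epsilon_x)x, (1+\epsilon_x)x]$ and likewise for $\lambda$,
   with $\epsilon = 10^{-6}$ by default (values $\ge 10^{-4}$ warn: results
   stay rigorous, verification may degrade).  Zero or negative candidates
   are input errors — multiplicative inflation is meaningless there.
2. The quantile equation is solved on $x_0$.
3. Only if step 2 verified uniqueness, the $\lambda$ equation is solved on
   $\lambda_0$, with the *entire step-2 enclosure* entering as a thick
   constant interval.  Using the enclosure rather than its midpoint is the
   choice that preserves the end-to-end guarantee: the $\lambda$ enclosure
   is then valid for every $x$ compatible with step 2.

Verdict semantics for cross-checking: `UNIQUE` ⇒ the candidate is at least
as accurate as the inflation radius (`VERIFIED`); `EMPTY` ⇒ it is not
(`REJECTED`); `FAILED` draws no conclusion and is usually remedied by a
larger radius.  The package surfaces failures and leaves the retry to the
caller.

**Wide mode.**  Both equations can also be solved with no candidate at all.
A naive branch-and-bound from $[0,1]$ is hopeless here: over wide boxes the
direct interval extension of the closed form overestimates by orders of
magnitude (the positive and negative parts of the derivative each vary by
factors of $10^5$ at $a=25$, $b=500$), so range tests cannot prune until
boxes are narrower than about $10^{-3}x$ — hundreds of subdivisions.
Instead the solver exploits the strict monotonicity of both targets:
*point* evaluations are tight, so a sign-certified bisection (each step
verifies the sign of the function value enclosure at a point) shrinks the
bracket cheaply until the derivative enclosure over it has one certified
sign, and the interval Newton iteration with the interior-containment
uniqueness test finishes.  For $\lambda$ the upper bracket comes from
verified doubling of $\Lambda$ until the cdf enclosure at $\Lambda$ lies
strictly below $\beta$, capped at $2^{60}$.  Every status reported in wide
mode carries the same guarantees as the candidate mode.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `eps_x`, `eps_lambda` | `1e-6` | relative inflation radius of candidate intervals (dimensionless); also the accuracy claim a `VERIFIED` verdict certifies |
| `rel_tol` | `1e-13` | Newton stop: relative enclosure width |
| `max_iter` | `100` | Newton iterations per branch |
| `max_bisect` | `64` | total bisection budget on derivative straddles |
| `digits` (reports) | `12` | printed significant digits; bounds are rounded outward so printed intervals still enclose |

The practically relevant parameter range is $a \le 25$, $b \le 500$,
$0.01 \le \alpha,\beta \le 0.99$; outside it the package warns and
proceeds — verification may start failing, incorrect enclosures cannot
occur.  Only even $\nu_2$ (integer $b$) is supported; this is a genuine
limitation of the closed form, not of the implementation.

## What the tests compute

The acceptance suite recomputes, from scratch and in wide mode, all 198
entries of the published upper-0.05 quantile grid and all 198 entries of the
noncentrality grid ($\alpha=0.05$, $\beta=0.10$; the grids ship as
plain-text fixtures, 6 significant digits), checks that every enclosure
midpoint rounds to the printed entry, that quantile enclosures determine at
least 12 and noncentrality enclosures at least 10 significant digits
(radius at most half a unit in the last counted digit), and that the five
published noncentral cdf comparison values reproduce to 7 digits together
with all ten published correct-digit counts.  Randomized suites check
containment, inclusion isotonicity and subdistributivity of the interval
layer (1000 cases each), containment of the closed-form cdf enclosures
against an independent Poisson-mixture oracle over
$a\in[0.5,25]$, $b\in\{1..500\}$, $\lambda\in[0,2500]$ (1000 cases), the
solve-then-evaluate round trip to $10^{-8}$ on a $4\times4$ grid, and
rejection of candidates perturbed by $10^{-3}$ at inflation $10^{-6}$.
The whole suite runs in a few minutes on one core; the grid sizes above are
the full published grids, not reductions.

Because no arbitrary-precision arithmetic is available at test time, the
runtime oracle is the Poisson-mixture series in double precision with a
rigorous Poisson tail bound, and containment is asserted up to the oracle's
own (≈$10^{-11}$) error; frozen reference constants in the tests were
computed once at 60-digit precision from the series definition.

## The fixture generator

`generate_fixtures()` plays the role of the software under test: it writes
candidate files whose records come from the package's own wide-mode
enclosure midpoints, optionally corrupted by an error model — `exact`
(every record should verify), `perturb` (the $\lambda$ candidate is moved
by a relative $[\delta/2,\delta]$ with random sign, the quantile left
exact, so every $\lambda$ verdict should be `REJECTED` at radii well below
$\delta$), and `overflow-bogus` ($\lambda$ off by 1–2 orders of magnitude,
emulating a silent overflow).  What passing these tests shows is that the
*verdict machinery* discriminates correct from corrupted values at the
stated radii; it does not emulate the specific failure patterns of any real
statistical package — real cross-checks should feed real outputs through
the text-file interface.

## Known limitations

* Even $\nu_2$ only; non-integer $b$ is out of scope.
* Univariate only; no extended interval division, no multivariate
  Newton/Krawczyk.
* `^`, `exp`, `log` enclosures assume the platform libm is accurate to
  within 2 ulps.
* The $O(b^2)$ noncentral evaluation is deliberately unoptimised; at
  $b \gg 500$ cost grows quadratically and verification failures become
  more likely (with warnings), though enclosures remain valid.
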