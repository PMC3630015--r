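---
title: "Methods: projection-based similarity and its graphical displays"
author: "crossOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projection-based similarity and its graphical displays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossOmics)
```

## The problem

Two omics platforms measured on the same $n$ samples produce matrices
$X\ (n \times p)$ and $Y\ (n \times q)$ — say transcript expression and
metabolite concentrations. The question is which subsets of $X$ variables
co-vary with which subsets of $Y$ variables. Projection methods answer it by
extracting paired *variates* $U^l = X a^l$, $V^l = Y b^l$ — linear
combinations that maximize either covariance (PLS) or correlation (CCA) —
and `crossOmics` turns those fits into a pair-wise variable similarity
matrix and three coordinated displays: Correlation Circle plots, bipartite
Relevance Networks and Clustered Image Maps (CIM).

## Models

**PLS.** A NIPALS-style inner loop alternates $a \propto E'v$,
$b \propto F'u$ (unit-norm loadings) on the residual matrices $E, F$ until
the loading update falls below $10^{-9}$ (at most 500 iterations). The loop
is started from the leading singular pair of $E'F$, which is the fixed point
of the dense iteration and a stable basin for the sparse one. After each
dimension both blocks are deflated: in *regression mode* $E$ and $F$ are
both regressed on $U$ (directional model, $X$ predicts $Y$); in *canonical
mode* $E$ is regressed on $U$ and $F$ on $V$ (symmetric model). Loadings
are sign-fixed so the largest-magnitude entry of each $a^l$ is positive,
making fits reproducible bit for bit. The reported association $\rho_l$ is
the sample correlation of the variate pair.

**Sparse PLS.** Inside each iteration the unnormalized loading is
soft-thresholded so that *exactly* `keepX[l]` (resp. `keepY[l]`) entries
stay nonzero, then renormalized. The threshold is the midpoint between the
`keep`-th and `(keep+1)`-th largest absolute raw loadings; exact ties are
resolved by variable index order, and a tied selected entry is retained at a
vanishing magnitude so the count contract holds exactly. With full counts
the sparse fit reproduces the dense one to machine precision.

**CCA and ridge CCA.** Classical CCA is solved by Cholesky whitening of the
two covariance matrices and an SVD of the whitened cross-covariance;
canonical correlations are the singular values, identical to the empirical
correlations of the variate pairs. Ridge regularization adds
$\lambda_1 I$, $\lambda_2 I$ to the two sample covariances (of standardized
columns — equivalent to regularizing the correlation matrices), which makes
the whitening well-posed when $p, q > n$. For a regularized fit the reported
$\rho_l$ are the singular values of the whitened *regularized*
cross-covariance — the canonical values the method maximizes and the
quantity the field's reference software prints. They are deliberately *not*
the empirical correlations of the variate pairs: with $p \gg n$ those are
always $\approx 1$ by overfitting and carry no information. At
$\lambda_1 = \lambda_2 = 0$ the two definitions coincide exactly.
$\lambda$ can be tuned by k-fold cross-validation (`tuneRCCA`), maximizing
the mean held-out correlation of the first variate pair over a grid
(default 11 log-spaced points in $[10^{-3}, 1]$); folds are assigned
deterministically from a seed and ties go to the earliest grid pair.

## The similarity matrix

Each variable is projected onto reference variates as a vector of sample
correlations ("coordinates"). For the CCA family the references are the
equiangular vectors $Z^l = U^l + V^l$, treating the blocks symmetrically;
for PLS the $X$ side uses $U^l$, and the $Y$ side uses $U^l$ (regression
mode) or $V^l$ (canonical mode). With $\mathbf{x}\ (p \times d)$ and
$\mathbf{y}\ (q \times d)$ the coordinate matrices, the similarity matrix
is the inner-product matrix

$$M = \mathbf{x}\,\mathbf{y}' , \qquad
  M_{jk} = \sum_{l=1}^{d} x^j_l\, y^k_l \approx \mathrm{cor}(X^j, Y^k).$$

$M$ is oriented $p \times q$ (rows = $X$ variables), following the
factorization order above. For standardized data the coordinates admit
closed forms through the deflation coefficients
($\mathrm{cor}(X^j, U^l) = \mathrm{sd}(U^l)\,\phi^l_j$); the package always
computes them as empirical correlations and uses the closed forms as test
oracles. In canonical mode the implied closed form for $M$ is
$\sum_l \mathrm{sd}(U^l)\,\mathrm{sd}(V^l)\,\phi^l_j \psi^l_k$, i.e. the
product carries one factor of each variate's standard deviation — a
squared-factor variant sometimes written down is inconsistent with the
coordinate definitions and is not used. For sparse fits, coordinates and
$M$ cover only the selected variables; unselected variables are omitted
entirely rather than zero-filled.

Because the reference variates are mutually orthogonal for PLS and
classical CCA, each coordinate row has norm $\le 1$ (Bessel) and therefore
$|M_{jk}| \le 1$ (Cauchy–Schwarz). Ridge-regularized variates are only
approximately orthogonal, so the bound is checked empirically there rather
than guaranteed.

## Graphical consumers

All three displays consume one coordinate object, so they are mutually
consistent by construction.

* **Correlation Circle** (`circleCoords`/`plotCircle`): variables plotted at
  the endpoints of their coordinate vectors for a chosen dimension pair,
  with guide circles at radii 0.5 and 1. Sharp angles between position
  vectors indicate positive correlation, obtuse angles negative, right
  angles none. An optional radius threshold hides weak variables without
  moving the survivors.
* **Relevance Network** (`relevanceNetwork`): bipartite graph over the
  entries with $|M_{jk}| \ge$ threshold. The boundary is *inclusive* so a
  printed threshold like 0.5 keeps an entry equal to 0.5 (the convention had
  to be fixed one way; it is documented and tested). Nodes without edges
  are dropped. Exports to GraphML (node attribute `side`, edge attributes
  `weight`, `sign`) and SIF (`pos`/`neg`).
* **CIM** (`clusterSimilarity`/`plotCIM`): rows and columns of $M$ clustered
  independently — Euclidean distance, Ward linkage by default. "Ward" here
  means the standard Lance–Williams update applied to the raw (non-squared)
  distances (`ward.D` in base-R terms); the naming is ambiguous across
  software, so the convention is stated and enforced by an oracle test.
  Leaf order within the tree constraints is deterministic: the subtree with
  the lower merge height is placed first, ties broken by smallest leaf
  index. The colour scale is symmetric about zero and saturates at $\pm 1$,
  so sign remains readable regardless of the empirical range.

## The simulation generator

`simulationDesign()` reproduces a validation design with known structure:
$n = 30$ samples; three independent groups of cross-correlated variables —
$X_A$ (10) with $Y_A$ (10), negatively, magnitudes spanning 0.51–0.93;
$X_B$ (10) with $Y_B$ (5), positively, 0.50–0.85; $X_C$ (3) with $Y_C$ (2),
magnitudes 0.81–0.93, positive towards $Y_{C1}$ and negative towards
$Y_{C2}$ — padded with independent standard-normal noise to $p = 100$ and
$q = 50$. Noise ids carry the reserved prefixes `NX`/`NY` so downstream
checks can count them.

Each matched block pair is driven by **one shared latent factor**: the
squared factor loadings are evenly spaced over the requested range, so the
population cross-correlations (products of loadings) span the range with
both endpoints attained exactly, the covariance matrix has unit diagonal,
and it is positive definite *by construction* — no eigenvalue repair step is
ever needed, and the extreme entries are never distorted. The natural
alternative — a compound-symmetric within-block correlation at a fixed
level (say 0.8) plus a free-range cross block — is not positive
semi-definite for these ranges (the Schur complement fails once the cross
block must reach 0.93), and repairing it moves exactly the entries the
design pins down. A consequence of the factor construction is that
within-block correlations are the loading products (0.51–0.93 in group A)
rather than a constant; the optional `withinShare` parameter can add a
block-level shared factor on top (default 0, the value used throughout,
chosen once because raising it only weakens the latent-correlation
structure).

What the generator emulates: block-structured cross-correlation between
disparate measurement types, with realistic noise padding. What it does
not: non-Gaussian margins, heteroscedastic platform noise, within-set
pathway structure beyond the shared factors. Passing tests therefore show
that the stack recovers *linear block associations* — not that it handles
every distributional quirk of real assays.

## Behaviour at the design's sample size

Three empirical facts about this design at $n = 30$, $p = 100$, $q = 50$
are worth stating because they bound what any method can show (all are
verified by the test suite):

* Canonical-mode PLS recovers the three planted dimensions with latent
  correlations $\approx 0.97/0.96/0.95$ (mean over 20 generator seeds).
  Residual dimensions keep *correlations* near 0.9 by overfitting — the
  diagnostic quantity that collapses after dimension 3 is the latent
  *covariance*, and the clean correlation drop-off is visible at
  $n = 500$.
* Ridge CCA at $\lambda_1 = \lambda_2 = 0.889$ yields a first canonical
  value of $\approx 0.91$. With unit-variance variables and blocks of at
  most 10 correlated variables, the per-side shrinkage factor
  $\sqrt{\mu/(\mu + \lambda)}$ with $\mu \le 10$ caps the population value
  near 0.92 at this $\lambda$ — larger values require either weaker
  effective regularization or non-unit variances.
* A noise variable's sample correlation with any variate is
  $N(0, \approx 1/29)$ regardless of the covariance structure, so with 110
  noise variables and 3 dimensions, most seeds produce at least one noise
  coordinate above $\approx 0.5$. Relevance networks thresholded at 0.5
  therefore usually contain a few borderline noise edges at $n = 30$; at
  $n = 500$ the same threshold separates signal from noise cleanly, and
  per-dimension sparse selection sized to the blocks
  (`keepX = c(10, 10, 3)`, `keepY = c(10, 5, 2)`) recovers exactly the
  planted variables.

## Numerical choices and degenerate inputs

* Standardization uses the $n-1$ variance; zero-variance columns are
  rejected by name. All fitting front ends require standardized data.
* NIPALS convergence: loading change $< 10^{-9}$, max 500 iterations;
  non-convergence and rank exhaustion are errors, not warnings.
* Classical CCA refuses near-singular covariance (reciprocal condition
  number $< 10^{-12}$) with a pointer to `fitRCCA`.
* Network construction on an empty result returns a valid zero-node object
  that exports to valid (edge-free) files.
* `clusterSimilarity` needs at least a $2 \times 2$ matrix; a constant
  matrix clusters (and renders) degenerately but validly.
* All randomness (simulation, CV folds) flows through explicit integer
  seeds; identical inputs give bit-identical outputs, including rendered
  images.

Problem sizes used in the shipped checks were chosen to keep every run at
desk scale: the full design at $n = 30$ for the study-level quantities
(averaged over 20 seeds), $n = 500$ where a law-of-large-numbers argument
is being exercised, $n = 5000$ once for generator-consistency bounds, and
matrices up to $8 \times 8$ for the exhaustive clustering oracle.

## Limitations

Linear associations only; a single similarity definition (no mutual
information); no within-set (X–X or Y–Y) networks by design; sparse-PLS
tuning criteria (e.g. $Q^2$) are out of scope — selection sizes are user
inputs; the ridge-CCA reported values are regularization-dependent and not
comparable across different $\lambda$ without care.
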