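---
title: "Models and methods behind screenrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind screenrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The prediction problem

Cervical cancer screening produces, for each woman, an irregular time series
of exam results: at ages $t_0 < t_1 < \dots < t_j$ she is examined with a
modality $\rho$ (cytology or histology) and classified into one of three
clinically actionable states — 1 = normal, 2 = low-grade, 3 = high-grade. A
history is the tuple set $y_{t_j} = \{(t_i, \rho_{t_i}, x_{t_i})\}_{i=0}^j$.
The task is to predict, at a target age $\hat t > t_j$, the risk triple
$p(x_{\hat t} = s \mid y_{t_j})$, $s \in \{1,2,3\}$, and to keep updating it
as new exams arrive, without ever re-fitting the reference model.

Two features of registry screening data drive every design decision in this
package: **imbalance** (well over 85% of results are normal, under 5%
high-grade) and **drift** (the normal share rises with age, from about 0.87
before age 36 to about 0.93 at 46 and older), on top of **irregular
sampling** (gaps from about a month to twenty years).

# Risk estimators

All estimators share a three-verb incremental contract —
`init_state()`, `observe()`, `predict_risk()` — so the rolling evaluation
protocol is estimator-agnostic.

## Latent-profile mixtures (MF and GDL)

The factorization estimators assume each woman's discrete results are noisy
readouts of a continuous latent trajectory $m(t)$ on an age grid. Given a
reference cohort rasterized into a partially observed matrix $Z$
(rows = women, columns = quarterly age bins from 16 to 80 by default), a
complete matrix $\widehat M$ of latent profiles is estimated by masked
least squares around a baseline shift of 1 (the normal state):

* `fit_swcmf()` penalizes squared forward differences of the temporal
  factor, so profiles drift slowly in age;
* `fit_gdl()` instead penalizes the Laplacian quadratic forms of two
  similarity graphs applied to the reconstruction: a graph over histories
  learned from the data (Gaussian kernel on distances over co-observed
  columns, per-node adaptive bandwidth, thresholded so node degrees are
  variable rather than fixed-$k$) and a path graph over age bins encoding
  that risk changes slowly within a year. The graph penalties act on the
  reconstructed profile matrix, not on the factors: factor-space penalties
  can be escaped by rescaling one factor against the other, which defeats
  the regularization at low rank.

Both are solved by alternating least squares with a small ridge
(`1e-4`), exact block minimizers per half-step (so the objective is
provably non-increasing), and a seeded deterministic initialization.

The emission model ties latent values to discrete states:
$$p(x = s \mid m) \propto \exp\!\left(-\frac{(m - s)^2}{2\sigma^2}\right),$$
normalized over $s \in \{1,2,3\}$ — the only normalization that makes the
kernel a proper distribution over the discrete state set. The scale
$\sigma$ is the 1-D maximum-likelihood estimate over the observed cells of
the fitted matrix, found on a bounded log scale with boundary diagnostics.
Note the negative sign in the exponent: a likelihood must decay with the
residual for the noisy-measurement reading to make sense.

Prediction is the posterior predictive mixture over the $N$ reference
profiles,
$$\widehat p(x_{\hat t}=s \mid y_{t_j}) \propto \sum_{n=1}^N
  p(x_{\hat t}=s \mid \widehat M_{n,\hat t})\,
  \widehat p(y_{t_j} \mid \widehat M_n),$$
with the per-profile history likelihood as the mixture weight and a
uniform prior over rows (the reference rows are the empirical stand-in for
the intractable prior over trajectories). Each new exam multiplies one
emission term into every weight, so incremental updating is $O(N)$ per
record and provably equals batch recomputation; everything runs in log
space with a max shift, tolerating underflow of individual rows.

## Hidden Markov filter

The HMM estimator treats the latent risk as one of three hidden states
(normal / low-risk / high-risk) evolving as a continuous-time Markov chain
whose intensity matrix is supplied by configuration — fitting those
parameters to registry data is a separate exercise this package consumes,
not reproduces. The forward variable
$\alpha(h_{t_j}) = p(h_{t_j} \mid y_{t_j})$ is initialized as the age-band
prior times the first emission, and updated by
$$\alpha(h_{t_i}) = p(x_{t_i} \mid h_{t_i}, \rho_{t_i})
 \sum_{h'} P_{h' h}(\Delta t)\, \alpha(h'),$$
with $P(\Delta t) = e^{Q \Delta t}$ the generator exponential over the
elapsed gap. Prediction marginalizes over the hidden state at the target
age and the future exam type, whose law $p(\rho \mid h)$ is obtained by
normalizing per-hidden-state Poisson exam intensities across modalities.
The filter is exact (verified against exhaustive hidden-path enumeration)
and runs in log space. The default parameters in `default_hmm_params()`
are plausible documented values used by tests and examples; the initial
law is banded by age because a continuous-in-age prior adds parameters the
rest of the machinery never exploits.

## Machine-learning comparators

Logistic regression, random forest and gradient tree boosting treat each
prediction as a tabular problem over cumulative counts of each state
crossed with exam type (six counts), the age at the last counted exam and
the target age. The learners are off-the-shelf (`nnet::multinom`,
`ranger`, `xgboost`); this package owns only the feature construction,
the Z-scoring protocol for the linear model (moments frozen from a
hold-out block, never recomputed), and the warm-start refit protocol:
logistic regression restarts its optimizer from the current coefficients,
boosting continues the ensemble, and the forest — which has no
incremental form — is refit from scratch on pooled data with a notice.

## Simulator-truth oracle

On synthetic cohorts an oracle estimator reads the simulator's latent true
state at the last visit and propagates it with the exact generator and
misclassification laws. It upper-bounds what any fitted model can achieve
and anchors the calibration comparisons.

# Classification under imbalance and drift

The **default strategy** takes the most probable state, with exact ties
broken toward severity (a screening program tolerates false positives far
better than false negatives). Under imbalance it predicts normal almost
always.

The **adaptive strategy** applies priority-ordered probability
thresholds: predict high-grade when $\widehat p(3) \ge \delta_3$, else
low-grade when $\widehat p(2) \ge \delta_2$, else normal. Normal is the
fallback, so only $\delta_2, \delta_3$ are free — a nominal
$\delta_1$ would never be evaluated. Drift is handled by fitting separate
thresholds in three age intervals (20–35, 36–45, 46+; few enough to avoid
per-interval overfitting). Thresholds maximize the $K$-category Matthews
correlation coefficient
$$R_K = \frac{n_+ n - \sum_s \hat n_s n_s}
 {\sqrt{(n^2 - \sum_s \hat n_s^2)(n^2 - \sum_s n_s^2)}},$$
with $\hat n_s$ the number of predictions of class $s$ (the standard
Gorodkin definition; defining $\hat n_s$ as *correct* predictions would
duplicate $n_+$ and break the $[-1,1]$ range). A zero denominator — all
truths or all predictions in one class — scores 0 by convention. The
maximization runs a classic rand/1/bin differential evolution
(population 30, at most 200 generations, bounds $(0.001, 0.999)$, fixed
seed), implemented in-package and verified against exhaustive grid search
at 0.005 resolution. Because a per-interval MCC rests on a handful of
minority predictions, the single-sample optimum can sit on a sampling
fluke; the experiment pipeline therefore maximizes the MCC averaged over
bootstrap resamples of the validation predictions (`n_boot = 25`) and
centers each threshold in its optimal plateau — the objective is
piecewise constant, and a knife-edge threshold at a sample's exact
probability transfers poorly. Thresholds (and the Z-scoring moments) are fit on a
hold-out validation split disjoint from both training and test subjects:
fitting them on test predictions would leak, and fitting them on a slice
of the severity-enriched training sample would tune them to a state
distribution systematically richer in abnormalities than the population
they are applied to. The hold-out is drawn from the unused cohort
remainder under the same filters as the test set.

# Evaluation statistics

* **Stratified Brier scores**: within the stratum of targets whose true
  state is $s$, $B_s = \operatorname{mean}(\widehat p(s) - 1)^2$. A
  normal-biased model scores low on the normal stratum and high on the
  minority strata — the diagnostic signature of imbalance.
* **Absolute risk curves**: per consecutive age window of about 10 months
  (10/12 years, configurable), the proportions of the three states among
  targets falling in the window.
* **Relative deviation** $\eta = \int |r - \hat r| \,dt / \int r\,dt$
  between a predicted and a reference curve, by trapezoidal quadrature on
  shared window centers; 0 means the predicted curve tracks the reference
  exactly, and the indicator is invariant to common rescaling.

# The synthetic cohort generator

Registry screening data are access-restricted, so the package ships a
simulator whose **defaults are calibrated once** to the published summary
characteristics and then frozen:

* disease process: a 3-state continuous-time Markov chain with
  age-band-piecewise reversible birth–death generators; the stationary law
  of each band is chosen so that the *observed* state mix (after exam
  misclassification) reproduces the drift targets — about 0.87 normal
  before 36, about 0.93 at 46+ — with regression rates of 0.45/yr
  (low-grade to normal) and 0.12/yr (high-grade to low-grade), reflecting
  that low-grade lesions often regress spontaneously;
* first exam: truncated normal, mean 26, sd 5, on [18, 55] — concentrated
  at ages 20–30;
* inter-exam gaps: truncated log-normal (median 2 years, $\sigma_{\log} =
  0.85$) supported on one month to twenty years;
* exams per history: $1 + \mathrm{NegBin}(\text{size}=2.2, \mu=6.2)$,
  giving a cohort median of 6;
* exam types: histology probability (0.03, 0.30, 0.60) by current true
  state — the confirmatory exam follows abnormality;
* misclassification: row-stochastic confusion matrices per modality, with
  cytology noisier than histology (the gold standard).

Transition over a visit gap uses the generator exponential, split at band
boundaries; this is cross-checked in tests against event-by-event
Gillespie simulation. One master seed spawns per-subject substreams, so
cohorts are reproducible and order-independent.

What the simulator does **not** emulate: HPV infection dynamics and
vaccination, state-dependent visit scheduling (in real programs an
abnormal result shortens the next interval), calendar-time effects
(screening-policy changes, the post-2005 HPV era), and population-level
heterogeneity beyond the age-band drift. Tests passing on this cohort
therefore certify the estimators' mechanics and their behaviour under
imbalance and drift — not clinical performance on registry data.

# The experiment protocol

`run_experiment()` reproduces the study design at configurable scale:
only histories with at least 3 exams are used; training histories are
drawn without replacement with probability proportional to the most
severe result in the history (enriching abnormal histories); test
histories come from the remainder with a first exam at ages 20–30. There
is no calendar axis in simulation, so the original first-exam calendar
cut-off has no analogue; the age filter is kept and a calendar field left
for real-data use. Evaluation reveals the first two results, predicts the
third, and walks forward, incorporating each previous result through the
estimator's incremental update. A prediction may only condition on
records at least six months (0.5 years) before the target; a record inside
that gap is withheld until a later target admits it, and targets whose
mandatory first two records violate the gap are skipped and logged rather
than silently dropped. An audit pass in the tests confirms no
conditioning record ever enters the six-month window.

The problem sizes used by the package's own end-to-end checks — a cohort
of 8,000–10,000 simulated histories, 1,000 training histories, 500
hold-out validation histories for threshold fitting, 2,000 test
histories — were chosen as the smallest sizes at which the per-interval
classification scores and per-state deviation indicators are stable
across seeds; registry-scale sizes (10K training / 50K test) are a
configuration change, not a code change.

# Numerical choices and edge cases

* All likelihoods, forward variables and mixture weights live in log
  space with max-shift normalization; a subject is lost only if *every*
  reference row underflows, which raises an error rather than returning
  noise.
* Bin collisions when rasterizing (two exams in one quarter) keep the
  more severe state, consistent with the severity-first stance.
* Argmax ties break toward severity; degenerate $R_K$ denominators score
  0; empty risk-curve windows are excluded; zero-variance features are
  floored before Z-scoring; an all-zero-residual emission fit pins
  $\sigma$ at the configured lower bound with a warning.
* The ALS solvers warn (and return the current iterate) when the
  objective's relative change has not reached the tolerance within
  `max_iters`.

# Known limitations

The GDL backend implements the graph-regularized objective, not a neural
architecture; exam-type information enters the factorization only through
the observation mask; and all empirical statements in this vignette are
about the synthetic cohort the tests construct — registry data are
outside the package's reach by design.

On the adaptive-versus-default comparison specifically, the package's
end-to-end checks show a consistent asymmetry: threshold adaptation
yields large out-of-sample gains exactly where the argmax rule is weak
(the logistic and graph-regularized models, and the tree ensembles in the
oldest interval), while for estimators whose argmax is already far from
the degenerate all-normal regime the two strategies are statistically
indistinguishable at a few thousand test histories — a per-interval MCC
rests on a few dozen minority predictions, and the sign of the difference
can flip between seeds. In-sample on the validation predictions the
fitted thresholds beat the argmax rule in every interval for every
estimator, so the mechanism works; guaranteeing the inequality on
held-out data at this scale would require either much larger test sets
or models as heavily biased as registry-trained ones.
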