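---
title: "Evaluating pragmatic reasoning in one-shot reference games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating pragmatic reasoning in one-shot reference games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refgames)
```

## The task and the two models

In a one-shot referential communication game a speaker sees three colored
shapes and describes the middle one (the *target*) with a single word — a
shape word such as "boot" (a noun) or a color word such as "blue" (an
adjective). A listener sees the same display and the word, and picks the
object they think was meant. A third group, the *salience* task, sees the
display and an unintelligible word and guesses the referent, which
operationalises the prior probability $P(r)$ of referring to each object.
Every participant contributes exactly one trial, so there is no
opportunity for convergence across trials.

The **RSA pragmatic listener** resolves the referent by Bayesian
inversion of an informative-speaker model:

$$P(r \mid w, C) = \frac{P(w \mid r, C)\,P(r)}
{\sum_{r' \in C} P(w \mid r', C)\,P(r')},
\qquad
P(w \mid r, C) = \frac{|w|^{-\alpha}}{\sum_{w' \in W} |w'|^{-\alpha}},$$

where $|w|$ is the number of objects in the context $C$ that $w$ literally
fits, $W$ is the pair of words (shape, color) that fit $r$, and the
likelihood is zero when $w$ does not fit $r$. The rationality exponent
$\alpha$ arises from a softmax over word utility $U(w; r, C) = \ln(1/|w|)$
with constant cost, so $e^{\alpha U} = |w|^{-\alpha}$; $\alpha = 1$ gives
the Luce-choice speaker of the basic model, and that is the value used for
all model predictions here.

The **baseline literal listener** replaces the speaker likelihood with the
literal truth function, uniform over the words that fit the referent. Its
posterior is simply the prior renormalized over the word's literal
extension. Algebraically this is the RSA model at $\alpha = 0$, an
identity the package exploits as a cross-check: `rsa_posterior(...,
alpha = 0)` must equal `literal_posterior(...)` to machine precision on
arbitrary contexts, words and priors, and the test suite verifies this on
1000 random cases.

Comparing the two models isolates the contribution of the *pragmatic
component* — reasoning about an informative speaker — because both models
share literal semantics and the prior.

## The 24-condition context space

Contexts are classified by how many objects share the target's shape
(`s`) and color (`c`), giving ten basic types from `1s1c` (three unique
objects) to `3s3c` (three identical objects); `2s2c` splits into `2s2c.a`
(one competitor shares both features) and `2s2c.b` (one shares the shape,
the other the color). Because the speaker model counts extensions over
*all* objects, the feature overlap *between the competitors* can also
change the predictions, but only in four (type, listener word)
combinations: `1s2c`/color word and `1s3c`/color word (competitors share a
shape or not: qualifiers `ss`/`ds`), and symmetrically `2s1c`/shape word
and `3s1c`/shape word (`sc`/`dc`). Crossing the types with the word
dimension and splitting exactly those four cells yields **24 conditions**,
which `enumerate_conditions()` builds and classifies *algorithmically*
from the model posteriors under a uniform prior:

* **trivial** — the word uniquely identifies an object (6 conditions);
* **ambiguous** — the RSA and literal posteriors coincide, so speaker
  reasoning cannot help (10 conditions);
* **solvable** — RSA singles out one of the literally matching objects
  (4 conditions: `1s2c.ss`+color, `2s1c.sc`+shape, and `2s2c.b` with
  either word);
* **reducible** — the word fits all three objects and RSA demotes exactly
  one, leaving two tied (4 conditions: `1s3c.ss`+color, `3s1c.sc`+shape,
  `2s3c`+color, `3s2c`+shape).

The solvable and reducible cells together are the eight *pragmatic
conditions*, the only ones where the two models disagree. The full cell
list is only partially recoverable from published descriptions, so the
enumeration is validated against its aggregate structure (24 cells, 4 + 4
pragmatic) and the classifier — not a hard-coded table — is the source of
truth; the expected per-cell taxonomy is nevertheless frozen as a test
fixture so that regressions are visible.

```{r taxonomy}
conds <- enumerate_conditions()
table(conds$category)
```

Two worked posteriors anchor the arithmetic (uniform prior,
$\alpha = 1$). In the canonical solvable context {blue boot, blue mitt,
green boot} with the word "blue", the boot's alternatives are two-way
ambiguous while the mitt has the sharper name "mitt", so the posterior is
(0.6, 0.4, 0). In the reducible context {blue boot, blue boot, blue mitt}
the posterior is (8/21, 8/21, 5/21): the mitt is demoted because "mitt"
would have been the better word for it. Both values are verified in the
tests against a brute-force evaluation with exact rational arithmetic.

```{r worked}
rsa_posterior("blue", visual_context(c("boot", "mitt", "boot"),
                                     c("blue", "blue", "green")))
rsa_posterior("blue", visual_context(c("boot", "boot", "mitt"),
                                     c("blue", "blue", "blue")))
```

## Items, roles and aggregation

`generate_item_set()` instantiates a condition's feature pattern with
random tokens from the vocabulary (four shapes × four colors by default):
target shape–color combinations cycle through a random order of all 16 so
each occurs approximately equally often, unconstrained competitor features
are drawn uniformly, and conditions whose left and right objects differ
alternate between the canonical and mirrored arrangement by item parity —
an exact 25/25 split at 50 items, which is why parity rather than an
extra random draw decides the orientation.

Observed choices are aggregated per condition over *object roles* rather
than screen positions, so mirrored items land in the same cells. Roles are
derived from the feature structure: in solvable contexts the *pragmatic
referent* is the object sharing a feature with both others, flanked by its
*color competitor* and *shape competitor*; in reducible contexts the
identical pair are the two *pragmatic referents* (ordered by position) and
the unique-featured object is the *competitor*. Trivial and ambiguous
contexts have no pragmatic structure, so competitors are labeled by the
features they share with the target, falling back to position order for
ties. The role round-trip (simulate choices by role, aggregate, recover
the proportions exactly) is property-tested.

Exclusions mirror standard crowdsourcing practice and are applied in a
fixed order: self-identified non-native/non-fluent speakers, attention-
check failures, and listener responses that violate the literal meaning of
the word (no interpretation, literal or pragmatic, licenses them). Each
category is counted in a report; rejected *rows* (malformed data) are kept
separately by the reader rather than silently dropped.

## Model evaluation

Predictions and observations are paired per condition × role
(`align_cells()`); an `item` unit is available when every distinct visual
context is analysed separately. Cells whose prediction is forced to 0 or 1
by literal semantics alone — the word excludes the object or uniquely
identifies it — are removed under the conservative comparison
(`drop_degenerate = TRUE`), because all models under consideration agree
there. Whether to remove them per cell or per condition is not fully
settled in published practice; removal here is per cell (a trivial
condition loses all three of its cells, a solvable condition only the
excluded object's cell) and the flag exposes the alternative.

Fits are Pearson correlations with adjusted $R^2 = 1 - (1 - r^2)(n -
1)/(n - 2)$ (the one-predictor regression of observed on predicted), $t =
r\sqrt{n-2}/\sqrt{1-r^2}$ and its two-sided $p$. Models are compared with
Dunn and Clark's $z$ for overlapping dependent correlations under
Hittner's modification, in which the covariance term is evaluated at the
back-transformed mean $\bar r = \tanh((Z_{12}+Z_{13})/2)$:

$$c = \frac{r_{23}(1-2\bar r^2) - \tfrac12 \bar r^2(1-2\bar r^2-r_{23}^2)}
{(1-\bar r^2)^2}, \qquad
z = (Z_{12}-Z_{13})\sqrt{\frac{n-3}{2(1-c)}}.$$

When the three correlations are nearly collinear $c$ can reach 1 and no
finite $z$ exists; the comparison then reports `NA` rather than a spurious
number. Exact binomial and three-category multinomial tests use the
probability-ordering two-sided convention (sum the null probabilities of
all outcomes no likelier than the observed one); the multinomial test
enumerates the full outcome space, which is feasible through a few hundred
trials for three categories, and refuses larger inputs rather than
approximating silently. The two-sample $t$ is pooled-variance (matching
the degrees of freedom convention of the engagement comparisons this
mirrors), and no multiple-testing correction is applied anywhere, by
design. `run_evaluation()` assembles all of this per data slice — overall
with and without degenerate cells, pragmatic, reducible, solvable — and
ranks models in its report only when the dependent-correlation comparison
is significant at $\alpha = 0.05$.

Empirical priors are the raw salience proportions, unsmoothed. A zero
salience cell therefore propagates a zero posterior; published tables
never contain zeros so no smoothing rule exists to follow, and the
behavior is left visible rather than patched. A posterior whose entire
support receives zero prior is an error.

## The synthetic-agent generator

`simulate_experiment()` generates trial tables with the statistical
structure the analysis assumes, so every pipeline stage is testable
without access to deposited data. All samplers are bit-reproducible given
the configuration: each (task, condition) pair derives its own seed from
the base seed, so regenerating one task does not disturb another. The
agents, with defaults anchored to the observed behavioral landscape of
one-shot web games and fixed once:

* **Speakers** sample from the informative-speaker distribution at
  `alpha_speaker = 4` — a word twice as specific as its alternative is
  chosen with probability $1/(1+2^{-4}) \approx 0.94$, matching the
  near-deterministic informativeness observed in speaker tasks (the
  $\alpha = 1$ model used for *predictions* is deliberately not assumed
  for *behavior*). Ties between equally informative words are broken by a
  noun bias of 0.70 toward the shape word.
* **Salience choosers** pick uniformly apart from a 16% relative
  increment for the middle position (`salience_bump = 0.16`), except in
  reducible contexts where the unique-featured competitor draws a 0.75
  base share — the strong pop-out such displays elicit.
* **Listeners** observe the condition's word and follow the RSA posterior
  with probability `lambda` (per cell type) and the literal posterior
  otherwise, both under the generative salience prior; an optional
  `lapse` adds uniform guessing over the *literally matching* objects
  only, because non-literal responses are excluded upstream and so never
  appear in analysed data. The preset `lambda` is 0 everywhere except the
  solvable color-word cells, where it is 1: pragmatic responding has been
  observed consistently only there, and the generator exposes the
  per-cell weight as a knob rather than asserting a mechanism for the
  color/shape asymmetry, which neither model explains.
* Exclusion metadata is generated too (10% non-native, 3% attention
  failures, 1% uniform random responders), so the exclusion pipeline has
  realistic work to do.

The presets select the study designs: experiment 1 runs all 24 conditions
and three tasks; experiment 2 the solvable conditions without a speaker
task; experiment 3 all eight pragmatic conditions.

What the generator does **not** emulate: participant heterogeneity beyond
the mixture (no per-subject parameters), word-class expectation effects on
listeners, response times, engagement ratings, and any perceptual detail
of the stimuli (chroma, rendering). Consequently, passing pipeline tests
on synthetic data demonstrates that the machinery — filtering,
aggregation, prediction, fitting, comparison — is correct under the
assumed generative structure; it does not by itself validate the models
against human behavior, and fits on synthetic data are cleaner (higher
$r$) than fits on real data, whose noise sources the mixture does not
model.

## Estimating the pragmatic mixture weight

`recover_lambda()` estimates the probability that a listener trial follows
the RSA rather than the literal posterior, by maximum likelihood over a
grid of step 0.01 on the trials from pragmatic conditions (elsewhere the
two posteriors coincide and carry no information). The fitting prior
defaults to uniform; an empirical salience table can be supplied. A lapse
rate can be fixed in the likelihood; mixture probabilities are floored at
1e-12 so an isolated zero-probability response cannot sink the whole
likelihood. Uncertainty comes from a bootstrap percentile interval over
participants (trials), which is the natural resampling unit in a one-shot
design.

Parameter recovery was sized as follows: with eight pragmatic conditions
at 500 trials each, the mixture's Fisher information (~0.05 per trial)
puts the replicate standard deviation of $\hat\lambda$ near 0.07, so
single runs scatter accordingly while the mean over 20 replications pins
the true value to within a few hundredths. The acceptance suite asserts
the replication-averaged recovery at true $\lambda \in \{0, 0.5, 1\}$,
plus single-run recovery at the extremes; recovery runs use a
neutral-salience configuration (uniform generative prior) so the fitted
and generative priors match and the check isolates the mixture machinery.

## Numerical choices

* Distribution equality (classification, ambiguity) uses an absolute
  per-cell tolerance of 1e-9: every quantity involved is a small exact
  rational represented in floating point, so this is conservative by many
  orders of magnitude. The test oracle re-derives posteriors in exact
  integer arithmetic and demands agreement to 1e-12.
* Positions are 0-based patterns internally but serialized as
  `left`/`middle`/`right`; the target is always `middle`.
* Reported CSV tables round to two decimals in the style of published
  tables; the accompanying JSON carries full precision.
* Problem sizes in the tests and acceptance script (12–500 trials per
  condition depending on the check, 1000-case property sweeps, 20
  recovery replications) were chosen to keep Monte-Carlo error well below
  the asserted tolerances.

## Known limitations

The package evaluates the *basic* RSA model only: one level of recursion,
fitted to nothing ($\alpha = 1$ throughout for predictions), constant word
cost, deterministic truth functions. Extensions with fitted rationality,
utterance cost terms, deeper recursion, or graded semantics are out of
scope, as are regression-tree analyses of feature importance and any
treatment of the noun/adjective expectation asymmetry, which the basic
model cannot capture. Experiment-2-style per-context analysis is
supported through the `item` aggregation unit, but the generator produces
one participant per context, not the ten-per-context design a deposited
dataset would have.
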