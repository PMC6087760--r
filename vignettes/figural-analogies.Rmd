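---
title: "Generating and calibrating figural analogy items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and calibrating figural analogy items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(figana)
```

## The measurement problem

Figural proportional analogies (A:B::C:D) are classic indicators of
analogical reasoning: the test taker must infer the transformation that turns
A into B, apply it to C, and pick the resulting D among response options.
Writing such items by hand is slow and error-prone; automatic item generation
replaces hand-writing with an *item model* whose structural features
(**radicals** — the transformation rules) determine the psychometric
difficulty, while surface features (**incidentals** — the initial positions
of the figure's parts) vary randomly across clones (**isomorphs**) without
intended effect on difficulty.

`figana` implements the whole chain: a geometric figure, a rule algebra, an
isomorph generator with distractor assembly, rendering, and the conditional
maximum likelihood (CML) psychometrics — Rasch model and Linear Logistic
Test Model (LLTM) — used to test whether the rules really predict
difficulty. A seeded response simulator closes the loop, so every
statistical claim made by the package is testable by parameter recovery
without any empirical data set.

## The figure and its reference geometry

Items are drawn from one basic figure: a main shape with six corners
connected by five internal line segments forming a simple path
c1–c2–…–c6, a dot sitting on one corner, a broken circle (an arc glyph)
attached next to corners 5 and 6, and a small trapezium attached outside
the outline with its own rotational position. The main shape occupies one
of eight 45°-spaced rotational states and can additionally be reflected;
the trapezium independently occupies one of eight states; the dot sits on
one of six corners. The incidental space of shape A therefore has
8 × 2 × 8 × 6 = 768 configurations.

No canonical coordinate set exists for this figure family, only its
topology, so the package fixes a concrete *reference geometry*: six corner
coordinates on an irregular convex outline spanning the unit box, with the
path corners visiting the outline in a zig-zag order so the path edges run
through the interior. Four presets each are available for the internal-line
arrangement (`form_int`) and the trapezium (`form_ext`); all share the
topology, preset "A" is the default everywhere. Any fixed geometry
satisfying the topology supports every rule; the tests that matter are
topological (path length, rotation algebra), not metric.

Two numerical conventions make the transformation algebra exact:

* **State indexing.** Main/trapezium state *k* means a rotation of
  45·(k−1) degrees counterclockwise from the template, so rotation is
  modular addition and a rotation by α composed with −α is the identity by
  construction.
* **Reflection.** Rendered as flip-then-rotate
  (T = R<sub>45(k−1)</sub> ∘ M<sub>x</sub><sup>f</sup>). Reflecting about x
  therefore toggles the flip flag and negates the state index
  (M<sub>x</sub>R<sub>θ</sub> = R<sub>−θ</sub>M<sub>x</sub>), which makes
  reflect∘reflect an exact identity, and y-reflection equal to x-reflection
  followed by a half turn — the identity that explains why reflection and
  main rotation may never be combined in one item (their compositions mimic
  each other).

## The rule algebra

Five general rules act on disjoint parts of the figure:

| rule (argument)          | effect A→B / A→C                                  |
|--------------------------|---------------------------------------------------|
| `main.rot = c(b, c)`     | rotate main shape by b, resp. c degrees           |
| `mirror = 1`             | reflect about x (A→B), about y (A→C)              |
| `trap.rot = c(b, c)`     | rotate the trapezium                              |
| `subtract = c(l1, l2)` or `"R"` | remove internal line l1, resp. l2          |
| `dot.mov = c(n1, n2)`    | move the dot n1, resp. n2 edges along the path    |

Angles are multiples of 45 within [−135, 180]; positive is
counterclockwise. Each general rule becomes a *specific* rule once its
arguments are fixed; the canonical nine-rule catalogue
(`specific_rules()`) distinguishes short clockwise, short counterclockwise
and long rotation variants for the main shape and the trapezium. The two
dot-movement counts must sum to five at most because the path has five
edges, and the two subtraction lines must differ — with an equal pair the
second pathway would remove an already-absent line and D could not be
formed.

Both solution pathways (A:B::C:D and A:C::B:D) must reach the same D. The
radicals act on disjoint state components, so the application order of
simultaneous rules is immaterial; the package fixes
reflection/rotation → trapezium → subtraction → dot movement to make
generation deterministic. Two build-time resolutions are worth noting:

* **Random subtraction** (`subtract = "R"`) draws a distinct line pair per
  item when the stem is built.
* **Dot travel direction.** The direction of dot movement is resolved once
  per item from shape A: toward corner 6 if the combined two-leg traversal
  fits, else toward corner 1, and it is stored with the item's rules. The
  obvious alternative — choosing a direction independently at each
  application — breaks pathway commutation (from corner 3 with moves
  (2, 1): B lands on 5, then 6; C lands on 4, then 6 only if the direction
  is shared), which is why the direction is a property of the item, not of
  the single move. When the travel sum exceeds 3 and the current corner
  cannot host both traversals, the dot of A is relocated to the nearest
  feasible corner among those attached to the broken circle (a sum of 5
  forces the path endpoint, corner 6); sums up to 3 are feasible from every
  corner.

## Isomorph generation

`build_analogies()` draws shape A for each isomorph from a seeded
permutation of the (possibly restricted) incidental product space; after
768 draws the same permutation runs again, so a bank larger than the
capacity records a repetition warning (warnings are data on the bank, never
interactive prompts). Constricting a part (`constrict = "main"`, `"trap"`,
`"dot"`) reorders the traversal so every consecutive block covers all
positions of that part — useful for small banks that must exhaust, say, all
eight main-shape positions. For restricted spaces the capacity is computed
as the product of the active domain sizes.

The correct answer's position (1–8, or 9 for "no answer is correct") is
drawn at random from 1–8 by default; position 9 is only used on explicit
request since a keyed "no answer" option is known to risk reliability
problems in practice (the generator logs nothing more than the key — the
concern is empirical, not structural).

## Distractors: the Solutions Combination Design

For every rule in an item a correct solution and a set of alternative
(incorrect) solutions are generated, and options are the combinations of
per-rule solutions. The designs, by rule count:

* 1 rule: 4 × 2 — four solutions of the manipulated rule crossed with two
  of an *extra* rule absent from the stem (drawn at random among the
  compatible general rules). Because an extra reflection-type alternative
  would act on the same state component as a rotation alternative, items
  whose single rule is main rotation or reflection draw their extra rule
  from the trapezium/subtraction/dot families only.
* 2 rules: 3 × 3 with one of the nine combinations eliminated. All four
  both-incorrect candidates differ from the key in exactly the same number
  of parts (two), so "eliminate the most similar non-key combination"
  reduces to a seeded uniform draw among them — the tie-break is the rule.
* 3 rules: 2³, nothing eliminated.
* 4 rules: 2⁴ with the combinations holding exactly three correct or three
  incorrect solutions eliminated, balancing the mix.

Every design survives with exactly eight options, exactly one of which is
all-correct. Alternatives are *referenced to the right answer D*: rotation
alternatives are angular offsets from D (near misses ±45°, ±90° first, the
remaining distinct rotations only when a design needs more), reflection
alternatives are flip/rotation combinations, subtraction alternatives
remove up to two lines of A with at least one differing from the correct
subtraction, and dot alternatives are corners distinct in effect from D's
corner (auto-relocated on collision). Since every rule controls a disjoint
state component, distinct combinations yield distinct figures; the
assembler still verifies pairwise distinctness and names any colliding pair.

When position 9 is keyed, the all-correct option is replaced by a similar
near-miss: the key with one rule's solution swapped to a fresh alternative
that duplicates no existing option, falling back to a previously eliminated
combination. With the extra rule suppressed (`add.rule = -1`) a single rule
must furnish seven distinct alternatives on its own; rules that cannot
(e.g. dot movement, with only five other corners) fail loudly.

## Rendering

`plot.fa_item_bank()` and `export_bank()` draw the stem (A, B, C, blank D)
above the eight options in reading order, with the two verbal options —
"no answer is correct" (position 9) and "I don't know" (scored incorrect
at import) — beneath, in English, German or Spanish. Mode "A" (stem row
over a 4 × 2 grid) is the empirically supported layout and the default;
modes "B" (2-wide grid) and "C" (compact) are layout variants. Exports are
PNG files plus a UTF-8 CSV answer key (`item_id`, `correct_position`,
`rules_used` semicolon-joined); re-exporting the same bank overwrites with
identical bytes, and `switch_options()` exchanges two option slots while
the key follows its option.

## Conditional maximum likelihood: Rasch and LLTM

The Rasch model gives person ν probability
logistic(θ<sub>ν</sub> − β<sub>i</sub>) of solving item i. Conditioning on
the raw scores removes θ entirely: with ε<sub>i</sub> = exp(−β<sub>i</sub>)
and γ<sub>r</sub> the elementary symmetric function (ESF) of order r, the
conditional likelihood depends on the data only through the item margins
and the raw-score counts. Persons with all-correct or all-incorrect scores
contribute nothing and are dropped; missing responses are handled by
conditioning each person on their observed item subset (grouped by
missingness pattern).

The LLTM restricts β = Qα: each item difficulty is the weighted sum of
**basic parameters** α<sub>j</sub> — the difficulty contributions of the
cognitive operations — with binary weights ω<sub>ij</sub> from the Q
matrix (`qmatrix_from_bank()` derives Q from a generated bank at
five-general-rule or nine-specific-rule granularity).

Numerical choices:

* ESFs by the summation recursion (all positive terms, stable at these test
  lengths); first derivatives via single-item-deleted ESFs, the observed
  information via pair-deleted ESFs.
* Newton–Raphson with step halving; convergence when the gradient
  ∞-norm falls below 1e−8 or the update no longer moves the parameters
  (the likelihood's floating-point noise floor grows with its magnitude,
  so very large samples can stall a pure gradient criterion a hair above
  the threshold); 200 iterations cap.
* **Identification.** The conditional likelihood is invariant under
  β → β + c, so the Rasch fit fixes one contrast during optimization and
  reports mean-centered β with observed-information standard errors (the
  centering matrix propagates through the covariance). Sum-to-zero and
  reference-item conventions are interconvertible. For the LLTM, α is
  identified exactly when Q has full column rank and the constant vector is
  *not* in its column span — a Q whose rows all sum to the same value (for
  example, one ω = 1 per row in a single column) is rejected with an
  identifiability error, because only difficulty differences are estimable.
  `beta_hat` is returned as Qα exactly; a centered copy is provided for
  comparison with Rasch estimates.

Model tests follow the standard conditional toolkit: Andersen's LR test
(default split at the raw-score median, ties to the lower group,
df = (groups − 1)(items − 1) — 22 for a 23-item test with two groups), the
per-item Wald test on commonly centered subgroup estimates, and the
Rasch-vs-LLTM deviance comparison with df = (items − 1) − p — 17 for
23 items and five basic parameters, 13 for nine. Cronbach's α is included
as the customary reliability utility.

## The simulator and what passing tests show

`simulate_responses()` draws abilities from N(mean, sd²) (defaults 0, 1 —
the ability distribution the analysis assumes) and Bernoulli responses from
the Rasch kernel, with named seed substreams for abilities and responses so
either component reproduces independently. The synthetic 23-item
*reference test* (`build_reference_test()`) covers all nine specific rules
with rule counts one to four; the exact composition of the originally
administered items is not publicly available, so this bank is a synthetic
stand-in that reproduces the design logic, not the items. Its companion
`fa_reference_alpha()` ships published nine-rule basic-parameter estimates
(traditional CML LLTM) as demonstration values — empirical estimates, not
ground truth.

The test suite's problem sizes are chosen to make sampling error
negligible relative to the tolerances while keeping a default run fast:
2 000 simulated persons for LLTM recovery (each of 100 replications must
place all nine α̂ within 3 estimated SEs of the generating values in at
least 95% of runs), 500 replications of 300 persons × 15 equally spaced
difficulties in [−1.5, 1.5] for the Andersen type-I rate (nominal 0.05,
accepted within 0.03–0.08), and exhaustive sweeps wherever the space is
finite (768 incidentals, all single- and two-rule sets, every SCD design).

What the simulator does *not* emulate: guessing and slipping, response
times, person misfit, multidimensionality, and the attractiveness of
individual distractors. Passing recovery tests therefore show that the
estimators are correct for data that follow the Rasch/LLTM process — they
do not show that real examinees behave this way, and empirical LLTM fits
on real data are routinely (and expectedly) worse than the Rasch model's.

## Known limitations

* The reference geometry and the plot-mode "B"/"C" layouts are this
  package's own conventions; only the topology and mode "A" reading order
  carry over from the published item family.
* Only complete 0/1/NA matrices are calibrated; "I don't know" responses
  must be scored (conventionally as incorrect) before import.
* No marginal-ML or Bayesian estimation, no 2PL/3PL, no random-effects
  LLTM; the conditional framework is the point here.
* A keyed position 9 can exhaust the near-miss pool for impoverished rule
  sets; the assembler then fails with an explicit error rather than
  emitting a duplicate option.

## A worked example

```{r, eval = FALSE}
library(figana)

# four isomorphs of a two-rule item model
bank <- build_analogies(isomorphs = 4, main.rot = c(180, 135),
                        dot.mov = c(1, 2), seed = 42)
export_bank(bank, "items/", language_dir = "E")

# calibrate simulated data for the 23-item reference test
test <- build_reference_test(seed = 1)
q9 <- qmatrix_from_bank(test, 9)
x <- simulate_responses(lltm_predict(q9, fa_reference_alpha()),
                        n_persons = 500, seed = 2)
rasch <- fit_rasch(x)
lltm <- fit_lltm(x, q9)
summary(lltm)
compare_deviance(rasch, lltm)
andersen_lr(x)
```
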