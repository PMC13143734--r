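---
title: "Cultural precision, moral typing, and structure learning: the models behind transcend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cultural precision, moral typing, and structure learning: the models behind transcend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcend)
```

`transcend` simulates small societies of active-inference agents to study a
specific question: what does it take, computationally, for agents to treat
each other not just as behaving well or badly, but as *being a certain kind
of agent* — faithful to shared norms or egocentric — and for that moral
typing to stabilize cooperation through declarations and sanctions? This
vignette explains the models the package implements, the parameters that
matter, the numerical choices, and what the synthetic world does and does
not capture. All indices in code and reports are 1-based.

## The agent model

Each agent is a discrete partially observable Markov decision process
(POMDP). A model consists of:

* **A** (likelihood): one array per sensory modality giving
  $P(o \mid s_1, \dots, s_F)$, outcome index first. Each state-column is a
  categorical distribution.
* **B** (transitions): one array per state factor giving
  $P(s' \mid s, u)$ for each control $u$.
* **C** (preferences): per-modality log-preferences over outcomes,
  unnormalized; they enter planning through `softmax(C)` so that risk is a
  well-defined KL divergence.
* **D** (state prior) and **E** (habit prior over policies).
* Dirichlet counts `pA`, `pE` from which A and E are re-derived after
  learning, floored at $10^{-3}$ so sparse evidence can never create exact
  zeros that lock the model up.

The default world-facing model (`foraging_model_spec()`) uses five state
factors — own satiety (3 bins), current-patch stock (3 bins), partner
identity (one slot per known agent plus a stranger slot), partner's last
move (cooperate/defect/conceal/none), and own social standing
(good/suspect) — and six modalities: satiety, patch yield, partner
identity, partner action, heard signal, and a declaration channel. This is
one admissible inventory, chosen as the smallest that supports cooperative
scarce-resource foraging, signalling, concealment, and norm enforcement.
Two elements deserve justification because they go beyond the minimum:

* the **standing** factor is the pathway by which concealment becomes
  costly *inside the agent's own model*: concealing shifts standing toward
  "suspect", and suspect standing raises the predicted probability of
  observing a declaration, which culturally-preferenced agents dislike;
* the **partner-identity observation** makes the identity factor
  observable, so Dirichlet learning of the partner-action likelihood
  becomes identity-conditioned — the mechanism of dyadic familiarity.

## Perception, free energy, and its decomposition

Perception inverts A by minimizing variational free energy. With a single
factor the posterior is exact Bayes; with several factors the package runs
a damped mean-field fixed point (damping 0.5, tolerance $10^{-8}$, at most
64 sweeps). Because each coordinate update maximizes a concave one-factor
objective, the damped iteration cannot increase free energy; the test
suite checks this on random models, along with exactness of
$F = -\ln(\text{evidence})$ in the one-factor case.

`free_energy()` reports the decomposition

$$F = -\underbrace{E_Q[\ln P(o \mid s)]}_{\text{accuracy}}
  + \underbrace{\mathrm{KL}[Q(s^{(1)}) \| P(s^{(1)})]}_{\text{level-1 complexity}}
  + \underbrace{\mathrm{KL}[Q(s^{(2)}) \| P(s^{(2)})]}_{\text{level-2 complexity}}
  + \underbrace{\mathrm{KL}[Q(\alpha) \| P(\alpha)]}_{\text{transcendental}}$$

in nats. For a one-level agent the higher-order and transcendental entries
are zero. The precision $\alpha$ is a fixed configuration scalar by
default; `infer_alpha()` implements the opt-in alternative of inferring it
on a discrete grid, with the KL of its posterior from its prior reported
as the transcendental term. We default to the fixed reading because it is
the simpler of the two supported uses, and the two levels of the
implemented hierarchy use a full mean-field factorization across levels
(structured cross-level posteriors are future work).

## Planning: expected free energy

Policies are open-loop action sequences of horizon $H$ (default 2) over a
configurable action subset (default forage/share/conceal — signals and
declarations are driven by dedicated machinery, see below). Each policy is
scored by expected free energy
$G = \sum_t \big(\text{risk}_t + \text{ambiguity}_t\big)$, with risk the
KL of predicted outcomes from `softmax(C)` (pragmatic value) and ambiguity
the expected outcome entropy of A under predicted states (epistemic
value). The policy posterior is $q(\pi) \propto E(\pi)\,
e^{-\gamma_{\text{policy}} G(\pi)}$ with $\gamma_{\text{policy}} = 2$ by
default; actions are sampled (reproducibly under a seed) or taken by
argmax with a lowest-index tie-break.

## Two levels and the precision gain alpha

Two-level agents (V2, or V3 after expansion) add a categorical typing
factor over the current partner, with configurable labels — binary
in-group/out-group by default, but any list of two or more labels (for
example Sage/Citizen/Soldier) is accepted. Message passing each tick:

1. **ascend**: the level-1 posterior over the linked factor
   (partner-move) is mapped through a summary matrix into a *soft*
   observation for level 2. Soft rather than sampled, so level-1
   uncertainty is preserved and the pipeline is deterministic given
   actions.
2. **level-2 update**: an expected-log-likelihood update of the typing
   posterior, kept per partner identity.
3. **descend**: the link matrix M turns the typing posterior into a
   top-down prediction for the linked level-1 factor, which is blended
   with the bottom-up belief log-linearly:
   $q_{\text{eff}} \propto \exp[(1-\alpha)\ln q + \alpha \ln m_{\text{top}}]$.

The blend is geometric, not arithmetic, because only the geometric form
satisfies both boundary contracts exactly: $\alpha = 0$ reproduces the
bottom-up belief bit-for-bit (a V2 agent with $\alpha = 0$ is
trace-identical to its V1 twin, which the tests assert across seeds), and
$\alpha = 1$ reproduces the top-down prediction exactly regardless of the
base's support. The blended belief is what planning sees, so high-$\alpha$
agents act on typing expectations; it is also rolled through B to become
the next tick's empirical prior, so a typed partner's defection produces
strictly larger free energy under high $\alpha$ — expectation-driven
surprise amplification. Level 2 can run at a slower timescale
(`k_timescale`, default 1 update per level-1 tick).

Each agent carries an *effective* $\alpha$ at runtime. Consuming a
verified declaration raises every observer's effective $\alpha$ by the
world's `alpha_increment` (default 0.1), capped at 1: public accusation
makes cultural expectations dominate in the audience.

## Moral typing as model comparison

An observer scores a watched agent under two behavioural models that share
likelihoods and transitions and differ only in preferences: the
**cultural** model prefers seeing cooperation and not being declared; the
**egocentric** model cares only about its own satiety. Each observed
action contributes its log evidence ratio to a running score:

$$\ln \frac{P(m \mid o)}{P(m' \mid o)} = \Delta F + \Delta G, \qquad
\Delta F = \sum_k \big[\ln P(o_k \mid m_{\text{culture}}) -
\ln P(o_k \mid m_{\text{ego}})\big],$$

where the per-action probabilities are the models' own softmax action
distributions in context. $\Delta G$ encodes prior model odds from
expected free energy. One convention point is worth making explicit: under
$P(m) \propto e^{-G(m)}$, a *lower* expected free energy must mean a
*higher* prior probability, so the package computes
$\Delta G = G(m_{\text{ego}}) - G(m_{\text{culture}})$ (each model's G
aggregated over its action set by a softmin at the policy temperature).
The opposite orientation is one sign flip away for anyone who prefers it.
$\Delta G$ is computed once per context and added once to the log odds;
only $\Delta F$ accumulates over time.

P(cultural) is the logistic of the log odds, capped at $\pm 50$ for
numeric safety. A **declaration** fires when P(cultural) falls below
$\theta_{\text{deviant}} = 0.5$ *after having reached at least*
$\theta + 0.1$ (hysteresis), at most once per crossing. In the simulation
loop, a firing watcher replaces its planned action with
`declare(target)` for that tick — a speech act prioritized over foraging —
while `declare` also remains available as an ordinary scripted action.
Sanctions verify world-truth: a declared target with a concealment inside
the lookback window loses its inventory (returned to the patch) and is
banished; declarations against innocents are logged as false and change
nothing.

## Structure learning (V3)

A V3 agent starts one-level and may grow the typing factor itself. Two
conditions must hold simultaneously:

1. **stalled reduction** — over a full window of W = 50 ticks, the first
   half's mean total F exceeds the second half's by less than
   $\varepsilon = 0.01$ nats, and at least 100 ticks (cooldown) have
   passed since the start or the last expansion;
2. **residual surprise** — the window-mean predictive surprisal on the
   partner-action channel is at least `surprise_floor()` = 1.0 nats.

The second gate exists because stalling alone cannot distinguish "my model
is as good as it can get and the world is simple" from "my model has hit a
ceiling it cannot explain": a homogeneous population also plateaus, just
at a low surprisal. The floor's value is derived, not fitted: under the
default observation noise (0.85 correct-identification probability), a
single consistent behavioural profile (share 0.9 / forage 0.1) leaves
about 0.77 nats of irreducible per-observation surprisal, while an even
mixture of that profile with a deviant profile (forage 0.5 / conceal 0.5)
leaves about 1.22 nats; 1.0 is their midpoint.

Expansion adds exactly one typing level with K states (default 2, richer
taxonomies via config). The link and level-2 likelihood columns are drawn
from Dirichlet distributions (total concentration 100 per column) centred
on the agent's *own* accumulated per-partner move statistics: partners
with at least three observations are ordered by their cooperate share and
split into K quantile groups, and each group's mean distribution becomes a
column's Dirichlet mean. With fresh statistics the columns are
near-symmetric. No oracle labels are used anywhere. Typing beliefs for
already-known partners are seeded from their empirical move distributions.
Pruning proposals are scored by `reduce_model()`, the analytic log-evidence
difference between reduced and full Dirichlet models (log multivariate
Beta normalizers, with merged columns pooling their data); the score is
antisymmetric under swapping the two roles.

## The world

The generative process is a patch-based foraging economy. Per-forager
yield on a patch with $n$ extractors is
$\min(\text{stock}/n,\; y_0 (1 + c(n-1)))$, so cooperation raises
per-capita yield until the patch cannot support it; stock regenerates
toward the cap at rate $r$. Foraging feeds the agent, concealing diverts
the harvest to private inventory (world-true, detected by a co-located
observer with probability `p_detect`, default 0.5 — concealment is risky,
not certain), sharing splits inventory across all co-located agents.
Satiety decays one unit every 5 ticks to keep foraging pressure on.
Resource bookkeeping is exact: stocks + inventories + cumulative consumed
units equal the initial total plus regeneration inflow to within 1e-9 on
every tested run.

Encounters: each tick, participating agents are paired symmetrically.
With probability `stranger_rate` a partner is drawn uniformly among
non-familiar agents (familiar = at least `f_min` = 3 prior co-located
ticks; the polarization study lowers this to 1); otherwise among familiar
agents with probability $\propto \exp(\gamma_{\text{att}} \cdot
P(\text{cultural}))$ — confirmation-biased attention. An odd agent
forages alone. Tag-based (shibboleth) structure is represented by
observable group tags on agents and signals plus the typing categories,
not by a third inference level; the two-level tower is the deliberate
scope of this implementation.

Within a tick the order is: encounters, actions, sanctions, satiety
decay, regeneration, observation synthesis. Illegal actions (a banished
agent trying to forage, a declaration without target) are rejected and
logged; the simulation never aborts mid-run. All randomness flows through
R's global RNG, so a configuration plus seed reproduces a bit-identical
trace.

## Metrics and study designs

**Polarization.** The index of a belief vector is twice its population
standard deviation — 0 at consensus, 1 at an even split between the
extremes, $2\sqrt{1/6} \approx 0.8165$ for beliefs $(0, 0.5, 1)$. The
scalar belief of a watcher defaults to its *evidence-weighted* mean final
P(cultural) over watched targets: each target's posterior is weighted by
the number of observations collected on it. The unweighted target-mean is
available as an option, but it is structurally insensitive to attention
bias — once a watcher has scored every partner at least once, revisiting
favourites cannot change a plain mean over targets — whereas the
evidence-weighted form is exactly the quantity attention reshapes. The
packaged study (`harness_polarization()`) uses six watchers with one
consistently cooperative and one consistently deviant partner,
`stranger_rate` 0.2 (new partners arrive rarely), and 80 ticks; under
these conditions mean polarization rises with $\gamma_{\text{att}}$
across $\{0, 2, 8\}$. An earlier design that thinned per-tick
participation instead of the stranger channel produced candidate pools of
size one, where no weighting can apply — sparseness must leave the
*choice* intact.

**Signal information.** Plug-in mutual information (bits) between emitted
signal symbols and a sender label — group tag, or valence (low versus
not-low satiety at emission) — computed per tick window so that a
migration of signal content from internal state toward group identity
would be visible as MI curves crossing.

**Fitness.** The sum over ticks of the log preference probability
assigned to the realized satiety observation, under a fixed reference
preference vector; this is the common currency for comparing agent
versions, reported per agent and per group. The version-fitness and
$\alpha$-sweep harnesses emit their comparisons with a permutation test
and a unimodality flag respectively; both are *predictions* of the
framework and are reported (warn-level), not asserted as identities.

**Structure-learning regimes.** Twenty seeded 500-tick runs of one V3
forager among seven scripted partners, fully anonymous encounters
(stranger rate 1, so identity slots cannot explain the variation) and
certain detection. In the heterogeneous regime partners split into
cooperators (share 0.9 / forage 0.1) and deviants (forage 0.5 / conceal
0.5); in the homogeneous control all partners are cooperators. Expansion
rates and best-permutation alignment between learned types and true
groups are reported by `harness_structure_learning()`.

## Numerical choices

Natural logarithms everywhere except MI (bits). Probability floors:
$10^{-300}$ inside logs, $10^{-12}$ for predictive action probabilities
and for top-down zeros blended against positive base support, $10^{-3}$
for Dirichlet counts. Log-odds capped at $\pm 50$. Argmax ties break to
the lowest index. The mean-field damping/tolerance/iteration defaults are
stable for categorical fixed points of this size. Problem sizes in the
packaged studies (20 runs × 500 ticks for structure learning, 10 seeds
per attention-bias level, 200 + 200 scored action sequences) were chosen
as the smallest designs whose expected effects clear their decision
margins by comfortable multiples of the standard error.

## What the synthetic world does not show

The world is the package's own construction; passing its tests
demonstrates internal coherence of the mechanisms — typing from
behavioural evidence, declaration-driven precision dynamics, emergence of
typing structure from unexplainable heterogeneity — not claims about any
empirical population. Scripted partners have stationary behavioural
profiles; real agents adapt, which would couple typing and behaviour in
ways the fixtures deliberately exclude. Fitness is preference-based, not
reproductive; there are no generations. The hierarchy stops at two
levels; deeper towers (dyadic, shibboleth, and cultural strata as separate
inference levels) are collapsed into the typing factor plus world-level
tags. Transitions are fixed per configuration (B is not learned), signal
semantics are not learned end-to-end, and sanction legitimacy uses a
configurable declaration-count threshold (`consensus_k`, default 1)
rather than a deliberation process.
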