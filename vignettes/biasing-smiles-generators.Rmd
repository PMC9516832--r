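---
title: "Biasing a character-level SMILES generator: CRLV versus REINFORCE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biasing a character-level SMILES generator: CRLV versus REINFORCE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

De novo molecular design with deep generative models usually follows a
two-stage pipeline. First a *general model* $G$ is trained on a large corpus
of drug-like molecules written as SMILES strings, purely to learn the
grammar of valid molecules. Then $G$ is *biased*: fine-tuned so that its
samples concentrate in a target chemical space defined by property
constraints (an *objective*), without destroying what it learned in stage
one. The classic biasing tool is the REINFORCE policy gradient; its known
failure mode in this setting is catastrophic forgetting — the biased model
collapses onto a handful of reliably rewarded molecules and loses validity,
novelty and diversity.

smigen implements both that baseline and an alternative, *conditional
reduction of the loss value* (CRLV): keep training with the ordinary
cross-entropy objective of stage one, but scale the loss by a factor that
shrinks as the fraction of generated molecules that already satisfy the
objective grows. When the model generates mostly undesirable molecules, it
receives full-strength language-model training (which protects validity and
keeps it moving through chemical space); as soon as it generates desirable
ones, the updates vanish and the parameters freeze. The loop behaves like a
ratchet on the desirable fraction.

## The general model

$G$ is an autoregressive character-level language model: embedding →
stacked GRU layers → linear readout over the vocabulary. SMILES are
tokenized strictly per character (two-letter element symbols such as `Cl`
become two tokens), with three reserved specials — padding, sequence start
and sequence end — added because autoregressive sampling needs a start
symbol and a stop criterion. Records longer than 100 characters are dropped
at ingestion.

The readout defines next-character probabilities through a
temperature-scaled softmax

$$P(y_i) = \frac{e^{y_i/T}}{\sum_{j=1}^{k} e^{y_j/T}},$$

with $T = 1$ during training. At sampling time $T < 1$ sharpens the
distribution (higher validity, more duplicates), $T > 1$ flattens it. The
benchmark operating point is $T = 0.5$, a compromise between validity on
one side and uniqueness/diversity on the other; `temperature_sweep()`
reproduces that trade-off curve on any trained model.

Training minimizes teacher-forced cross-entropy. The standalone
`cross_entropy()` operation implements the printed definition with its
$1/k$ prefactor,
$CE(y_p, y_r) = -\tfrac{1}{k}\sum_i y_r \log y_p$; the training loop uses
the conventional per-position mean instead. The two differ by the constant
$1/k$ only, which merely rescales the learning rate; both are exposed so
either convention can be checked, and the default is documented.

Reference architecture: 3 GRU layers × 512 units, Adam at learning rate
0.0005. The embedding width is not pinned by the architecture description;
the default is 128 and configurable. Batch size, padding and loss masking
are implementation decisions: sequences are padded per batch with the pad
token and padded positions are masked out of the loss. The full-scale
protocol (millions of molecules, 2500 epochs) is reachable through
`gen_config()`, but every shipped test and example runs at desk scale
(see "Problem sizes" below).

The GRU, backprop-through-time and Adam are implemented in vectorized base
R. At the desk scales used here (1 layer × 64 units, vocabularies of ~15
tokens, sequences ≤ 30 characters) a full training run takes seconds on one
CPU; all randomness flows from explicit integer seeds, so every training,
sampling and biasing run is bit-reproducible.

## Chemistry

All molecule handling — strict validity (parse + sanitize),
canonicalization, descriptors (Crippen logP, molecular weight, Lipinski
H-bond donor/acceptor counts, rotatable bonds, ring perception), SMARTS
functional-group matching, and Morgan fingerprints — is delegated to RDKit
through a batched Python bridge (a persistent worker with a one-shot
fallback and a per-session cache). Validity is deliberately strict: a
string counts as valid only if RDKit builds and sanitizes the molecule, so
downstream descriptor calls can never fail. Canonical SMILES are RDKit's;
every set comparison in the package (novelty, uniqueness, intersections)
operates on canonical forms.

## The objectives

Five built-in desirability predicates over descriptor tibbles
(`builtin_objective("obj1")` … `"obj5"`), all with inclusive boundaries:

1. lipophilicity: $\log P \le 3$;
2. structure: exactly 2 aromatic and 1 non-aromatic ring, at least one of
   –OH, –COOR, –COOH, –NH2, and an R-value within $[0.05, 0.50]$;
3. the full rule of three: $\log P \le 3$, MW $\le 480$ g/mol, HBA $\le 3$,
   HBD $\le 3$, rotatable bonds $\le 3$;
4. objectives 2 and 3 simultaneously;
5. objective 2 with *all four* functional groups required.

Two conventions deserve comment. Ring counts split the SSSR into aromatic
rings (every ring atom aromatic) and non-aromatic rings (the remainder);
this is stated here as the package's convention because ring-counting
dialects differ between toolkits. The *R-value* of objectives 2, 4 and 5 is
defined only in secondary literature we do not reimplement; the shipped
`r_value` column is a clearly documented **placeholder** (rotatable bonds
per heavy atom), the descriptor slot is pluggable
(`compute_descriptors(smiles, r_value = your_function)`), and the clause
can be disabled (`use_r_value = FALSE`). The functional-group SMARTS
patterns are config-visible (`fg_patterns()`,
`options(smigen.fg_patterns = ...)`) so a chemist can amend them. Custom
objectives load from YAML clause lists (`objective_from_yaml()`).

## CRLV

Each biasing epoch:

1. sample `n_probe` molecules (default 20) and measure the desirable
   fraction $d$ — desirable means *valid and* objective-satisfying;
2. compute the loss scale $s(d)$; the default rule is linear, $s = 1 - d$,
   which satisfies both limit requirements: at $d = 0$ the backpropagated
   loss is exactly the general-training loss, at $d = 1$ the update is
   exactly zero. A step rule (`"step@tau"`: full loss while $d < \tau$,
   then $\varepsilon = 10^{-3}$) is available for comparison;
3. run one pass of teacher-forced training over randomly drawn corpus
   batches with the loss (equivalently, the gradients) multiplied by
   $s(d)$.

Design decisions worth recording: $d$ is estimated once per epoch, not per
batch — estimating more often would multiply sampling cost without changing
the ratchet semantics; probes sample at the same temperature as the final
benchmark
(default 0.5), so the optimized quantity is the measured one; and the
scale multiplies the per-batch mean loss, the natural reading of "reduce
the loss value" within an otherwise unchanged training loop.

Both biasing loops share the *best-epoch* rule: after every epoch the
current model generates $k = 20$ molecules, and the checkpoint is kept only
if its desirable count **strictly** surpasses the best so far (ties keep
the earlier, less-fine-tuned model — the conservative choice under
catastrophic forgetting). The unbiased input model is the epoch-0
reference, so a run that never improves returns it unchanged.

## REINFORCE

The policy-gradient baseline maximizes $J(\theta) = E[r(s, a)]$ by gradient
ascent on $\sum_t \log p(a_t \mid s_t)\, r$ per episode, averaged over the
batch. An episode is one sampled SMILES; the terminal reward is broadcast
to every step, with no discounting and no baseline subtraction (a
moving-average baseline is config-gated and off by default). Episode
termination is identical to sampling: end token or 100 characters.

The reward values are not canonical — hand-engineered rewards are a known
reproducibility sore point for policy-gradient molecule generators — so the
table is fully configurable with defaults 1 (valid and desirable), 0 (valid
only), −0.1 (invalid), validated so that
desirable > valid-undesirable ≥ invalid.

Implementation note: the REINFORCE update reuses the same weighted
cross-entropy backward pass as supervised training, with per-episode weight
$r_b / B$. This makes two contracts easy to verify mechanically: a
zero-reward batch leaves parameters exactly unchanged, and with a constant
unit reward the update equals the supervised gradient up to the
normalization ratio. The test suite asserts both, plus sign-linearity of
the gradient in the rewards.

## The evaluation funnel

`run_funnel()` applies, in order: **validity** (fraction of generated
strings RDKit accepts), **novelty** (fraction of valid molecules whose
canonical form is absent from the training set), **uniqueness** (fraction
of novel molecules surviving canonical deduplication), **internal
diversity** (1 − mean pairwise Tanimoto similarity of Morgan fingerprints,
radius 2, 1024 bits, averaged over the full $|S| \times |S|$ matrix
including the diagonal — which makes the singleton case well-defined and
score 0), and **desirability** (fraction *and count* of unique molecules
satisfying the objective). Every stage's fraction is relative to the
previous stage's survivors.

Desirability is always reported both ways because percentages mislead when
funnel attrition differs between models: a collapsed model can convert 100%
of its five unique molecules and still deliver fewer desirable molecules
than a diverse model converting 10% of a thousand. The report schema
carries both, and the suite includes a constructed case where the
percentage ranking and the count ranking disagree.

Fingerprint parameters (1024 bits, radius 2) are the stated convention for
the intersection/projection analysis and are reused for internal diversity;
both are config-exposed.

## Structural variance and objective difficulty

The difficulty of biasing toward an objective tracks two quantities: the
objective's frequency in the training corpus, and the *structural variance*
(SV) of the satisfying molecules,

$$SV(\text{SMILES}) = \frac{\#\,\text{distinct characters}}{100},$$

with 100 the global maximum length. Dividing by a fixed global length —
rather than each molecule's own length — keeps a common reference so values
are comparable across molecules; the per-length variant is shipped
(`structural_variance_per_length()`) but documented as a non-canonical
diagnostic. SV counts characters of the raw whitespace-stripped string, not
tokens, matching the per-character tokenization. `difficulty_profile()`
reports both ingredients for any corpus and objective.

The intuition: molecules needing many distinct characters expose the
generator to more opportunities for validity-breaking mistakes, so
equally frequent but higher-SV targets take longer to learn. The test suite
checks exactly this at desk scale, with two planted string populations of
equal corpus frequency and different SV.

## The synthetic fixture corpus

`generate_fixture_corpus()` assembles chemically valid SMILES from
parametric templates: linear C/N/O chains, branches, double bonds, benzene,
pyridine and aliphatic rings, with a `ring-rich` variant for ring-heavy
corpora. It emulates the *statistical shape* a character-level model needs
— a modest alphabet, recurring substrings, length variation, a mix of
cyclic and acyclic molecules — and is deterministic per seed and 100% valid
by construction.

It does **not** emulate real screening libraries: no stereochemistry, no
charged or bracket atoms, no fused polycycles, a far narrower scaffold
distribution, and much shorter strings. Consequently the desk-scale tests
demonstrate *mechanisms* (validity learning, the CRLV ratchet, RL collapse,
temperature trade-offs), not full-scale performance numbers; nothing at
this scale should be read as a benchmark value for a model trained on
millions of molecules.

## Numerical choices and degenerate inputs

- $\log$ arguments are floored at $10^{-12}$, so zero predicted
  probabilities yield large finite losses, never `Inf`.
- Softmax uses max-subtraction; probabilities sum to 1 within $10^{-9}$.
- Weights initialize uniformly in $\pm 1/\sqrt{\text{fan-in}}$; Adam uses
  $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-8}$.
- Non-finite training or biasing loss aborts with a diagnostic rather than
  continuing silently.
- Empty generated strings are invalid by definition; an empty corpus after
  filtering, an empty set given to `internal_diversity()`, and an empty
  side of an intersection are explicit errors; an empty input to
  `validity_filter()` warns and returns fraction 0.
- Duplicate corpus lines are retained at ingestion — deduplication is an
  evaluation concern, and silently deduplicating would change the training
  distribution.
- Tokenization is per-character by design; a multi-character tokenizer
  would change the vocabulary, the model and SV, so it is deliberately not
  the default anywhere.

## Problem sizes used by the shipped tests

The test suite and examples run a deliberately small configuration chosen
to exercise every mechanism on one CPU: a 500-molecule fixture corpus, a
1-layer × 64-unit GRU (embedding 32) trained 30 epochs, 50-epoch biasing
runs with 20-molecule probes, funnel evaluations on 500-sample draws, and
three seeds for every comparative claim. The comparative experiment
reliably shows, at this scale, the dynamics expected of full-scale
models: both methods beat the unbiased model on desirable counts;
REINFORCE reaches higher raw desirability but its final model collapses
(often to a single unique molecule); CRLV's final model keeps validity and
uniqueness near the unbiased level; and lower-temperature sampling trades
uniqueness for validity.

## Known limitations

- The R-value descriptor is a placeholder (see above); objective-2/4/5
  results depend on it unless a real implementation is plugged in.
- CRLV's exploration is entirely inherited from the training corpus: it
  cannot bias toward a space the corpus never visits (the objective-5
  regime — extremely rare, high-SV targets — defeats both methods).
- Plain REINFORCE is implemented as the comparison baseline; no variance
  reduction beyond the optional moving-average baseline, and no PPO-style
  trust region.
- The pure-R network is CPU-bound; it is sized for desk-scale experiments
  and method development, not for training on millions of molecules.

## A worked desk-scale session

```{r example}
library(smigen)

corpus <- generate_fixture_corpus(500, seed = 7)
g <- train_general_model(
  corpus,
  gen_config(embedding_dim = 32, recurrent_layers = 1, hidden_units = 64,
             epochs = 30, batch_size = 50, seed = 1)
)

no_aromatic <- objective("no_aromatic", function(d) d$aromatic_rings == 0L,
                         "no aromatic ring")
probe <- sampling_config(temperature = 0.5, n_samples = 20, seed = 1)

crlv <- run_crlv(g, corpus, no_aromatic,
                 crlv_config(epochs = 50, seed = 101, sampling = probe))
rl <- run_reinforce(g, no_aromatic,
                    rl_config(epochs = 50, batch_episodes = 32,
                              learning_rate = 2e-3, seed = 101,
                              sampling = probe))

run_benchmark(crlv$best_model, corpus, no_aromatic, n = 500, seeds = 1:3) |>
  glance()
autoplot(crlv)
```
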