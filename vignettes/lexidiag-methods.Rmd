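---
title: "Models and methods behind lexidiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lexidiag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexidiag)
```

This vignette documents the models the package implements, the parameters
that matter, the numerical and design choices made where the design was
genuinely open, and what the simulations do — and do not — show about real
readers.

## The virtual reader

A `reader_profile` reduces a reader to the quantities that tachistoscopic
pseudoword testing can manipulate and measure:

* `capacity_by_time` — the maximum number of letters recognizable
  *simultaneously*, as a non-decreasing step function of fixation time on the
  50 ms grid from 250 to 500 ms. Queries off the grid clamp down to the
  nearest defined level: the testing protocol only ever uses the grid, so
  nothing finer is identifiable.
* `required_vrt_ms` — the minimal time from fixation onset to the earliest
  correct pronunciation. The same convention (measured from fixation onset)
  is used everywhere, including guided reading, where the acoustic go-signal
  is modelled as a timestamp rather than audio.
* `lapse_rate` — a residual error probability (at most 5%) when every
  condition is met, the standard psychophysical lapse parameter.
* `field_defect` — an optional homonymous visual field defect. Only defects
  involving the fovea mask letters: a right-sided foveal defect hides
  everything right of the fixated letter, a left-sided one everything left of
  it. The compensatory strategies re-aim the fixation: `gaze_to_end` (for
  right-sided defects) projects the whole segment into the spared left
  hemifield, `gaze_to_beginning` mirrors this for left-sided defects. A
  compensation on the wrong side is rejected as meaningless. No
  retino-cortical mechanism (temporal summation, magno/parvo pathways) is
  modelled; the defect is a pure visibility mask.
* `grapheme_confusions` — unordered letter pairs (p/q, b/d, m/n) whose
  sounds may be exchanged at pronunciation. Each occurrence of a confusable
  letter triggers an exchange independently with probability 0.5; no rate is
  available to estimate, so a maximally uninformative coin was fixed once.

A single recognition attempt (`recognize()`) is correct iff the window is
complete, the length is within capacity at the presentation time, the allowed
VRT is at least the required VRT, no lapse occurs and no confusion fires.
When the failure is letter-level (capacity or lapse), the error position is
drawn uniformly over the word — reflecting the empirical finding that errors
occur at all positions with no excess at word beginnings, ends, or crowded
interior letters. `error_position_profile()` exists precisely to check that
simulated error profiles stay uniform (chi-square goodness of fit).

### The synthetic cohort

`sample_cohort()` emulates the study populations: ceilings drawn from
{3, 4, 5, 6} letters with probabilities (0.3, 0.3, 0.3, 0.1) — "few" children
reach six, and no counts are published, so the three common ceilings are
equiprobable with 0.1 left for six. Each reader reaches the ceiling at a
threshold time drawn uniformly from {350, 400, 450, 500} ms, losing one
letter per 50 ms below it but never dropping under three (the shortest
diagnostic pseudoword; capacities below the staircase's starting length are
not identifiable by the protocol and are not generated). Required VRTs come
from a normal with the reported low preset (mean 1316, SD 712 ms) or high
preset (mean 1670, SD 641 ms), truncated below at 200 ms as a physiological
floor — the sources are silent on truncation, and 200 ms is well below any
plausible articulation latency. The truncation raises the low-preset
population mean to about 1404 ms; tests therefore compare sample means
against the analytic truncated mean, not the untruncated 1316 ms. Defaults:
whole-word strategy, compliance 0.9, lapse 0.02.

Extreme cases (e.g. a reader needing 9–11 s of VRT) are outside these priors
by design; they are supported through explicit `reader_profile()`
construction, not the sampler.

## The adaptive staircase

`run_staircase()` administers 20-item pseudoword lists at a (length, time)
cell, passing a list iff at least ⌈0.95·20⌉ = 19 items are read correctly.
Escalation order is length first at fixed time, then time — matching the
narrated procedure (start with 3-letter items at 250 ms; if they are
recognized, increase the number of letters; if letters are missed, lengthen
the fixation time in 50 ms steps up to 500 ms). During all capacity phases
the allowed VRT is *generous* (max time + 3000 ms), so pronunciation timing
never confounds capacity estimation.

A failed list triggers a spelling probe on a missed item: if the reader
cannot spell it, the failure is visual (capacity/fixation-time) and time
escalates; if the reader *can* spell it while the allowed VRT is generous,
the failure can only be a lapse streak, and the protocol re-administers up to
two fresh lists at the same cell. Without this retry, a 2% lapse rate would
spuriously fail about 6% of lists (two lapses in twenty items) and truncate
the capacity sweep early in roughly half of all sessions; with it, the
recovered ceiling stays within one letter of truth in well over 95% of
sessions. No failed list is ever re-administered item-for-item — retries draw
fresh items.

The minimal allowed VRT is bisected once, after the capacity sweep, on the
50 ms grid between the best cell's presentation time and the generous
allowance. Consequences: the estimate is exact-to-grid for lapse-free
readers whose requirement lies in that range; requirements below the
presentation time floor are reported *at* the floor (not observable by this
protocol); requirements above the generous ceiling are reported as `NA` and
flagged as a VRT cause. When the VRT sweep concludes that VRT was not
limiting, no second time-escalation is attempted.

Cause attribution uses the recovered map: a ceiling below the 8-letter cap is
labelled "trying to recognize too many letters"; capacity growth between
250 ms and the ceiling's threshold is "too short a fixation time"; a minimal
VRT beyond the 500 ms maximum fixation time (pronunciation cannot begin
within the fixation itself) is "too short a verbal reaction time".

## Pseudowords and grapheme clusters

"Pronounceable pseudoword" is operationalized as: every adjacent bigram is
attested in a reference lexicon and the item itself is not a lexicon word
(case-folded). This is a stand-in — the original testing material is
described only by that attestation property, and no phonotactic or
syllabification model is attempted. The bundled German lexicon (about 250
common colloquial words, realistic length mix) serves as the default; any
plain-text word list can replace it.

Cluster inventories list letter sequences that map to a single phoneme and
must never be split across segments: German {sch, ch, ie, ah, ei, eu},
English {ea, au, oa, aw}, French {eau, eaux, au, en, ou}. Entries beyond the
canonical examples are editable defaults. Matching is longest-cluster-first,
left to right, with overlapping occurrences resolved leftmost — deterministic
and consistent with "sch" containing "ch".

## The causal-condition engine

The engine formalizes the two definitions of the diagnostic framework. Let Δ
be the declared conditions and let the oracle map each met-subset S ⊆ Δ to
pass/fail. The oracle must be monotone (meeting more conditions never hurts);
this is checked exhaustively and non-monotone oracles are rejected with a
violating pair.

A set C ⊆ Δ is an *implicate* iff the maximal subset avoiding C fails, i.e.
oracle(Δ∖C) = fail; minimal such C are the prime implicates of the monotone
pass-function. Singleton prime implicates are exactly the irreplaceable
necessary conditions Γ (removing one alone abolishes reading); multi-element
prime implicates are the candidate interchangeable sets Λᵢ (at least one
member of each must be met; single members are replaceable, whole sets are
not); conditions in no prime implicate are superfluous. The classification is
*canonical* when the Λᵢ are pairwise disjoint and the reconstruction
pass(S) ⇔ Γ ⊆ S ∧ ∀i: S ∩ Λᵢ ≠ ∅ agrees with the oracle on every subset —
the only structure consistent with the framework's definitions. Because the
conjunction of all prime implicates always reproduces a monotone function,
non-canonical cases in practice have overlapping Λ sets rather than a
counterexample subset; a `witness` is reported only when a genuine
disagreement exists. Oracles outside the canonical family are reported as
such, never force-fitted.

Everything is exhaustive (hard cap 20 conditions, at most 6 in tests):
the universes in this domain are small because trivial conditions (eyes open,
functional visual system, …) are deliberately excluded from Δ, and the engine
never extrapolates to undeclared conditions (an uninvestigated background
colour is simply outside Δ).

One scenario in the source framework describes a child who cannot read at
the larger size or the longer time "but when … presented on a green
background" — as written this contradicts the surrounding summary, which the
worked example follows (two interchangeable sets: {size, time} and the three
backgrounds); the ambiguous variant is documented here and not encoded.

## The therapy simulator

Unguided reading follows the reader's own strategy with self-chosen
parameters, fixed once as model constants: 250 ms fixations and pronunciation
begun at 0.8 × the required VRT (premature pronunciation — the mechanisms are
described qualitatively in the source material, so the constants are the
package's own). Whole-word readers fixate each word's middle letter;
searching readers add to-and-fro eye movements (doubling time); hypermetric
readers jump capacity + 2 letters, leaving coverage gaps whose letters are
never seen; self-segmenting staircase readers split the text themselves at
their capacity with adequate timing (correct but slow); letter-by-letter
readers crawl. Isolated regressions are interspersed with probability 0.1
per transition and add time without ever changing correctness — they are
neither necessary nor sufficient for failure.

Natural words, unlike pseudowords, can be guessed from partial information.
The model: a failed attempt is rescued with probability 0.5 when at least
half the word's letters were recognized, 0.1 otherwise. The recognized-letter
count is itself a modelling choice: an attempt whose span fits within
capacity yields every visible letter (so a word failed only on timing can
still be guessed at 0.5), whereas an attempt *exceeding* capacity disrupts
simultaneous identification and reliably yields only the fixated letter
(guess at 0.1). This reflects the mechanism that attempting too many letters
at once is itself what breaks recognition — a reader who could cleanly
harvest their capacity's worth of letters from an oversized span would
effectively be segmenting, which is a different strategy.

Guided reading segments the text at the diagnosed capacity, enforces the
diagnosed fixation time and VRT, and withholds the next segment until the
previous one is read correctly. Compliance applies per attempt: with
probability `compliance` the enforced parameters are used (errors then arise
only from lapses); otherwise that attempt runs with the reader's self-chosen
parameters. A failed segment counts as one error regardless of how many
re-attempts it needs (a guard of 25 attempts prevents non-termination for
readers whose VRT exceeds even the generous allowance — such readers cannot
be helped within the protocol's parameter ranges and are reported
accordingly).

Reading time is the sum of fixation durations plus 30 ms per saccade; only
relative, monotone time claims are asserted anywhere.

### The cohort experiment

`run_therapy_experiment()` draws the default cohort (low-VRT preset,
whole-word strategy, compliance 0.9, lapse 0.02), diagnoses each reader with
the staircase, and has each reader read the same synthetic text (~600
letters, about 200 segments at capacity three) unguided and guided at their
own diagnosed parameters. With 50 readers this takes a few seconds; the
problem sizes throughout (50 readers, 200 recovery profiles, 500
lapse-robustness sessions, 10⁴ cohort draws) were chosen so the whole test
suite completes in minutes while keeping Monte-Carlo error far below the
asserted margins.

Expected behaviour under the pinned constants: premature pronunciation makes
nearly every unguided whole-word attempt fail before guessing, so unguided
error rates sit around 0.8–0.9 per word; guided errors are dominated by the
10% non-compliant first attempts plus lapses, about 0.12 per segment. Pooled
over the cohort the reduction lands near 76%, comfortably above the 70%
immediate improvement that motivates guided reading, on every seed tested.
The Hedges g between per-reader unguided and guided error counts comes out
enormous (>10) because virtual readers share identical mechanics and differ
only in sampled parameters; the simulator reproduces the *mechanism* of the
effect, and no match to human effect sizes (g ≈ 2) is claimed — those depend
on between-child variability the model does not contain.

## What passing tests do and do not show

The generator emulates: per-child capacity ceilings 3–6 with time thresholds,
truncated-normal VRTs, lapses, imperfect compliance, strategy differences,
field defects as visibility masks. It does not emulate: learning or transfer
across sessions, attention, motivation, audio, real eye-tracker noise,
syllable structure, word frequency or orthographic neighbourhood effects on
guessing. Passing tests therefore validate the internal logic — parameter
recovery, causal classification, segmentation invariants, the direction and
rough size of the guided-reading effect under the stated model — not clinical
efficacy.

## Numerical choices and degenerate inputs

* Capacity queries clamp down to the defined grid; below the lowest grid
  level capacity is 0.
* Even-length segments fixate left of centre; fixed for determinism.
* The VRT bisection resolves to the 50 ms grid, the same granularity as the
  fixation grid.
* Empty words, empty texts, zero-length lists, non-positive error baselines
  and zero pooled variances raise immediately with named errors.
* A grapheme cluster longer than the capacity makes a text unsegmentable;
  the error names the cluster.
* All stochastic entry points take an `rng_seed` and restore the caller's
  RNG state; equal seeds give identical results.
* Natural words may be allowed one extra letter beyond pseudoword capacity
  via `segment_text(..., natural_bonus = TRUE)`; it is off by default and
  used nowhere internally, since only some children tolerate longer natural
  words. Syllable-based segmentation is deliberately not offered at all:
  syllables can exceed a reader's capacity or fall needlessly short of it,
  and a syllabification model would drag in exactly the hyphenation and
  morphology machinery this package excludes.

## Known limitations

Capacities below three letters are outside the staircase's resolution (it
starts, as the protocol does, at three). VRTs below the best presentation
time or above the generous allowance are censored at the protocol's range.
The pseudoword generator guarantees bigram attestation, not phonotactic
legality. The causal engine is purely Boolean — no probabilistic inference,
no condition intensities beyond a pass level L, no causal graphs. The CLI is
a thin convenience wrapper; interactive (human-responder) staircases are not
implemented beyond the programmatic responder interface.
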