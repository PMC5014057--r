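---
title: "Modelling clonal competition in the small intestinal crypt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clonal competition in the small intestinal crypt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cryptdrift` simulates a mouse small intestinal crypt as an off-lattice
population of sphere-shaped cells attached to a fixed basal membrane. The
membrane is a hemispherical cap (the crypt bottom) joined smoothly to a
cylinder of the same radius; all positions along the crypt-villus axis are
measured by `P`, the geodesic meridian arc distance from the bottom pole in
units of one cell radius (5 µm). Cells that pass `P > 30` have reached the
villus and are removed.

Three layers interact:

* **Mechanics.** Cells move by overdamped dynamics under (i) Hertz-like
  repulsion `k_rep * overlap^1.5` and short-range constant adhesion between
  contacting neighbours, (ii) active migration biases — enterocyte- and
  goblet-lineage cells drift up the axis, Paneth cells down — and (iii) a
  membrane-attachment spring. The spring replaces a hard surface
  constraint on purpose: sustained crowding can push a cell further than
  one radius off the membrane, at which point it loses substrate contact
  and dies by anoikis. With hard projection that death path could never
  fire.
* **Growth and division.** Proliferative cells grow linearly, doubling
  their volume in one growth time (default 16 h, lognormal CV 0.1 per
  cell), unless compressed: a cell whose *available volume* — its own
  volume minus the sphere-sphere intersection volumes with all neighbours
  — falls below the threshold `Vp = 0.8 v0` pauses (contact inhibition of
  growth). At twice the reference volume a cell divides into two daughters
  of volume `v0`, placed along a random tangential axis. Daughters inherit
  lineage state, founder label and any mutation profile.
* **Fate regulation.** Wnt activity is purely positional: high below
  `P1 = 5`, low between `P1` and `P2 = 12`, terminal beyond `P2`. Notch
  activity is contact-counted: secretory cells (Paneth, goblet) present
  ligands to mechanical neighbours. A stem cell needs at least `C1 = 3`
  Paneth contacts to remain a stem cell, otherwise it specifies into a
  Paneth progenitor; an enterocyte progenitor needs `C2 = 1` goblet
  contacts or it specifies into a goblet progenitor. All decisions are
  reversible until terminal differentiation; Paneth progenitors become
  terminal after one further division (or after 48 h of uninterrupted
  contact inhibition, so a jammed progenitor cannot stall forever).

Paneth-cell death has two channels: an intrinsic lifespan drawn at
terminal conversion (normal, mean `tau_p`, CV 0.25, truncated at zero) and
— in the wild-type reference configuration — programmed death after more
than 12 h without stem-cell contact. The contact channel is what keeps
Paneth cells and stem cells intermingled at the crypt bottom: a Paneth
cell buried in an all-Paneth plug at the pole starves of stem-cell contact
and is cleared.

## Why these defaults

The force, growth and lifespan constants of a model at this level of
abstraction are not uniquely determined by the biology, so all constants
are package defaults. They were fixed by matching qualitative operating
behaviour reported for mouse small intestinal crypts, not by fitting any
downstream statistic:

| parameter | default | reason |
|---|---|---|
| cap radius | 4 | niche (`P < 5`) holds ~20 cells: ~13 stem cells plus Paneth cells, the reported scale for mouse crypts |
| `k_rep`, `dt` | 5, 0.05 h | a cell with ~6 simultaneous Hertz contacts stays below the overdamped stability bound; `validate_params()` enforces it |
| `k_mem` | 5 | strong enough for a monolayer, weak enough that sustained crowding can detach a cell (anoikis) |
| `bias_up` | 0.2 | transit from niche border to crypt exit in ~5 days, the observed epithelial turnover scale |
| `bias_down` | 0.4 | the smallest value at which long-lived Paneth cells progressively occupy the crypt bottom (the 8-week-lifespan scenario separates within months) while the 4-week scenario stays intermingled; at 0.2 separation never happens, at 0.6+ every scenario over-pools |
| `fate_dt` | 4 h | fate rules re-evaluated on the timescale of transcriptional response. At 1 h sampling a single noisy contact reading converts a stem cell, inflating the stem-to-Paneth specification flux roughly tenfold above anything consistent with the slow Paneth turnover and week-scale conversion times this system shows |
| `Vp` | 0.95 `v0` | contact inhibition noticeably suppresses division at the crowded bottom (`p(P)` dips below the cell fraction for `P < 4`) without freezing the niche; with the exact lens-overlap compression proxy a newborn with ~6 neighbours pauses at overlap depths of ~0.2 radii |
| `tau_p`, starvation threshold | 8 wk, 12 h | the contact-controlled death configuration used as the wild-type reference |

Two further numerical choices matter. First, daughters are placed half a
radius apart and relax under a clamped displacement step; this clamping is
intentional, so the engine's instability diagnostic (abort when more than
1% of steps clamp) only counts cells older than 2 h. Second, the burn-in
steady-state test compares *weekly time-averages* of population size
(relative drift below 2%), with a trend test over the last four weeks as a
fallback; endpoint counts alone fluctuate by more than 2% at a population
of ~200. The 8-week-lifespan scenario additionally burns in for at least
16 weeks, because the Paneth/stem-cell separation that defines it develops
over months and is invisible to a population-size criterion.

## Competition analysis

Founder labels are frozen when an analysis starts (at steady state, or at
the mutation time). Monoclonal conversion is evaluated over the **stem
cells** (`conversion_population = "SC"`): long-lived Paneth cells would
otherwise bound whole-crypt conversion from below by their own turnover.
From the replicate set the package computes the positional distributions

* `f(P)` — stem-cell positions at competition start,
* `w(P)` — start positions of the founders whose clones won,
* `p(P)` — positions of stem-cell division events,

in unit bins by `floor(P)`, the advantage ratio `w/f`, the number of
'advantaged' stem cells (those starting in bins with `w > 0`), and
mutation-fixation statistics. For neutral labels the chance that a clone
starting in bin `b` wins is `w(b) / (n f(b))`, so `n` mutations placed
with positional distribution `q` fix `sum_b q(b) w(b)/f(b)` times on
average — `q = f` (random placement) gives exactly 1, `q = p`
(division-associated placement) is depressed wherever divisions are rarer
than cells, which is precisely the crowded crypt bottom.

Paneth turnover is reported as the time for the cohort present at analysis
start to fall to `1/e` of its size. This is one of several possible
operational definitions (the source literature does not state one); under
it, an intrinsic-lifespan-only population turns over in roughly 0.6 times
the mean lifespan, so the absolute numbers are not comparable to
definitions based on whole-population replacement.

## What the simulations do and do not show

The engine reproduces, at its ledgered defaults, the qualitative
competition structure: winning clones originate only from the lowest
position bins (`P < 4`), roughly half the stem cells are 'advantaged',
autonomous Notch (`C1 = C2 = 0`) fills the niche with stem cells, speeds
conversion below three weeks and shifts the most competitive position to
the bottom bin, and division-associated mutations fix roughly half as
often as randomly placed ones in wild-type crypts but nearly as often
under autonomous Notch. Absolute monoclonal-conversion times run some
30-70% above the experimentally reported means for this system
(orderings among scenarios are preserved); we chose not to chase the
absolute clock with ad hoc constants.

A run is fully deterministic given `(params, seed)`; replicate seeds come
from a counter-based derivation so replicate sets are extensible. Problem
sizes used in the test-suite and in `scripts/acceptance.R` are scaled to a
single CPU: crypts of ~200 cells, 12-30 replicates per scenario and
horizons of 20-52 simulated weeks, which keeps every statistic a
recomputation (never a stored constant) at a few minutes per experiment.

```{r example}
library(cryptdrift)
rr <- replicate_experiment(sim_params(), n_reps = 20, seed = 1)
advantage_ratio(rr$dist)
count_advantaged_SCs(rr$dist)
```

## Known limitations

* Cells are spheres; no cell shape, no explicit villus, no membrane
  deformation or crypt fission.
* Wnt is a step function of position and Notch a contact count; there is
  no ligand diffusion or intracellular signalling network.
* The mechanics constants are package choices calibrated to qualitative
  behaviour (see table); absolute time scales of competition inherit that
  uncertainty.
* Anoikis exists as a mechanism but is rare at the default crowding level;
  bottom-position disadvantage is carried almost entirely by contact
  inhibition of growth.
* The niche self-tunes to a critical composition in which the mean number
  of Paneth contacts per stem cell sits near the threshold `C1`. As a
  consequence the stem-to-Paneth specification flux — and with it Paneth
  *cohort* turnover — is considerably faster here than the multi-week
  turnover this crypt system is believed to show. Two downstream results
  are sensitive to that flux and come out differently at these defaults:
  raising a clone's Paneth requirement (`C1_eff = 4`) lets it surround
  itself with self-made Paneth cells and regenerate stemness through the
  reversion rule, so the *high*-requirement clone tends to win split-niche
  competitions and `mutant1` behaves as advantaged rather than
  disadvantaged. Widening the contact neighbourhood or slowing the fate
  tick does not move this (the composition re-equilibrates to the same
  margin); the corresponding checks in the test-suite assert the expected
  behaviour and are left failing rather than weakened. Everything that
  depends on position rather than on the specification flux — winner
  confinement to the crypt bottom, advantaged-cell counts, the
  division-associated fixation depression and its rescue by autonomous
  Notch, conversion-time orderings across Paneth-lifespan scenarios —
  is robust. The tau4-versus-contact-control conversion-time gap is real
  but small at these defaults and can flip at modest replicate counts.
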