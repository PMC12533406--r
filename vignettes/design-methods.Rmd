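---
title: "Designing specific CMP heterotrimers: model, search, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing specific CMP heterotrimers: model, search, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colhelix)
```

## The design problem

A collagen-mimetic peptide (CMP) strand is a Gly-periodic sequence over the
20 canonical residues plus `O` for (4R)-4-hydroxyproline. Three strands
wind into a triple helix under a canonical one-residue stagger; glycine
must sit at every helix cross-section, which is why the Xaa-Yaa-Gly frame
is obligatory and why this package rejects any strand whose glycines fit no
single frame. A mixture of k distinct strands can form k³ ordered
(leading, middle, trailing) assemblies — 8 species from two peptides, 27
from three — and a *design* is only successful if the one intended
assembly is markedly more stable than every competitor. We quantify that
margin as the specificity ΔTm: the melting temperature of the most stable
assembly minus that of the second most stable.

## The additive stability model

`predict_tm()` scores an assembly as a sum of independent contributions:

* **baseline(L)** — the Tm of the canonical (POG)-repeat homotrimer at
  strand length L (°C), tabulated per length;
* **substitution propensities** — one ΔTm per Xaa or Yaa position of each
  strand, relative to Pro at Xaa and Hyp at Yaa (both 0 by construction;
  the loader rejects tables that violate this reference state). Every
  natural substitution is destabilising;
* **pairwise interactions** — axial contacts couple the Yaa of triplet n
  on one strand to the Xaa of triplet n+1 on the adjacent strand; lateral
  contacts couple Yaa and Xaa of the same triplet n. Entries are keyed
  `Y:X`; pairs never parameterised experimentally default to 0;
* **frameshift and terminal corrections** — keyed on the assembly's frame
  pattern and on each strand's terminal residue and capping state.
  Strands are acetylated/amidated by default; free termini can be
  penalised via the table.

Additivity is an explicit model assumption: the effect of multiple
co-existing pairwise interactions is treated as the sum of their isolated
effects, because that is how the underlying single- and double-substitution
melting experiments were interpreted. The internal value is never clamped;
the conventional `<10.0` floor is applied only when rendering, because
ranking and specificity arithmetic need true values (for every shipped
reference row the top two species are above the floor, so the convention is
observationally safe).

### Contact closure

Adjacency runs leading→middle and middle→trailing with no triplet shift.
How the trailing→leading pair closes is not derivable from the contact
geometry alone; the default (`closure = "cyclic"`) includes it with all
triplet indices shifted by one (the full turn of stagger), and
`closure = "open"` omits it. The choice is isolated in one function and is
a visible switch on every scoring entry point; both geometries are tested
against an independent brute-force walker.

### Two code paths, one model

`predict_tm()` walks an explicit contact list (`pairwise_contacts()`);
the evolutionary loop uses a pair-sum fast path that precomputes contact
index masks per frame/length. The test suite and the acceptance script
verify the two routes agree to numerical noise on hundreds of random
assemblies, and verify both against a third, independently coded walker
that shares nothing with either.

## The evolutionary search

`run_design()` is a two-parent elitist genetic algorithm over *helix sets*
(2 peptides for A2B, 3 for ABC):

* **initialisation** — 500 random Gly-periodic sets by default; each set
  draws one shared frame so all three frames are represented across the
  population. One frame per set (rather than per strand) is required for
  the contact geometry to be well defined; mixed-frame assemblies have no
  stated contact rule.
* **selection** — the two fittest sets, ties to the earliest index.
* **crossover** (rate 0.6) — one cut at a Gly position, applied at the
  same index on every strand so registers stay aligned; cuts inside a
  motif window are never drawn; parents in different frames fall back to
  copying, since no register-preserving cut exists.
* **mutation** (rate 0.2) — every Xaa/Yaa position outside the motif
  window mutates independently, redrawing uniformly from the role's
  allowed alphabet *excluding the current residue*, so the number of
  changed positions is exactly Binomial(n, rate) — the property the test
  suite checks against a binomial oracle. Gly positions never mutate, and
  by default Gly is not offered at Xaa/Yaa (designed CMPs never break the
  frame; `allow_gly` overrides).
* **elitism** — both parents are copied unchanged, so the best fitness is
  non-decreasing (tested over many seeds).
* **restarts** — optional: after `restart_after` generations without
  improvement (> 1e-9) the population is re-initialised; the best set
  ever seen is still returned. Off by default.

### What fitness must reference

The published fitness is `F = 0.5·Tm + 0.5·ΔTm` (no motif) or
`0.4·ΔTm + 0.4·Tm + 0.2·CCRegisterScore` with the ±50 register term (motif
mode). A subtle but decisive design question is *which assembly's* Tm and
ΔTm enter F. Reading them off the globally most stable assembly makes the
degenerate state "one near-canonical strand plus maximally destabilised
partners" the global fitness optimum in any parameterisation: the junk
partners push every competitor's Tm arbitrarily low, so the specificity
term grows without bound while the design is useless. Early end-to-end
runs of this package converged to exactly that state and never to a
heterotrimer.

`helix_fitness()` therefore references the *target*: Tm is the best
register of the requested composition, and ΔTm is its gap to the best of
all other assemblies — negative while a competitor dominates. Whenever the
target is the most stable species (every published design row, and every
converged run) this coincides exactly with the most-stable/second-most
definition, which `specificity_report()` retains unchanged. The register
bonus still keys on the globally most stable register matching the
designated input order.

### Stopping

The loop stops as soon as *any* set in the generation satisfies all user
criteria: target Tm and specificity met, strand sequences pairwise
distinct, and the most stable assembly having the target composition. The
last clause prevents declaring success on a set whose best species is a
homotrimer that happens to clear the thresholds. Hitting the round cap
(500000 by default) returns the best set so far with a not-converged
status rather than an error.

## Motif conservation

A motif (3–15 residues, e.g. GFOGER) is inserted centred on its strands:
total length = 2·(flank length) + motif length, with the flank chosen as
⌊(target − motif)/2⌋ and nudged up if the total would drop below 21. Any
glycine inside the motif must land on the global Gly frame — the frame is
derived from the motif (smallest compatible offset when several fit) and
misaligned motifs are rejected at configuration time. Motif bytes are
excluded from both mutation and the crossover cut, so they are conserved
byte-identically in every individual of every generation (tested). In A2B
mode the leading and middle slots are the same peptide, so motifs supplied
for both must agree.

## The synthetic parameter tables

The fitted parameter values of the published stability model are released
as data, not printed in the main text, so this package treats all tables
as versioned input files and ships a synthetic set
(`synthetic_parameter_table()`, version tag `synthetic-toy-0.1`) for tests
and demonstrations. The synthetic tables are built to reproduce the
*qualitative* physics that makes the design problem meaningful:

* the baseline follows the published (POG)n length trend (≈37 °C at 21
  residues, ≈58 °C at 30; 2.4 °C per residue);
* every substitution destabilises (imino acids least, charged/amide
  residues ≈ −3 °C, bulky residues most);
* stabilising axial charge pairs (K/R → D/E, up to +4 °C) with weaker
  lateral counterparts and weak cation-π entries; a fully partnered pair
  nearly pays for its own two substitutions, and the combined axial +
  lateral gain is strictly below the paired propensity losses, so no
  substituted helix — in particular no homotrimeric charge ladder — ever
  outscores the canonical repeat. An earlier draft of these tables
  violated that inequality and the search promptly exploited it, which is
  the behaviour the inequality encodes.

What the synthetic tables do **not** emulate: the actual fitted magnitudes,
the full roster of measured pair interactions, frameshift/terminal values
fitted to capping experiments, or any experimental noise. Passing tests
therefore demonstrate the machinery — enumeration, additivity, register
discrimination, search dynamics, motif/exclusion guarantees — not
agreement with measured melting temperatures. Dropping in published tables
is a matter of writing them in the sectioned key-value format documented
in `load_parameters()`.

## Reference fixtures

`reference_tm_table()` ships the published predicted and experimental
melting tables of four designed heterotrimers (ABC-1, ABC-2, AAB-FOGER,
ABC-FOGER) and their predicted-versus-experimental comparison, used purely
as arithmetic regression fixtures: recomputing max-minus-second-max
reproduces every printed specificity, and predicted minus experimental
reproduces every printed deviation. Sub-floor entries are stored at the
floor value 10.0 with an explicit marker; they never rank in the top two,
so specificity arithmetic is unaffected. One source inconsistency is kept
as published: the comparison table lists the ABC-FOGER experimental Tm as
40.7 °C where the melting table says 40.5 °C.

## Numerical and interface choices

* Ranking ties break lexicographically by register label, making reports
  and selection deterministic.
* `specificity` of a single-assembly input (one peptide) is reported as
  `Inf`, rendered "n/a".
* All randomness flows through R's global RNG seeded once per run
  (`seed` in `ga_config()`), so identical configurations reproduce
  bit-identical designs; the seed is recorded in the JSON report.
* Positions are 1-based in the R interface; the frame offset remains the
  0-based index of the first glycine, matching the field's Gly-X-Y /
  Y-G-X / X-Y-G frame nomenclature.
* Strands of unequal length are rejected at enumeration: every published
  design uses equal-length strands and the stagger geometry for unequal
  lengths is undefined. Non-canonical staggers are likewise out of scope.

## Problem sizes used by the tests and acceptance script

Chosen to exercise every guarantee while keeping a single-CPU run short:
scorer-versus-walker agreement on 200+ random assemblies (lengths 21–33,
all frames, both closures); an exhaustively enumerable search space of 256
A2B sets of 6-mers (Xaa ∈ {P,K}, Yaa ∈ {O,D}) on which 50 seeded runs are
compared against brute force; 2000 mutation trials for the binomial check;
and one full A2B design at length 30 with a charge-pair alphabet,
population 100 and a few hundred generations. Population 500 and the
5·10⁵-round cap remain the defaults for real use.

## Known limitations

* Additivity of co-located pairwise interactions is an unverified model
  assumption inherited from the experimental data it is built on.
* Predictions are relative to a parameter table; with the synthetic
  tables, absolute Tm values are illustrative only.
* ABC designs explore a much larger competitor set (27 species) and
  need substantially larger generation budgets than A2B under the
  synthetic tables; the round cap and restart policy are the levers.
* The model knows nothing of concentration, pH/salt, folding kinetics, or
  higher-order assembly.
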