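---
title: "Scoring long-range electron-transfer pathways in heme proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring long-range electron-transfer pathways in heme proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etpaths)
```

## The problem

Heme peroxidases form protein-based radicals on tyrosine or tryptophan
residues by transferring an electron hole from the oxidized heme across
10–20 Å of protein matrix.  Which residue hosts the radical is hard to
see experimentally and expensive to test residue by residue.  `etpaths`
ranks the candidates computationally: it models the protein as a graph of
atoms connected by covalent bonds, hydrogen bonds and through-space
contacts, scores every connection with an empirical tunneling decay
factor, and finds for each candidate the single pathway from the heme iron
that maximizes the product of decay factors.

The underlying physics is the pathways picture of protein electron
transfer: the electronic coupling between donor and acceptor falls off
roughly exponentially with distance, but much more slowly through bonded
contacts than through empty space, so the best route is usually a chain of
covalent bonds with a small number of hydrogen-bond or space "jumps".
The decay product is reported on a log scale, `ln(k)`; differences of 1–2
units between residues are meaningful, absolute values are not rates.

## The decay law and its parameters

Every edge of kind $t \in \{\text{covalent}, \text{hbond},
\text{space}\}$ with length $r$ (Å, heavy-atom distance for hydrogen
bonds) contributes

$$ q = \min\!\left(A_t\, e^{-B_t (r - R_t)},\; A_t\right), $$

with defaults

| kind      | A    | B (Å⁻¹) | R (Å) | rationale |
|-----------|------|---------|-------|-----------|
| covalent  | 0.6  | 0       | 0     | one bond costs a fixed factor; bond lengths barely vary |
| hbond     | 0.36 | 1.7     | 2.8   | equals two covalent bonds (0.6²) at the reference O/N separation |
| space     | 0.6  | 1.7     | 1.4   | decays from the covalent contact value at van-der-Waals contact |

These are the classic pathways-model values; all are configurable through
`decay_parameters()`.  The clamp at $A_t$ serves two purposes: physically,
no jump should couple better than a covalent bond at contact; numerically,
it makes every Dijkstra edge weight $-\ln q \ge -\ln A_t \ge 0$, which the
algorithm requires.

## Graph construction

**Covalent bonds** come from heavy-atom templates for the twenty standard
residues, heme b and water, plus peptide C–N bonds within 2.0 Å.  Atoms a
template does not name — hydrogens, nonstandard atoms, unknown residues —
fall back to the distance rule $r \le r_{\mathrm{cov},i} +
r_{\mathrm{cov},j} + 0.45$ Å.  The heme iron is linked to the proximal
histidine NE2 when within 3.0 Å.  That coordination link is chemically a
dative bond, not a covalent pathway segment, so every path is flagged when
it uses the link and `forbid_fe_his = TRUE` removes it from the search;
both treatments are useful when comparing proximal- and distal-side
acceptors.

**Hydrogen bonds** use the geometric criterion common in MD analysis:
hydrogen–acceptor distance < 2.5 Å (0.25 nm) and donor–H–acceptor angle
> 135°, evaluated for every polar hydrogen.  Crystal structures usually
carry no hydrogens, and united-atom force fields carry only polar ones, so
the detector switches on what the structure provides: if any N/O-attached
hydrogen exists the H-based criterion is used exclusively; otherwise all
N/O pairs within 3.5 Å that are not connected by one or two covalent bonds
count as hydrogen-bonded.  The fallback is deliberately permissive (it
cannot distinguish donors from acceptors); its purpose is to keep
crystal-structure scoring possible, and its edge length — like the scoring
convention for detected H-bonds generally — is the donor–acceptor
heavy-atom distance on which the decay law's $R = 2.8$ Å is parameterized.

**Space edges** connect every remaining pair within 6.0 Å.  The cutoff is
a sparsity device, not a physical claim: a 6 Å jump is already attenuated
by $e^{-1.7 \cdot 4.6} \approx e^{-7.8}$ relative to contact, more than
fifteen covalent bonds, so longer jumps cannot occur on an optimal path
while shorter alternatives exist; enlarging the cutoff only adds edges
(a tested monotonicity property) and run time.

## The search

Maximizing $\prod q$ equals minimizing $\sum -\ln q$, so the optimal
pathway is a standard shortest path under non-negative weights, found with
Dijkstra's algorithm.  Exact ties in total weight are broken toward fewer
atoms, then toward the lexicographically smallest sequence of atom
serials — with continuous coordinates ties are rare, but the rule makes
output deterministic across platforms, which matters when diffing reports.
The implementation is validated two independent ways: against exhaustive
enumeration of all simple paths (`brute_force_best_path()`, the testing
oracle, guarded to ≤ 14 nodes) on hundreds of seeded random graphs, and
against `igraph` shortest-path distances.

Per-residue ranking starts every search at the heme iron.  The electron is
really donated at the porphyrin edge nearest the acceptor; starting at the
iron adds a near-constant two-bond offset to every residue and keeps the
donor unambiguous, so relative ranking — the quantity of interest — is
unaffected.  Acceptor atoms are the phenolic OH for tyrosine and the
indole NE1 for tryptophan, the atoms that carry the radical character.
Candidate selection applies a user-supplied `ln(k)` cutoff, typically the
score of an experimentally established radical site in a related enzyme.

## Ensemble analytics

A single energy-minimized structure is one snapshot; thermal motion
changes hydrogen-bond and space distances enough to reroute optimal paths.
`per_frame_paths()` therefore rebuilds the hydrogen-bond and space edges
from each frame's coordinates (covalent topology stays fixed — bonds do
not break in classical MD) and repeats the search.  Three summaries
follow:

* **Participation** — the fraction of frames whose optimal path contains
  each atom, binned as <10%, 10–30%, 30–40%, 40–50%, 50–65%, 65–80%,
  80–90%, >90% (left-open/right-closed).  High-participation atoms form
  the consensus route.
* **Ensemble decay** — mean and SD of per-frame `ln(k)` plus the extreme
  frames.  The mean of `ln(k)` corresponds to the geometric mean of the
  decay product; the arithmetic-mean alternative (log of mean k) can be
  formed from the per-frame results, which is why they are returned
  alongside the summary.
* Frames with an unreachable acceptor yield an explicit `ln_k = -Inf`
  sentinel, are excluded from statistics and reported in the frame counts.

**Hydrogen-bond occupancy** counts frames in which a chosen donor's polar
hydrogen satisfies the geometric criteria against each candidate acceptor
(a frame counts once per pair even with two hydroxyl protons, using the
closest satisfying hydrogen), with mean distance (nm) and angle over
bonded frames only.  **Water structure** around a target atom is
summarized as a shell-volume-normalized radial distribution function
(density from the periodic box when supplied, minimum-image convention;
otherwise estimated from the mean count inside `r_max`) and a per-frame
minimum-distance series.  Default bins: 0.1 Å width to 10 Å.

## Synthetic data: what it does and does not show

All tests run on generated inputs with analytically known answers:

* `make_covalent_chain(n)` — straight glycine-backbone chain; unique
  optimal path with `ln_k = n·ln 0.6` exactly.
* `make_bridged_pair(a, b, kind, r)` — two chains joined by one H-bond or
  space bridge, mirroring a relay like Tyr–Glu–Tyr; closed-form mixed
  score.
* `make_occupancy_trajectory(p, n, seed)` — a donor/acceptor pair toggling
  between bonded (1.8 Å, 165°) and broken (3.2 Å) geometry by Bernoulli
  draws; the realized mask is emitted so the estimator can be checked
  exactly and against the binomial 3σ bound.
* `make_water_box(density, box, seed, n_frames)` — ideal-gas water at
  prescribed density (count Poisson-drawn, bulk water ≈ 0.0334 Å⁻³);
  multiple frames redraw positions independently, because a single 30 Å
  box realizes only ~2–3 waters per 0.1 Å shell and the g(r) tail then
  fluctuates at the ±0.1 level; averaging 40 frames brings the ideal-gas
  tail within a few percent of 1.
* `make_random_graph(n, p, seed)` — random typed graphs for the oracle
  equivalence tests, connectivity not guaranteed.

Generators emit their ground truth as an attribute; consumers under test
assert against it rather than recomputing it.  Fixtures are written
through the real PDB writer and reader where I/O is part of the claim.

What passing these tests shows: bond perception, edge typing, the decay
law, the search, and the estimators are each correct against independent
ground truth.  What they do not show: that the defaults reproduce scores
on real deposited structures, which depend on crystallographic resolution,
hydrogen placement and any prior energy minimization.  On real structures
the ranking should be read comparatively, and the united-atom versus
no-hydrogen distinction (which switches the H-bond detector) checked
first.

## Numerical and interface choices

* Coordinates are Å everywhere internally; the 0.25 nm criterion and the
  nm distances in occupancy tables are converted at the boundary.
* Residue numbering is taken verbatim from the file so "Tyr247" means the
  depositor's residue 247; no renumbering.
* Altlocs: highest occupancy wins, ties go to conformer A.
* Path scores satisfy `ln_k = Σ ln q` to 1e-12 relative (tested); the
  JSON ranking serializer writes 17 significant digits so values
  round-trip bit-exactly.
* Degenerate inputs: donor == acceptor gives `ln_k = 0` with one atom;
  empty structures, zero-water selections and all-sentinel ensembles
  error with named messages rather than returning silent zeros.
* Problem sizes in the shipped tests and acceptance script — 200 random
  12-node graphs, 2000-frame occupancy runs, a 30 Å / 40-frame water box —
  were chosen so each statistical check sits well inside its bound while
  the whole suite stays interactive (seconds, one core).

## Limitations

* The decay model is the empirical pathways approximation: no explicit
  electronic structure, reorganization energy or multi-route interference;
  `ln(k)` orders pathways, it does not predict rates.
* One optimal path per acceptor; near-degenerate alternative routes are
  visible only through the ensemble participation map.
* The heavy-atom H-bond fallback cannot tell donors from acceptors and
  will connect, e.g., two backbone carbonyls within 3.5 Å.
* Orthorhombic periodic boxes only; no triclinic minimum image.
* PDB and XYZ-stack input only; compressed MD formats (XTC/DCD) are out
  of scope.
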