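---
title: "Quantifying outer-leaflet lipid extraction by a membrane transporter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying outer-leaflet lipid extraction by a membrane transporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidgate)
```

## The scientific question

ABCA1 exports phospholipid from the plasma membrane to apolipoprotein A-I,
the first committed step of HDL biogenesis. Coarse-grained simulations of
the transporter embedded in a POPC bilayer show a characteristic sequence:
a handful of lipids is lifted out of the *outer* leaflet into the
transporter's outward-open cavity (the "membrane mound"), a charged
29-residue loop of the first extracellular domain (the *gateway*, residues
564–592) binds their headgroups through salt bridges, and a single lipid is
then walked upward along a ladder of acidic residues toward a ring of
tunnel-lining residues (the *annulus*) and its central opening (the
*annulus orifice*). `lipidgate` implements the quantitative analyses behind
that picture so they can be applied to any pre-oriented trajectory — and
validated, end to end, on synthetic trajectories with planted ground truth.

## The measurements

**Membrane reference frame.** All heights are measured along z (the
membrane normal; inputs must be pre-oriented, no automatic normal
detection). Lipids are assigned to leaflets per frame: a lipid is *upper*
iff its phosphate z exceeds the median phosphate z of all lipids in that
frame. The reference plane `z0` is the unweighted mean z of upper-leaflet
phosphates. Because lipids currently lifted into the cavity would bias that
mean, a one-pass trim first drops lipids more than `exclusion_height_A`
(default 10 Å) above a provisional anchor. We use the *median* upper
phosphate z as the anchor: a provisional mean — the obvious alternative —
is itself dragged upward when several lifted lipids sit in a small leaflet
(with a 5-lipid mound above a 16-lipid leaflet the mean moves ~3.5 Å and
the trim excludes nothing), whereas the median is unaffected until half the
leaflet is lifted. Setting `exclusion_height_A = Inf` recovers the literal
untrimmed mean. One marginal case is accepted and documented: a lipid
lifted *exactly* at the threshold is kept by the strict `>` comparison, so
a 10 Å plateau is measured as ≈ 10 − 10/n<sub>upper</sub> (≈ 9.84 Å at 128
lipids).

**Lift histogram.** Lipid height Δz = z(phosphate) − z0 is binned into six
half-open 1 Å bins \[10,11), …, \[15,16). The left edge is inclusive, so
exactly 10 Å counts and exactly 16 Å does not — the only convention that
makes the upper boundary unambiguous. By default the histogram counts
lipids whose phosphate lies within 15 Å (lateral) of the protein centroid,
since "lipids in the cavity" needs an explicit, testable definition; any
explicit selection overrides.

**Mound detection.** Lipids with Δz ≥ 10 Å are clustered by single linkage
on their lateral phosphate positions at a 10 Å cut; the largest cluster
with ≥ 3 members (matching the observed 3–5-lipid mounds) is reported.
Absence of a mound is a result, not an error.

**Salt-bridge occupancy.** A contact between a charged residue and a lipid
moiety (choline or phosphate) exists when the *minimum particle-pair
distance* between the moiety bead(s) and the residue's side-chain particles
is ≤ 6 Å. Minimum-pair distance — not centre of mass — is the only
convention under which a single cutoff is meaningful for both
coarse-grained beads and all-atom charged groups. In coarse-grained
structures the side chain is every non-backbone particle of the residue;
a glycine in the residue set is an error, not a silent zero. Occupancy is
the fraction of window frames with ≥ 1 contact; per-replica rows are
always emitted alongside a pooled row whose occupancy is the
frame-weighted mean, following the 3 × 1000-frame pooling convention of
the source analyses. Both moiety × residue cross-tables are always
computed — the printed pairings (basic↔phosphate, acidic↔choline) emerge
from the data rather than being imposed.

**Extraction trace and ladder.** The extracted lipid is the one with the
greatest number of window frames at Δz ≥ 10 Å, ties broken by larger mean
Δz. For each ladder residue, the onset is the first frame with at least
`sustain_frames` (default 2) consecutive contacts; requiring two saved
frames suppresses single-frame flicker, and `sustain_frames = 1` restores
the literal reading. The report orders residues by onset and records the
lipid's height at onset; the wild-type reference ladder engages D571,
D575, E584 and D585 at roughly 10, 12, 15 and 17 Å.

**Domains.** The gateway (564–592), annulus (69, 71–80, 363, 368–379) and
the 11 charged gateway residues ship as presets with author numbering.
The annulus can be *re-derived* with `derive_proximity_domain()`: every
tunnel-lining candidate residue with any particle within 10 Å of any
gateway particle (all particles, not Cα only, matching the atom-level
wording of the definition). The tunnel-lining set itself is an input —
cavity detection is out of scope. The orifice is stated two ways in the
source literature (73–75, 77, 78, 371, 375 in figure legends; 73–74, 77,
371, 375 in the text); both ship as named presets and neither is promoted.

**Residue classes.** The seven-class scheme (basic K/R; acidic D/E;
aromatic F/W/Y; hydrophobic A/V/L/I/M/C; proline; glycine; neutral
S/T/N/Q/H) is not spelled out in the source; this assignment reproduces
the printed gateway census (5 basic, 6 acidic, 5 aromatic, 7 hydrophobic
of 29) and treats histidine as neutral, consistent with it being discussed
separately from the basic residues.

**Homology threading.** `map_alignment()` walks a two-row alignment:
columns occupied in both rows become residue pairs, target-only columns
are dropped insertions (they cannot be threaded), template-only columns
are skipped. `thread_backbone()` copies the template backbone verbatim —
aligned Cα positions are bitwise identical to the template — keeps
identical side chains, and flags substitutions. `place_side_chain()`
rebuilds each substituted side chain from an embedded backbone-independent
rotamer library (χ at the staggered values −60°, 60°, 180°; ≤ 81
candidates per type) using natural-extension-of-reference-frame geometry,
and picks the candidate with the fewest heavy-atom clashes (< 2.5 Å to any
model atom outside the placed residue), ties to the earlier library entry.
The contract is argmin-by-clash, not fidelity to a published library; the
model is delivered unminimized with its clash report, and loop building
for regions disordered in the template is deliberately not performed —
such residues are omitted and listed.

## The synthetic generator

`simulate_trajectory()` emulates the statistical structure the analyses
assume, not membrane physics: no forces, no thermostat. The defaults are
the desk-scale study conditions — 128 twelve-bead pseudo-POPC lipids in
two flat leaflets 38 Å apart, frames every 5 ns, 0.5 Å Gaussian
positional noise, a gateway loop with author numbering hovering above the
upper leaflet, and the two headline planted schedules (phosphate↔K568 at
p = 0.77, choline↔D571 at p = 0.39). A full-scale preset (792 lipids,
2000 frames) is a constructor call away.

Planted events are realised *exactly*: on a contact frame the residue's
side-chain bead is placed 5.0 Å from the designated lipid's target moiety
with the counter-moiety at 8.5 Å, and on non-contact frames it sits tens
of Å away — a guard band (≤ 6 Å vs > 8 Å) that keeps contact labels
decidable under noise, so occupancy recovery is exact against the recorded
draws rather than merely close. Planted lipids are kept ≥ 10 Å apart
laterally so schedules cannot interfere. The extracted lipid's phosphate
is held exactly at its scheduled height and mound lipids are placed
exactly, so lift-based assertions are deterministic; all other beads carry
the noise. The gateway sequence is synthetic: the 11 charged residues sit
at their published positions and the rest are filled to match the
published class census — the real sequence is never required by any
analysis here.

What the generator does *not* emulate — curvature and undulations,
lateral diffusion, headgroup orientation dynamics, realistic contact
kinetics, protein flexibility — bounds what green tests mean: they
demonstrate that the estimators recover what was planted under the stated
noise model, not that the biology of any particular trajectory is
reproduced. Analysing real trajectories goes through the same functions
via `read_trajectory()`.

## Orchestration and reproducibility

`run_config()` validates every parameter at once and `run_pipeline()`
writes long-format TSV / JSON reports, each stamped with an FNV-1a hash of
the configuration (minus the output path); identical configuration and
seed give byte-identical reports, with timestamps confined to the run log.
The frame window is expressed as a trailing fraction (0.5 = the last half
of the run, the equilibrated-tail convention) or explicit indices.

Problem sizes used by the test suite and the acceptance script were chosen
to keep statistical assertions sharp at interactive runtimes: occupancy
recovery uses 3 replicas × 1000 analysed frames (3000 pooled, the
published pooling convention) and a 100-seed sweep at 3000 frames each
with a 16-lipid bilayer, since the occupancy statistic is independent of
bilayer size; ladder and mound runs use the full 128-lipid default.

## Known limitations

* z is assumed to be the membrane normal; tilted or curved membranes are
  out of scope, as is lateral periodic-boundary handling.
* The trimmed reference plane treats a lipid at exactly the exclusion
  height as part of the leaflet (see above).
* The rotamer library is deliberately coarse; clash counts rank candidates
  but are not an energy. Models should be minimized externally before
  structural interpretation.
* Recomputed alignment identity/similarity depends on the upstream
  alignment tool and is reported, not asserted, against published values.
* Tier-2 validations that need external downloads (deposited trajectories,
  PDB entries 5XJY/7LKZ) are not part of the test suite.
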