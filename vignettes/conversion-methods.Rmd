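---
title: "Converting metabolic maps between SBGN-ML and yEd GraphML"
author: "sbgnyed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting metabolic maps between SBGN-ML and yEd GraphML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbgnyed)
```

## The problem

Genome-scale metabolic maps are drawn and curated by hand. The community
standard for storing them is the Systems Biology Graphical Notation, whose
Process Description (PD) language describes biochemistry mechanistically:
entity pools (metabolites, macromolecules), process glyphs for reactions,
compartments, clone markers for pools drawn more than once, and auxiliary
units (state variables, units of information) decorating their carriers.
General-purpose graph editors such as yEd are far better drawing
environments than most SBGN-specific tools — they scale to thousands of
nodes, have strong layout algorithms, and ship an SBGN shape palette — but
they speak GraphML, not SBGN-ML. This package translates complete maps in
both directions so that drawing can happen in the editor while the archived
artifact stays standard.

Most of the translation is a vocabulary mapping: each PD glyph class has a
palette configuration string (`com.yworks.sbgn.Macromolecule`, ...), each
arc class an arrowhead (plain line = consumption, regular arrow =
production, empty circle = catalysis, empty triangle = stimulation, T-shape
= inhibition, empty diamond = modulation, triangle-with-bar = necessary
stimulation), compartments become yEd group nodes, multimer cardinality the
`mcount` style attribute, and right-oriented tags the `inverse` attribute.
Colours and annotations travel in SBGN-ML `<extension>` elements in one
direction and in shape style attributes in the other. Three PD constructs
have no palette shape and degrade with a logged notification: association
and dissociation are shown as plain processes, and up/down tags become
left-oriented tags. These degradations are not invertible; the reverse
direction cannot recover them, by design.

## The hard part: process ports

A PD process carries two *ports* — antenna tips on opposite sides of the
square — and the consumption/production arcs attach to the ports, not the
box. The two ports separate the two sides of the reaction equation, which
matters most for reversible reactions. yEd has no port concept: arcs attach
straight to the box. The forward converter therefore renders each port as
an extra bend point at the antenna tip (first bend when the port is at the
edge's source, last bend otherwise), so all arcs of one port visually
converge there. The reverse converter has to *reconstruct* the ports, and
this is the package's core algorithm. Per process:

1. **Reversibility.** The incident flux arcs are classified: at least one
   consumption and one production means irreversible; all production means
   reversible (the drawing convention for reversible reactions). The
   modulation family (catalysis, stimulation, inhibition, modulation,
   necessary stimulation) attaches to the process body and is excluded
   throughout — this keeps the one-type-per-port rule satisfiable and
   follows PD drawing practice.
2. **Anchors and orientation.** Each flux arc gets an *anchor*: the bend
   point adjacent to the process end if the edge has bends, else the centre
   of the far node's box (the natural reading of "endpoint" for an edge
   attached to a node). The anchor's side is the axis of larger
   displacement from the box centre. All processes start out assumed
   horizontal; if the top/bottom sides hold the strict majority of anchors
   the orientation flips to vertical, the ports are re-placed on the
   top/bottom midpoints, and assignment is re-run once (the flip is
   logged). Ties keep the horizontal assumption; an `|dx| == |dy|` tie
   resolves to the horizontal axis, and an anchor on the exact centre
   defaults to the left side — all deterministic, seed-free tie-breaks.
3. **Assignment.** Irreversible: consumptions to one port, productions to
   the other (rule 1 by construction); the consumption port is the majority
   side of the consumption anchors along the orientation axis, ties going
   left/top. Reversible: each arc to its Euclidean-nearest port (we read
   "distance to the process" as distance to each candidate port position,
   the only reading that makes the assignment well-defined); if one port
   ends up empty, the single arc farthest from the crowded port moves over,
   so at most one repair per process, and both port rules hold.

Ports are placed on the side midpoints, offset outward by the **antenna
length** (default 10 canvas units, configurable; canvas units are the
shared unitless coordinate system of both formats — top-left origin, y
down — so geometry passes through conversion unchanged). Processes with
fewer than two flux arcs cannot satisfy the both-ports-occupied rule; they
are emitted without ports, arcs attached to the glyph body (legal SBGN-ML),
and reported. A process whose flux arcs are all consumptions is degenerate;
it is reported and assigned by distance as a best effort.

Two further reconstruction passes run in the reverse direction.
**Clone detection** groups entity pools by normalised label, class,
multimer cardinality, state-variable multiset and — under the default
`per-compartment` policy — compartment (ATP in the cytosol and ATP in the
mitochondrion are two pools, not clones; `global` relaxes this); every
member of a group of two or more gets a clone marker, in addition to any
markers carried through the converter's own style attribute.
**Auxiliary-unit attachment** turns free-standing state-variable and
unit-of-information nodes back into child glyphs: first via the explicit
id references the forward converter writes into a converter-owned GraphML
key, then via a geometric fallback for hand-drawn files — any auxiliary
node intersecting a candidate's boundary band (±10 units around the box
border) attaches to the nearest such candidate; true orphans stay
standalone with a warning. State labels parse as `value@variable`
(`P@Ser15`), bare labels as a value alone.

Because reconstruction re-derives ports, orientations and bends, a full
field identity is the wrong fidelity measure for a round trip. The
package's documented equivalence (`pdEquivalent()`) compares signature
multisets: glyph class, label, compartment membership, clone flag, multimer
cardinality and the auxiliary-unit multiset per carrier, plus each arc's
class and endpoint signatures with ports collapsed onto their process.
Port ids and positions, bend lists, element ids and inferred orientations
are explicitly outside the relation.

## Dialects and numerical choices

The SBGN-ML writer emits the milestone-2 namespace (`…/libsbgn/0.2`),
glyphs before arcs, auxiliary glyphs nested in their carriers; the reader
also accepts milestone-3 namespaces. Colour conservation uses a
converter-owned extension element (`urn:sbgnyed:style`, attributes `fill`,
`stroke`, and `cardinality` for multimers, whose class is written with the
standard `" multimer"` suffix); unrecognised extension payloads are
preserved verbatim. The GraphML emitter's vocabulary — key ids, palette
configuration strings, arrowhead tokens, the converter-owned clone style
properties and the `auxRefs` data key — is frozen in one table
(`graphmlDialect()`); arrow token spellings are the one place that may need
adjusting for other yEd releases. A structural XSD subset shipped with the
package (authored here, not the official libSBGN schema) backs
`validateSbgnFile()`.

Coordinates serialise as fixed six-decimal strings with trailing zeros
trimmed, and every constructor canonicalises numbers to the double that
this serialisation parses back to, making write-then-read bit-exact.
Container order in `PDMap` and `YedGraph` is canonical (ids sorted
bytewise), since GraphML's nested-group encoding cannot preserve arbitrary
document order anyway. Files that draw flux arcs against the PD convention
(consumption leaving a port, production entering one) are repaired by
endpoint swap with a logged warning rather than rejected — hand-drawn
files are messy and the converter's job is repair. Conversion never aborts
on a single bad element: unclassifiable nodes or edges are recorded as
errors in the `ConversionReport` and the rest of the map converts.

## The synthetic-map generator

No external dataset is needed: `generatePD()` builds seeded synthetic maps
on a jittered grid (0.1-unit resolution, cells 160x120 — wide enough that
anchor sides are unambiguous except in deliberately constructed tie cases).
Defaults describe a small mixed map; the distributional choices mimic drawn
metabolic maps: pools dominated by simple chemicals and macromolecules,
irreversible processes with 1-3 consumptions and 1-3 productions,
reversible ones with 2-4 productions split across both ports, a quarter of
processes catalysed, and optional clone pairs, state variables, multimers
and degradation elements. `generateYed()` expresses the same map in yEd
vocabulary with *no* ports — and drops the bend points from every third
process's edges — so the reverse algorithms are genuinely exercised on both
anchor paths. `fig2Fixtures()` pins the three textbook drawings
(reversible, irreversible-horizontal, irreversible-vertical).

What the generator does not emulate: biologically meaningful stoichiometry
or naming, curved splines (bends are polyline points), complex member
nesting in the GraphML direction, submap interiors, and hand-drawn
sloppiness beyond the specific repairs above. Green tests therefore
demonstrate algorithmic correctness on well-formed and mildly adversarial
drawings, not robustness against every artefact a human editor can
produce.

The test suite exercises scale on a synthetic map of roughly 3,800 entity
pools and 5,600 processes (~10,000 glyphs, ~22,000 arcs, the size class of
a genome-scale human metabolic map); both directions run in seconds, and
the reverse direction — which additionally runs port reconstruction, clone
detection, auxiliary-unit attachment and a final validation of its own
output — is the slower one, as its extra work predicts. Smaller
property-based suites (500 seeded fixtures for port-rule validity, 100 for
round-trip equivalence, 60 for the nearest-port oracle) keep the default
test run fast.

## Known limitations

* Association/dissociation and up/down tags are lossy by design; nothing
  attempts to guess them back.
* Complex members survive SBGN round trips (nested glyphs) but flatten to
  plain nodes in the yEd direction; membership is not recovered.
* The clone style attribute and `auxRefs` key are converter-owned dialect;
  other tools will not write them (the geometric fallback and clone
  detection exist precisely for such files).
* Arc-crossing aesthetics beyond the majority-side orientation rule are out
  of scope; positions and layout always pass through unchanged.

## A worked example

```{r example}
spec <- fixtureSpec(nPools = 10, nProcesses = 6, seed = 42)
m <- generatePD(spec)
m
fwd <- sbgnToYed(m)
fwd$graph
rev <- yedToSbgn(fwd$graph)
nrow(validatePD(rev$map))          # reconstructed map is PD-valid
isTRUE(pdEquivalent(m, rev$map))   # and equivalent to the original
```
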