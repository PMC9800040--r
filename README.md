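# sbgnyed

Bidirectional conversion of metabolic pathway diagrams between **SBGN-ML
Process Description** (the systems-biology standard exchange format,
milestone 2) and **yEd-flavoured GraphML** (the dialect written by the yEd
graph editor and its SBGN shape palette).

Curators of genome-scale metabolic maps want to *draw* in a powerful
general-purpose editor and *archive* in the community standard. The two
formats share geometry and most vocabulary, but differ in one structural
point that makes naive translation wrong: an SBGN process glyph connects its
consumption and production arcs through two **ports** (antenna tips that
separate the two sides of the reaction equation), while yEd attaches edges
straight to the process box. This package maps every element class in both
directions and reconstructs what each side is missing:

* **SBGN → yEd**: ports are rendered as an extra bend point at each antenna
  tip so arcs visually converge there; association/dissociation processes
  and up/down tags, which have no palette shape, degrade to plain processes
  and left tags with a logged notification; colours and annotations are
  conserved as style attributes.
* **yEd → SBGN**: for every process the converter classifies reversibility
  from the incident flux arcs (irreversible = consumption and production
  both present; reversible = all production), computes each arc's *anchor*
  (the bend adjacent to the process, else the far node's centre), infers the
  process orientation from the anchor-side majority (ties stay horizontal),
  places two ports on the side midpoints offset by the antenna length
  (default 10 canvas units), and assigns arcs to ports — by type for
  irreversible processes, by Euclidean nearest-port distance for reversible
  ones, moving the single farthest arc whenever one port would end up empty.
  It also detects **clone markers** (entity pools drawn more than once,
  keyed by label, class, cardinality, state decoration and compartment) and
  re-attaches **auxiliary units** (state variables, units of information) to
  their carrier glyphs by explicit reference or geometric border overlap.
  The emitted map satisfies the PD port rules: one arc type per port, no
  empty port.

Every conversion returns a structured `ConversionReport` (notifications,
warnings, errors); a single bad element never aborts a run.

## Worked example

```r
library(sbgnyed)

spec <- fixtureSpec(nPools = 10, nProcesses = 6, seed = 42)
m <- generatePD(spec)          # seeded synthetic PD map
m
#> PDMap: 21 glyphs (6 processes), 18 arcs
#>   classes: process(6) macromolecule(3) simple chemical(3) compartment(2)
#>            complex(2) nucleic acid feature(2) state variable(2)
#>            unspecified entity(1)

fwd <- sbgnToYed(m)            # forward conversion
fwd$graph
#> YedGraph: 21 nodes (2 groups), 18 edges

rev <- yedToSbgn(fwd$graph)    # reverse conversion: ports reconstructed
rev$report
#> ConversionReport: 0 notifications, 0 warnings, 0 errors
nrow(validatePD(rev$map))      # port rules and references all satisfied
#> [1] 0
isTRUE(pdEquivalent(m, rev$map))  # round trip preserves the map's content
#> [1] TRUE

glyphs(rev$map)[["proc0001"]]$orientation
#> [1] "horizontal"
```

The 21 glyphs are the 10 pools plus their duplicated clone, 2 state
variables, 2 compartments and 6 processes; `pdEquivalent()` checks the
documented round-trip relation (classes, labels, compartment membership,
clone flags, multimer cardinalities, state variables, and arc endpoints
with ports collapsed — port ids/positions and bend lists are reconstructed,
not preserved).

File I/O: `readSbgnMl()` / `writeSbgnMl()` and `readGraphml()` /
`writeGraphml()`; write-then-read is bit-exact on both formats, and emitted
SBGN-ML validates against the structural schema shipped in
`inst/extdata/`.

## Command line

```sh
inst/scripts/sbgnyed convert map.sbgn -o map.graphml
inst/scripts/sbgnyed convert drawings/ --bulk -o out/ --report log.jsonl
inst/scripts/sbgnyed fixtures --spec spec.json --out fixtures/
```

Direction is auto-detected (`--direction` forces it; forcing one that
contradicts the input is an error), bulk mode converts a directory and
survives individual failures, and `--report` writes the conversion log as
JSON lines. Exit status: 0 clean, 1 warnings, 2 errors.

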