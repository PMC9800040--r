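# Hand-laid micro-maps used across test files.

# an irreversible process with 2 consumptions + 1 production, wired to ports
tinyProcessMap <- function() {
  b <- function(x, y, w = 60, h = 30) bbox(x, y, w, h)
  proc <- pdGlyph("P", "process", bbox(100, 100, 20, 20),
                  orientation = "horizontal",
                  ports = list(pdPort("P.p1", 90, 110),
                               pdPort("P.p2", 130, 110)))
  pdMap(
    list(pdGlyph("A", "simple chemical", b(0, 60), label = "A"),
         pdGlyph("B", "simple chemical", b(0, 160), label = "B"),
         pdGlyph("C", "macromolecule", b(200, 95), label = "C"),
         proc),
    list(pdArc("a1", "consumption", "A", "P.p1"),
         pdArc("a2", "consumption", "B", "P.p1"),
         pdArc("a3", "production", "P.p2", "C")))
}

# a compartmentalised map: compartment, two pools (one with a state
# variable), one process, two flux arcs
smallCompartmentMap <- function() {
  comp <- pdGlyph("c1", "compartment", bbox(0, 0, 500, 300),
                  label = "cytosol")
  a <- pdGlyph("m1", "macromolecule", bbox(40, 100, 90, 40), label = "PK",
               compartmentRef = "c1")
  sv <- pdGlyph("m1.sv", "state variable", bbox(50, 92, 24, 16),
                parent = "m1", stateValue = "P", stateVariable = "Ser15")
  b <- pdGlyph("m2", "simple chemical", bbox(320, 100, 60, 40),
               label = "pyruvate", compartmentRef = "c1")
  proc <- pdGlyph("p1", "process", bbox(200, 108, 24, 24),
                  orientation = "horizontal", compartmentRef = "c1",
                  ports = list(pdPort("p1.p1", 190, 120),
                               pdPort("p1.p2", 234, 120)))
  pdMap(list(comp, a, sv, b, proc),
        list(pdArc("a1", "consumption", "m1", "p1.p1"),
             pdArc("a2", "production", "p1.p2", "m2")))
}

# assemble a node style vector using the dialect's attribute names
makeStyleForTest <- function(mcount = NA, inverse = NA, clone = NA,
                             cloneLabel = NA, fill = NA, border = NA) {
  d <- graphmlDialect()
  v <- as.character(c(mcount, inverse, clone, cloneLabel, fill, border))
  names(v) <- c(d$mcountKey, d$inverseKey, d$cloneKey, d$cloneLabelKey,
                "fill", "border")
  v[!is.na(v)]
}

expectNoPortRuleViolations <- function(map) {
  v <- validatePD(map)
  v <- v[v$rule %in% c("port-arc-type", "port-occupancy"), , drop = FALSE]
  expect_identical(nrow(v), 0L)
}
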