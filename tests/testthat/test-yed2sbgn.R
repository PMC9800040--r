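# Reverse conversion: yEd graph -> PD map (port reconstruction, clones,
# auxiliary units).

test_that("reversibility classification follows the flux-arc definition", {
  expect_identical(
    classifyReversibility(c("consumption", "consumption", "production")),
    "irreversible")
  expect_identical(classifyReversibility(c("production", "production")),
                   "reversible")
  # modulation arcs are ignored for the classification
  expect_identical(classifyReversibility(c("production", "catalysis")),
                   "reversible")
  expect_error(classifyReversibility(c("catalysis")), "no flux arcs")
})

test_that("anchors pick the dominant axis, with documented tie-breaks", {
  b <- bbox(-10, -10, 20, 20)    # centre (0, 0)
  noBends <- matrix(numeric(), ncol = 2)
  a <- arcAnchor(noBends, "target", c(-50, 5), b)
  expect_identical(a$side, "left")
  expect_identical(arcAnchor(noBends, "target", c(0, -40), b)$side, "top")
  # |dx| == |dy|: the horizontal axis wins
  expect_identical(arcAnchor(noBends, "target", c(30, 30), b)$side, "right")
  expect_identical(arcAnchor(noBends, "target", c(0, 0), b)$side, "left")
  # with bends, the bend adjacent to the process end is the anchor
  withBends <- rbind(c(-40, 2), c(80, 9))
  expect_identical(arcAnchor(withBends, "target", c(500, 0), b)$side,
                   "right")
  expect_identical(arcAnchor(withBends, "source", c(500, 0), b)$side,
                   "left")
})

test_that("anchor distances are Euclidean distances to the port candidates", {
  b <- bbox(-10, -10, 20, 20)    # horizontal ports at (-20, 0), (20, 0)
  a <- arcAnchor(matrix(numeric(), ncol = 2), "target", c(-50, 0), b)
  expect_equal(a$distLeft, 30)
  expect_equal(a$distRight, 70)
})

test_that("orientation is the side majority with a horizontal tie-break", {
  expect_identical(computeOrientation(c("left", "right", "left")),
                   "horizontal")
  expect_identical(computeOrientation(c("top", "bottom", "top")), "vertical")
  expect_identical(computeOrientation(c("left", "top")), "horizontal")
})

test_that("irreversible assignment splits by type, consumption by majority", {
  ids <- c("a1", "a2", "a3")
  cls <- c("consumption", "consumption", "production")
  anchors <- rbind(c(-50, 0), c(-60, 5), c(40, 0))
  asg <- assignPortsIrreversible(ids, cls, anchors, c(0, 0), "horizontal")
  expect_identical(asg$port1Arcs, c("a1", "a2"))
  expect_identical(asg$port2Arcs, "a3")
  expect_identical(asg$repairs, 0L)

  # consumption anchored right: the majority side is honoured
  asg2 <- assignPortsIrreversible(c("a1", "a2"),
                                  c("consumption", "production"),
                                  rbind(c(50, 0), c(-50, 0)), c(0, 0),
                                  "horizontal")
  expect_identical(asg2$consumptionPort, 2L)
  expect_identical(asg2$port2Arcs, "a1")

  # both anchored left: tie over sides resolves consumption to the left port
  asg3 <- assignPortsIrreversible(c("a1", "a2"),
                                  c("consumption", "production"),
                                  rbind(c(-50, 0), c(-60, 0)), c(0, 0),
                                  "horizontal")
  expect_identical(asg3$port1Arcs, "a1")
  expect_identical(asg3$port2Arcs, "a2")
})

test_that("reversible assignment is nearest-port with farthest-arc repair", {
  pp <- rbind(p1 = c(-12, 0), p2 = c(12, 0))
  colnames(pp) <- c("x", "y")

  asg <- assignPortsReversible(c("a1", "a2", "a3"),
                               rbind(c(-50, 0), c(-60, 5), c(40, 0)), pp)
  expect_identical(asg$port1Arcs, c("a1", "a2"))
  expect_identical(asg$port2Arcs, "a3")
  expect_identical(asg$repairs, 0L)

  # all initially on the left port: the farthest arc is moved to the right
  asg2 <- assignPortsReversible(c("a1", "a2", "a3"),
                                rbind(c(-50, 0), c(-60, 0), c(-70, 0)), pp)
  expect_identical(asg2$repairs, 1L)
  expect_identical(asg2$moved, "a3")
  expect_identical(asg2$port1Arcs, c("a1", "a2"))
  expect_identical(asg2$port2Arcs, "a3")

  # two equidistant arcs: first by id to port 1, repair forces the second
  asg3 <- assignPortsReversible(c("a1", "a2"),
                                rbind(c(0, 30), c(0, 30)), pp)
  expect_identical(asg3$port1Arcs, "a1")
  expect_identical(asg3$port2Arcs, "a2")
  expect_identical(asg3$repairs, 1L)
})

test_that("clone detection groups by label, class and compartment", {
  mk <- function(id, label, comp, cls = "simple chemical")
    pdGlyph(id, cls, bbox(0, 0, 60, 40), label = label,
            compartmentRef = comp)
  comps <- list(pdGlyph("cyt", "compartment", bbox(0, 0, 500, 500)),
                pdGlyph("mit", "compartment", bbox(500, 0, 500, 500)))
  m <- pdMap(c(comps, list(mk("g1", "ATP", "cyt"), mk("g2", "ATP", "cyt"),
                           mk("g3", "ATP", "mit"), mk("g4", "Glucose", "cyt"))),
             list())
  expect_setequal(detectClones(m), c("g1", "g2"))
  # global policy ignores the compartment
  expect_setequal(detectClones(m, policy = "global"), c("g1", "g2", "g3"))
})

test_that("clone keys distinguish cardinality and state decoration", {
  m <- pdMap(list(
    pdGlyph("g1", "macromolecule", bbox(0, 0, 90, 40), label = "PK"),
    pdGlyph("g2", "macromolecule", bbox(0, 100, 90, 40), label = "PK",
            multimer = 2L),
    pdGlyph("g3", "macromolecule", bbox(0, 200, 90, 40), label = "ENO"),
    pdGlyph("g3.sv", "state variable", bbox(5, 195, 20, 14), parent = "g3",
            stateValue = "P"),
    pdGlyph("g4", "macromolecule", bbox(0, 300, 90, 40), label = "ENO")),
    list())
  expect_length(detectClones(m), 0L)
})

test_that("auxiliary units attach by reference, geometry, or stay orphans", {
  nodes <- list(
    yedNode("m1", "com.yworks.sbgn.Macromolecule", bbox(0, 0, 90, 40),
            label = "PK", auxRefs = "sv1"),
    yedNode("sv1", "com.yworks.sbgn.StateVariable", bbox(300, 300, 24, 16),
            label = "P@Ser15"),
    yedNode("m2", "com.yworks.sbgn.Macromolecule", bbox(200, 0, 90, 40),
            label = "ENO"),
    yedNode("ui1", "com.yworks.sbgn.UnitOfInformation", bbox(210, -8, 30, 16),
            label = "mt:prot"),
    yedNode("sv2", "com.yworks.sbgn.StateVariable", bbox(600, 600, 24, 16),
            label = "Ub"))
  g <- yedGraph(nodes, list())
  att <- attachAuxUnits(g)
  att <- att[order(att$aux), ]
  expect_identical(att$parent[att$aux == "sv1"], "m1")     # explicit ref
  expect_identical(att$method[att$aux == "sv1"], "refs")
  expect_identical(att$parent[att$aux == "ui1"], "m2")     # border overlap
  expect_identical(att$method[att$aux == "ui1"], "geometry")
  expect_true(is.na(att$parent[att$aux == "sv2"]))         # orphan

  r <- yedToSbgn(g)
  sv1 <- glyphs(r$map)[["sv1"]]
  expect_identical(sv1$parent, "m1")
  expect_identical(sv1$stateValue, "P")
  expect_identical(sv1$stateVariable, "Ser15")
  ui1 <- glyphs(r$map)[["ui1"]]
  expect_identical(ui1$parent, "m2")
  expect_identical(ui1$label, "mt:prot")
  sv2 <- glyphs(r$map)[["sv2"]]
  expect_true(is.na(sv2$parent))
  expect_identical(sv2$stateValue, "Ub")                   # bare label
  rep <- reportRecords(r$report)
  expect_identical(sum(rep$rule == "orphan-aux-unit"), 1L)
})

test_that("the canonical process drawings convert as drawn", {
  f <- fig2Fixtures()

  rh <- yedToSbgn(f$irreversibleHorizontal)
  p <- glyphs(rh$map)[["P"]]
  expect_identical(p$orientation, "horizontal")
  expect_length(p$ports, 2L)
  # consumptions (left majority) on the left port, production on the right
  expect_identical(arcs(rh$map)[["e1"]]$target, "P.p1")
  expect_identical(arcs(rh$map)[["e2"]]$target, "P.p1")
  expect_identical(arcs(rh$map)[["e3"]]$source, "P.p2")
  expect_identical(nrow(validatePD(rh$map)), 0L)

  rv <- yedToSbgn(f$irreversibleVertical)
  expect_identical(glyphs(rv$map)[["P"]]$orientation, "vertical")
  expect_identical(nrow(validatePD(rv$map)), 0L)

  rr <- yedToSbgn(f$reversible)
  p <- glyphs(rr$map)[["P"]]
  expect_identical(p$orientation, "horizontal")
  # both ports occupied by production arcs
  cls <- vapply(arcs(rr$map), function(a) a$cls, character(1))
  expect_true(all(cls == "production"))
  expectNoPortRuleViolations(rr$map)
})

test_that("an unclassifiable node is isolated, the rest converts", {
  g <- yedGraph(
    list(yedNode("ok", "com.yworks.sbgn.SimpleChemical", bbox(0, 0, 60, 40),
                 label = "A"),
         yedNode("bad", "com.yworks.flowchart.Widget", bbox(100, 0, 60, 40)),
         yedNode("ok2", "com.yworks.sbgn.SimpleChemical", bbox(200, 0, 60, 40),
                 label = "B")),
    list(yedEdge("e1", "ok", "bad")))
  r <- yedToSbgn(g)
  expect_length(glyphs(r$map), 2L)
  rep <- reportRecords(r$report)
  expect_identical(sum(rep$rule == "unclassifiable-node" &
                         rep$severity == "error"), 1L)
  expect_identical(sum(rep$rule == "endpoint-dropped"), 1L)
})

test_that("single-flux-arc processes are reported and emitted portless", {
  g <- yedGraph(
    list(yedNode("s", "com.yworks.sbgn.SimpleChemical", bbox(0, 0, 60, 40),
                 label = "A"),
         yedNode("P", "com.yworks.sbgn.Process", bbox(200, 10, 20, 20))),
    list(yedEdge("e1", "s", "P")))   # one consumption
  r <- yedToSbgn(g)
  expect_length(glyphs(r$map)[["P"]]$ports, 0L)
  rep <- reportRecords(r$report)
  expect_identical(sum(rep$rule == "port-occupancy-unsatisfiable"), 1L)
  expect_identical(nrow(validatePD(r$map)), 0L)
})

test_that("consumption-only processes get a best-effort assignment", {
  g <- yedGraph(
    list(yedNode("s1", "com.yworks.sbgn.SimpleChemical", bbox(0, 0, 60, 40),
                 label = "A"),
         yedNode("s2", "com.yworks.sbgn.SimpleChemical", bbox(400, 0, 60, 40),
                 label = "B"),
         yedNode("P", "com.yworks.sbgn.Process", bbox(200, 10, 20, 20))),
    list(yedEdge("e1", "s1", "P"), yedEdge("e2", "s2", "P")))
  r <- yedToSbgn(g)
  rep <- reportRecords(r$report)
  expect_identical(sum(rep$rule == "degenerate-process"), 1L)
  expectNoPortRuleViolations(r$map)
})

test_that("forward-then-reverse reproduces the map up to the documented equivalence", {
  for (seed in c(5, 6, 7)) {
    spec <- fixtureSpec(nPools = 9, nProcesses = 5, seed = seed,
                        cloneFraction = 0.25, auxUnitFraction = 0.3,
                        reversibleFraction = 0.4)
    m <- generatePD(spec)
    r <- yedToSbgn(sbgnToYed(m)$graph)
    expect_true(isTRUE(pdEquivalent(m, r$map)),
                info = attr(pdEquivalent(m, r$map), "why"))
    expect_identical(nrow(validatePD(r$map)), 0L)
  }
})

test_that("flux arcs drawn backwards in yEd are normalised", {
  # consumption drawn process -> pool
  g <- yedGraph(
    list(yedNode("s1", "com.yworks.sbgn.SimpleChemical", bbox(0, 0, 60, 40),
                 label = "A"),
         yedNode("s2", "com.yworks.sbgn.SimpleChemical", bbox(400, 0, 60, 40),
                 label = "B"),
         yedNode("P", "com.yworks.sbgn.Process", bbox(200, 10, 20, 20))),
    list(yedEdge("e1", "P", "s1"),   # consumption, backwards
         yedEdge("e2", "P", "s2", targetArrow = "standard")))
  r <- yedToSbgn(g)
  rep <- reportRecords(r$report)
  expect_identical(sum(rep$rule == "arc-direction-normalised"), 1L)
  expect_identical(arcs(r$map)[["e1"]]$source, "s1")
  expect_identical(nrow(validatePD(r$map)), 0L)
})
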