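# Forward conversion: PD map -> yEd graph.

test_that("glyph mapping follows the palette table", {
  naf <- pdGlyph("g", "nucleic acid feature", bbox(0, 0, 90, 40))
  expect_identical(mapGlyph(naf)$node$configuration,
                   "com.yworks.sbgn.NucleicAcidFeature")

  mm <- pdGlyph("g", "macromolecule", bbox(0, 0, 90, 40), multimer = 2L)
  n <- mapGlyph(mm)$node
  expect_identical(unname(n$style[graphmlDialect()$mcountKey]), "2")
  expect_identical(n$configuration, "com.yworks.sbgn.Macromolecule")

  for (cls in c("omitted process", "uncertain process")) {
    n <- mapGlyph(pdGlyph("g", cls, bbox(0, 0, 20, 20)))$node
    expect_identical(n$configuration, "com.yworks.sbgn.Process")
  }
  expect_identical(mapGlyph(pdGlyph("g", "omitted process",
                                    bbox(0, 0, 20, 20)))$node$label, "\\\\")

  op <- mapGlyph(pdGlyph("g", "not", bbox(0, 0, 30, 30)))$node
  expect_identical(op$configuration, "com.yworks.sbgn.Operator")
  expect_identical(op$label, "NOT")

  expect_error(mapGlyph(pdGlyph("g", "state variable", bbox(0, 0, 20, 10))),
               "attach pass")
})

test_that("association and dissociation degrade to a process, once each", {
  a <- mapGlyph(pdGlyph("g", "association", bbox(0, 0, 20, 20)))
  expect_identical(a$node$configuration, "com.yworks.sbgn.Process")
  expect_identical(a$degradation$rule, "assoc_to_process")
  d <- mapGlyph(pdGlyph("g", "dissociation", bbox(0, 0, 20, 20)))
  expect_identical(d$degradation$rule, "dissoc_to_process")

  m <- pdMap(list(pdGlyph("g", "association", bbox(0, 0, 20, 20))), list())
  rep <- reportRecords(sbgnToYed(m)$report)
  expect_identical(sum(rep$rule == "assoc_to_process"), 1L)
})

test_that("up and down tags degrade to left-oriented tags", {
  up <- mapGlyph(pdGlyph("g", "tag", bbox(0, 0, 60, 30), orientation = "up"))
  expect_identical(up$degradation$rule, "updown_tag_to_left")
  expect_true(is.na(up$node$style[graphmlDialect()$inverseKey]))
  right <- mapGlyph(pdGlyph("g", "tag", bbox(0, 0, 60, 30),
                            orientation = "right"))
  expect_identical(unname(right$node$style[graphmlDialect()$inverseKey]),
                   "true")
  expect_null(right$degradation)
})

test_that("arc mapping collapses ports and applies the arrow bijection", {
  m <- tinyProcessMap()
  e <- mapArc(arcs(m)[["a3"]], m)         # production from port P.p2
  expect_identical(e$source, "P")
  expect_identical(e$targetArrow, "standard")
  ns <- pdArc("x", "necessary stimulation", "A", "P")
  expect_identical(mapArc(ns, m)$targetArrow, "white_delta_bar")
  expect_identical(mapArc(pdArc("x", "modulation", "A", "P"),
                          m)$targetArrow, "white_diamond")
})

test_that("port positions become bend points at the correct edge end", {
  m <- tinyProcessMap()   # left port at (90,110)
  conv <- sbgnToYed(m)
  e1 <- edges(conv$graph)[["a1"]]           # consumption A -> P
  expect_identical(unname(e1$bends[nrow(e1$bends), ]), c(90, 110))
  e3 <- edges(conv$graph)[["a3"]]           # production P -> C
  expect_identical(unname(e3$bends[1, ]), c(130, 110))
  # edges connect to the process node itself, not a port
  expect_identical(e1$target, "P")
  expect_identical(e3$source, "P")
})

test_that("renderPorts preserves pre-existing bends", {
  m <- tinyProcessMap()
  m@arcs[["a1"]]$bends <- rbind(c(40, 80), c(60, 95))
  conv <- sbgnToYed(m)
  b <- edges(conv$graph)[["a1"]]$bends
  expect_identical(unname(b),
                   rbind(c(40, 80), c(60, 95), c(90, 110)))
  edits <- renderPorts(glyphs(m)[["P"]], incidentArcs(m, "P"))
  expect_length(edits, 3L)
  expect_identical(edits[[1]]$where, "append")   # consumption ends at port
})

test_that("missing port coordinates are synthesised from the orientation", {
  g <- pdGlyph("P", "process", bbox(100, 100, 20, 20),
               orientation = "vertical",
               ports = list(pdPort("P.p1", NA, NA), pdPort("P.p2", NA, NA)))
  s <- pdGlyph("A", "simple chemical", bbox(100, 0, 60, 40), label = "A")
  t <- pdGlyph("B", "simple chemical", bbox(100, 200, 60, 40), label = "B")
  m <- pdMap(list(g, s, t),
             list(pdArc("a1", "consumption", "A", "P.p1"),
                  pdArc("a2", "production", "P.p2", "B")))
  conv <- sbgnToYed(m)
  rep <- reportRecords(conv$report)
  expect_identical(sum(rep$rule == "port-position-synthesised"), 1L)
  e <- edges(conv$graph)[["a1"]]
  expect_identical(unname(e$bends[nrow(e$bends), ]), c(110, 90))  # top tip
})

test_that("full conversion counts: nodes, groups, edges, aux refs", {
  m <- smallCompartmentMap()  # compartment + 2 pools + process + state var
  conv <- sbgnToYed(m)
  g <- conv$graph
  expect_length(nodes(g), 5L)
  expect_identical(sum(vapply(nodes(g), function(n) n$isGroup, logical(1))),
                   1L)
  expect_length(edges(g), 2L)
  expect_identical(nodes(g)[["m1"]]$auxRefs, "m1.sv")
  expect_identical(nodes(g)[["m1.sv"]]$label, "P@Ser15")
  expect_identical(nodes(g)[["m1"]]$parentGroup, "c1")
  expect_identical(nrow(reportRecords(conv$report)), 0L)
})

test_that("an empty map converts to an empty graph and report", {
  conv <- sbgnToYed(pdMap())
  expect_length(nodes(conv$graph), 0L)
  expect_length(edges(conv$graph), 0L)
  expect_identical(nrow(reportRecords(conv$report)), 0L)
})

test_that("class preservation holds across the forward map", {
  direct <- setdiff(glyphClasses(),
                    c("association", "dissociation", "state variable",
                      "unit of information"))
  for (cls in direct) {
    ori <- if (cls == "tag") "left" else NA_character_
    n <- mapGlyph(pdGlyph("g", cls, bbox(0, 0, 30, 30), orientation = ori))$node
    expect_identical(nodeClassOf(n), cls)
  }
})

test_that("geometry is copied coordinate-identically", {
  m <- generatePD(fixtureSpec(nPools = 6, nProcesses = 3, seed = 11))
  g <- sbgnToYed(m)$graph
  for (gid in names(glyphs(m)))
    expect_identical(nodes(g)[[gid]]$bbox, glyphs(m)[[gid]]$bbox)
  expect_length(nodes(g), length(glyphs(m)))
  expect_length(edges(g), length(arcs(m)))
})
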