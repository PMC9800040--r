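# Palette vocabulary: node and edge classification.

test_that("every directly-encoded palette configuration classifies back", {
  direct <- c(
    "complex"              = "com.yworks.sbgn.Complex",
    "macromolecule"        = "com.yworks.sbgn.Macromolecule",
    "nucleic acid feature" = "com.yworks.sbgn.NucleicAcidFeature",
    "simple chemical"      = "com.yworks.sbgn.SimpleChemical",
    "unspecified entity"   = "com.yworks.sbgn.UnspecifiedEntity",
    "perturbing agent"     = "com.yworks.sbgn.PerturbingAgent",
    "phenotype"            = "com.yworks.sbgn.Phenotype",
    "source and sink"      = "com.yworks.sbgn.EmptySet",
    "process"              = "com.yworks.sbgn.Process",
    "submap"               = "com.yworks.sbgn.Submap",
    "tag"                  = "com.yworks.sbgn.Tag",
    "state variable"       = "com.yworks.sbgn.StateVariable",
    "unit of information"  = "com.yworks.sbgn.UnitOfInformation")
  for (cls in names(direct)) {
    n <- yedNode("n", direct[[cls]], bbox(0, 0, 10, 10))
    expect_identical(nodeClassOf(n), cls)
  }
})

test_that("process nodes disambiguate by label", {
  mk <- function(label) yedNode("n", "com.yworks.sbgn.Process",
                                bbox(0, 0, 10, 10), label = label)
  expect_identical(nodeClassOf(mk(NA_character_)), "process")
  expect_identical(nodeClassOf(mk("\\\\")), "omitted process")
  expect_identical(nodeClassOf(mk("?")), "uncertain process")
})

test_that("operator nodes read AND/OR/NOT from the label", {
  mk <- function(label) yedNode("n", "com.yworks.sbgn.Operator",
                                bbox(0, 0, 10, 10), label = label)
  expect_identical(nodeClassOf(mk("AND")), "and")
  expect_identical(nodeClassOf(mk("or")), "or")
  expect_identical(nodeClassOf(mk("NOT")), "not")
  expect_error(nodeClassOf(mk("XOR")), "unrecognised label",
               class = "sbgnyedClassificationError")
})

test_that("group nodes are compartments and unknown configurations error", {
  g <- yedNode("c", bbox = bbox(0, 0, 100, 100), isGroup = TRUE)
  expect_identical(nodeClassOf(g), "compartment")
  bad <- yedNode("n", "com.yworks.bpmn.Task", bbox(0, 0, 10, 10))
  err <- tryCatch(nodeClassOf(bad), error = identity)
  expect_s3_class(err, "sbgnyedClassificationError")
  expect_match(conditionMessage(err), "com.yworks.bpmn.Task", fixed = TRUE)
})

test_that("mcount below 2 is rejected and tag inversion is read", {
  d <- graphmlDialect()
  expect_error(yedNode("n", "com.yworks.sbgn.SimpleChemical",
                       bbox(0, 0, 10, 10),
                       style = makeStyleForTest(mcount = 1)),
               "mcount")
  n <- yedNode("t", "com.yworks.sbgn.Tag", bbox(0, 0, 10, 10),
               style = makeStyleForTest(inverse = "true"))
  r <- yedToSbgn(yedGraph(list(n), list()))
  expect_identical(glyphs(r$map)[["t"]]$orientation, "right")
})

test_that("the seven arrow pairs map bijectively to arc classes", {
  d <- graphmlDialect()
  for (cls in arcClasses()) {
    a <- d$arrows[[cls]]
    e <- yedEdge("e", "x", "y", sourceArrow = a[["source"]],
                 targetArrow = a[["target"]])
    expect_identical(edgeClassOf(e), cls)
  }
  # the named examples
  expect_identical(edgeClassOf(yedEdge("e", "x", "y",
                                       targetArrow = "t_shape")),
                   "inhibition")
  expect_identical(edgeClassOf(yedEdge("e", "x", "y")), "consumption")
  expect_identical(edgeClassOf(yedEdge("e", "x", "y",
                                       targetArrow = "circle")),
                   "catalysis")
  expect_error(edgeClassOf(yedEdge("e", "x", "y", targetArrow = "skull")),
               class = "sbgnyedClassificationError")
})
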