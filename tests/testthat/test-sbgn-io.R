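# SBGN-ML reading and writing.

test_that("a minimal document parses into one glyph", {
  xml <- paste0(
    '<sbgn xmlns="http://sbgn.org/libsbgn/0.2">',
    '<map language="process description">',
    '<glyph class="macromolecule" id="g1"><label text="PK"/>',
    '<bbox x="10" y="20" w="90" h="40"/></glyph>',
    '</map></sbgn>')
  m <- readSbgnMl(xml)
  expect_length(glyphs(m), 1L)
  expect_length(arcs(m), 0L)
  g <- glyphs(m)[["g1"]]
  expect_identical(g$cls, "macromolecule")
  expect_identical(g$label, "PK")
  expect_identical(unname(g$bbox), c(10, 20, 90, 40))
})

test_that("ports, arcs and bends are captured; port refs resolve as ports", {
  f <- tempfile(fileext = ".sbgn")
  writeSbgnMl(tinyProcessMap(), f)
  m <- readSbgnMl(f)
  expect_length(incidentArcs(m, "P"), 3L)
  a1 <- arcs(m)[["a1"]]
  expect_identical(a1$target, "P.p1")
  pidx <- sbgnyed:::portIndex(m)
  expect_true(a1$target %in% pidx$port)        # a port, not a glyph
  expect_false(a1$target %in% names(glyphs(m)))
})

test_that("write-then-read is the identity on all model fields", {
  for (seed in c(1, 2)) {
    m <- generatePD(fixtureSpec(nPools = 8, nProcesses = 5, seed = seed,
                                cloneFraction = 0.25, auxUnitFraction = 0.4,
                                multimerFraction = 0.4,
                                degradationElements = TRUE))
    f <- tempfile(fileext = ".sbgn")
    writeSbgnMl(m, f)
    m2 <- readSbgnMl(f)
    expect_identical(glyphs(m2), glyphs(m))
    expect_identical(arcs(m2), arcs(m))
  }
})

test_that("colour extensions survive the round trip", {
  m <- tinyProcessMap()
  m@glyphs[["A"]]$extension <- c(fill = "#CCFFCC", stroke = "#112233")
  f <- tempfile(fileext = ".sbgn")
  writeSbgnMl(m, f)
  txt <- readChar(f, file.size(f))
  expect_match(txt, "#CCFFCC", fixed = TRUE)
  m2 <- readSbgnMl(f)
  expect_identical(m2@glyphs[["A"]]$extension,
                   c(fill = "#CCFFCC", stroke = "#112233"))
})

test_that("unknown extension payloads are preserved verbatim", {
  m <- tinyProcessMap()
  m@glyphs[["A"]]$extension <-
    c(raw = "<annotation xmlns=\"urn:test\">kegg:C00022</annotation>")
  f <- tempfile(fileext = ".sbgn")
  writeSbgnMl(m, f)
  m2 <- readSbgnMl(f)
  expect_match(m2@glyphs[["A"]]$extension[["raw"]], "kegg:C00022")
})

test_that("an empty map writes a schema-valid document", {
  f <- tempfile(fileext = ".sbgn")
  writeSbgnMl(pdMap(), f)
  expect_true(validateSbgnFile(f))
  expect_length(glyphs(readSbgnMl(f)), 0L)
})

test_that("emitted files validate against the shipped schema", {
  f <- tempfile(fileext = ".sbgn")
  writeSbgnMl(generatePD(fixtureSpec(nPools = 10, nProcesses = 6, seed = 3,
                                     degradationElements = TRUE)), f)
  expect_true(validateSbgnFile(f))
})

test_that("milestone-3 namespaces read tolerantly; other roots do not", {
  xml3 <- paste0(
    '<sbgn xmlns="http://sbgn.org/libsbgn/0.3">',
    '<map language="process description">',
    '<glyph class="simple chemical" id="s1">',
    '<bbox x="0" y="0" w="60" h="40"/></glyph></map></sbgn>')
  expect_length(glyphs(readSbgnMl(xml3)), 1L)
  expect_error(readSbgnMl("<graphml></graphml>"), "root element")
  expect_error(readSbgnMl("<sbgn><map language='activity flow'/></sbgn>"),
               "unsupported SBGN language")
  expect_error(readSbgnMl("<sbgn><map language='process descr"),
               "parse error")
})

test_that("dangling arc references are a reference error", {
  xml <- paste0(
    '<sbgn xmlns="http://sbgn.org/libsbgn/0.2">',
    '<map language="process description">',
    '<glyph class="simple chemical" id="s1">',
    '<bbox x="0" y="0" w="60" h="40"/></glyph>',
    '<arc class="consumption" id="a1" source="s1" target="ghost">',
    '<start x="0" y="0"/><end x="1" y="1"/></arc></map></sbgn>')
  expect_error(readSbgnMl(xml), "ghost")
})

test_that("strict writing refuses invalid maps; lax mode warns", {
  m <- tinyProcessMap()
  m@arcs <- m@arcs[c("a1", "a2")]   # port rule 2 violated
  f <- tempfile(fileext = ".sbgn")
  expect_error(writeSbgnMl(m, f, strict = TRUE), "violation")
  expect_warning(writeSbgnMl(m, f, strict = FALSE), "violation")
  expect_true(file.exists(f))
})

test_that("flux arcs drawn against the port convention are normalised", {
  xml <- paste0(
    '<sbgn xmlns="http://sbgn.org/libsbgn/0.2">',
    '<map language="process description">',
    '<glyph class="simple chemical" id="s1">',
    '<bbox x="0" y="100" w="60" h="40"/></glyph>',
    '<glyph class="simple chemical" id="s2">',
    '<bbox x="300" y="100" w="60" h="40"/></glyph>',
    '<glyph class="process" id="p" orientation="horizontal">',
    '<bbox x="150" y="110" w="20" h="20"/>',
    '<port id="p.1" x="140" y="120"/><port id="p.2" x="180" y="120"/>',
    '</glyph>',
    '<arc class="consumption" id="a1" source="p.1" target="s1">',
    '<start x="0" y="0"/><end x="1" y="1"/></arc>',
    '<arc class="production" id="a2" source="s2" target="p.2">',
    '<start x="0" y="0"/><end x="1" y="1"/></arc>',
    '</map></sbgn>')
  m <- readSbgnMl(xml)
  expect_identical(arcs(m)[["a1"]]$source, "s1")   # entity -> port
  expect_identical(arcs(m)[["a1"]]$target, "p.1")
  expect_identical(arcs(m)[["a2"]]$source, "p.2")  # port -> entity
  expect_identical(nrow(validatePD(m)), 0L)
})
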