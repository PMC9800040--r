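# SBGN-ML (Process Description, milestone 2) reader and writer.
#
# The writer emits the milestone-2 namespace with glyphs before arcs and
# decimal geometry attributes; the reader additionally tolerates the
# milestone-3 namespace. Colour/annotation conservation uses a converter-owned
# <extension> child (urn:sbgnyed:style) holding fill/stroke hex strings and
# the multimer cardinality; unknown extension payloads are preserved verbatim.

SBGN_NS_M2 <- "http://sbgn.org/libsbgn/0.2"
SBGN_NS_M3 <- "http://sbgn.org/libsbgn/0.3"
STYLE_NS <- "urn:sbgnyed:style"

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# decimal attribute formatting: fixed %.6f with trailing zeros trimmed, so
# values on the package's 0.1-unit grids serialise exactly
fmtNum <- function(x) {
  s <- sprintf("%.6f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

extensionXml <- function(ext, indent) {
  if (!length(ext)) return(character())
  keys <- setdiff(names(ext), "raw")
  keys <- keys[!is.na(ext[keys])]
  parts <- character()
  if (length(keys))
    parts <- sprintf('%s  <ysbgn:style xmlns:ysbgn="%s" %s/>', indent, STYLE_NS,
                     paste(sprintf('%s="%s"', keys, xmlEscape(ext[keys])),
                           collapse = " "))
  if ("raw" %in% names(ext) && !is.na(ext[["raw"]]) && nzchar(ext[["raw"]]))
    parts <- c(parts, paste0(indent, "  ", ext[["raw"]]))
  c(paste0(indent, "<extension>"), parts, paste0(indent, "</extension>"))
}

glyphXml <- function(g, childrenOf, glyphs, indent) {
  cls <- g$cls
  if (!is.na(g$multimer)) cls <- paste(cls, "multimer")
  attrs <- sprintf('class="%s" id="%s"', xmlEscape(cls), xmlEscape(g$id))
  if (!is.na(g$compartmentRef))
    attrs <- paste0(attrs, sprintf(' compartmentRef="%s"',
                                   xmlEscape(g$compartmentRef)))
  if (!is.na(g$orientation))
    attrs <- paste0(attrs, sprintf(' orientation="%s"', g$orientation))
  ext <- g$extension
  if (!is.na(g$multimer)) ext["cardinality"] <- as.character(g$multimer)
  lines <- c(sprintf("%s<glyph %s>", indent, attrs),
             extensionXml(ext, paste0(indent, "  ")))
  if (!is.na(g$label))
    lines <- c(lines, sprintf('%s  <label text="%s"/>', indent,
                              xmlEscape(g$label)))
  if (!is.na(g$stateValue) || !is.na(g$stateVariable)) {
    sa <- character()
    if (!is.na(g$stateValue))
      sa <- c(sa, sprintf('value="%s"', xmlEscape(g$stateValue)))
    if (!is.na(g$stateVariable))
      sa <- c(sa, sprintf('variable="%s"', xmlEscape(g$stateVariable)))
    lines <- c(lines, sprintf("%s  <state %s/>", indent,
                              paste(sa, collapse = " ")))
  }
  if (isTRUE(g$clone)) {
    lines <- c(lines, if (!is.na(g$cloneLabel))
      sprintf('%s  <clone><label text="%s"/></clone>', indent,
              xmlEscape(g$cloneLabel))
      else paste0(indent, "  <clone/>"))
  }
  b <- g$bbox
  lines <- c(lines, sprintf('%s  <bbox x="%s" y="%s" w="%s" h="%s"/>', indent,
                            fmtNum(b[["x"]]), fmtNum(b[["y"]]),
                            fmtNum(b[["w"]]), fmtNum(b[["h"]])))
  for (cid in childrenOf[[g$id]])
    lines <- c(lines, glyphXml(glyphs[[cid]], childrenOf, glyphs,
                               paste0(indent, "  ")))
  for (p in g$ports)
    lines <- c(lines, sprintf('%s  <port id="%s" x="%s" y="%s"/>', indent,
                              xmlEscape(p$id), fmtNum(p$x), fmtNum(p$y)))
  c(lines, paste0(indent, "</glyph>"))
}

arcXml <- function(a, s, t, indent) {
  lines <- c(sprintf('%s<arc class="%s" id="%s" source="%s" target="%s">',
                     indent, xmlEscape(a$cls), xmlEscape(a$id),
                     xmlEscape(a$source), xmlEscape(a$target)),
             extensionXml(a$extension, paste0(indent, "  ")),
             sprintf('%s  <start x="%s" y="%s"/>', indent,
                     fmtNum(s[1]), fmtNum(s[2])))
  if (nrow(a$bends))
    lines <- c(lines, sprintf('%s  <next x="%s" y="%s"/>', indent,
                              fmtNum(a$bends[, "x"]), fmtNum(a$bends[, "y"])))
  c(lines, sprintf('%s  <end x="%s" y="%s"/>', indent,
                   fmtNum(t[1]), fmtNum(t[2])),
    paste0(indent, "</arc>"))
}

#' Serialise a PDMap to SBGN-ML
#'
#' \code{sbgnmlString} renders the XML text; [writeSbgnMl()] writes it to a
#' file after validating the map. Auxiliary units and complex members (glyphs
#' with a \code{parent}) are nested inside their carrying glyph; arc
#' \code{start}/\code{end} points are derived from the endpoint geometry
#' (port position, or glyph centre) and bend points become \code{<next>}
#' elements.
#'
#' @param map a [PDMap].
#' @return a single XML string.
#' @export
sbgnmlString <- function(map) {
  stopifnot(is(map, "PDMap"))
  gl <- map@glyphs
  parent <- vapply(gl, function(g) g$parent, character(1))
  childrenOf <- split(names(gl)[!is.na(parent)], parent[!is.na(parent)])
  pidx <- portIndex(map)
  # vectorised endpoint geometry: glyph centres and port positions by id
  endIds <- c(names(gl), pidx$port)
  ctrX <- c(vapply(gl, function(g) g$bbox[["x"]] + g$bbox[["w"]] / 2,
                   numeric(1), USE.NAMES = FALSE), pidx$x)
  ctrY <- c(vapply(gl, function(g) g$bbox[["y"]] + g$bbox[["h"]] / 2,
                   numeric(1), USE.NAMES = FALSE), pidx$y)
  ar <- map@arcs
  si <- match(vapply(ar, function(a) a$source, character(1),
                     USE.NAMES = FALSE), endIds)
  ti <- match(vapply(ar, function(a) a$target, character(1),
                     USE.NAMES = FALSE), endIds)
  top <- names(gl)[is.na(parent)]
  head <- c('<?xml version="1.0" encoding="UTF-8"?>',
            sprintf('<sbgn xmlns="%s">', SBGN_NS_M2),
            '  <map language="process description">')
  glyphLines <- lapply(gl[top], glyphXml, childrenOf = childrenOf,
                       glyphs = gl, indent = "    ")
  arcLines <- lapply(seq_along(ar), function(i) {
    pick <- function(j) if (is.na(j)) c(0, 0) else c(ctrX[j], ctrY[j])
    arcXml(ar[[i]], pick(si[i]), pick(ti[i]), "    ")
  })
  paste(c(head, unlist(glyphLines, use.names = FALSE),
          unlist(arcLines, use.names = FALSE), "  </map>", "</sbgn>", ""),
        collapse = "\n")
}

#' Write a PDMap as an SBGN-ML file
#'
#' @param map a [PDMap].
#' @param path output file path.
#' @param strict if \code{TRUE} (default) refuse to write a map with
#'   [validatePD()] violations; if \code{FALSE}, warn and write anyway.
#' @return invisibly, \code{path}.
#' @seealso [readSbgnMl()], [sbgnmlString()], [validateSbgnFile()]
#' @export
writeSbgnMl <- function(map, path, strict = TRUE) {
  v <- validatePD(map)
  if (nrow(v)) {
    msg <- sprintf("map has %d validation violation(s); first: [%s] %s", nrow(v),
                   v$rule[1], v$message[1])
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  writeLines(sbgnmlString(map), path, sep = "")
  invisible(path)
}

.parseExtension <- function(node) {
  extNode <- xml2::xml_find_first(node, "./extension")
  ext <- character()
  if (!inherits(extNode, "xml_missing")) {
    for (ch in xml2::xml_children(extNode)) {
      if (xml2::xml_name(ch) == "style") {
        at <- xml2::xml_attrs(ch)
        at <- at[setdiff(names(at), c("xmlns:ysbgn", "xmlns"))]
        for (k in names(at)) ext[k] <- at[[k]]
      } else {
        raw <- as.character(ch)
        ext["raw"] <- if (is.na(ext["raw"])) raw else paste0(ext[["raw"]], raw)
      }
    }
  }
  ext
}

.parseGlyphNode <- function(node, parentId) {
  at <- xml2::xml_attrs(node)
  cls <- at[["class"]]
  multimer <- NA_integer_
  ext <- .parseExtension(node)
  if (grepl(" multimer$", cls)) {
    cls <- sub(" multimer$", "", cls)
    multimer <- if (!is.na(ext["cardinality"]))
      as.integer(ext[["cardinality"]]) else 2L
    ext <- ext[setdiff(names(ext), "cardinality")]
  }
  if (!cls %in% glyphClasses())
    stop(sprintf("unknown glyph class '%s' on glyph '%s'", cls, at[["id"]]),
         call. = FALSE)
  bb <- xml2::xml_find_first(node, "./bbox")
  if (inherits(bb, "xml_missing"))
    stop(sprintf("glyph '%s' has no bbox", at[["id"]]), call. = FALSE)
  bbv <- bbox(as.numeric(xml2::xml_attr(bb, "x")),
              as.numeric(xml2::xml_attr(bb, "y")),
              as.numeric(xml2::xml_attr(bb, "w")),
              as.numeric(xml2::xml_attr(bb, "h")))
  lab <- xml2::xml_find_first(node, "./label")
  label <- if (inherits(lab, "xml_missing")) NA_character_ else
    xml2::xml_attr(lab, "text")
  st <- xml2::xml_find_first(node, "./state")
  sv <- svv <- NA_character_
  if (!inherits(st, "xml_missing")) {
    sv <- xml2::xml_attr(st, "value")
    svv <- xml2::xml_attr(st, "variable")
  }
  cl <- xml2::xml_find_first(node, "./clone")
  clone <- !inherits(cl, "xml_missing")
  cloneLabel <- NA_character_
  if (clone) {
    cll <- xml2::xml_find_first(cl, "./label")
    if (!inherits(cll, "xml_missing")) cloneLabel <- xml2::xml_attr(cll, "text")
  }
  ports <- lapply(xml2::xml_find_all(node, "./port"), function(p) {
    pdPort(xml2::xml_attr(p, "id"), as.numeric(xml2::xml_attr(p, "x")),
           as.numeric(xml2::xml_attr(p, "y")))
  })
  g <- pdGlyph(at[["id"]], cls, bbv, label = label,
               compartmentRef = if ("compartmentRef" %in% names(at))
                 at[["compartmentRef"]] else NA_character_,
               parent = parentId, multimer = multimer,
               clone = clone, cloneLabel = cloneLabel,
               stateValue = sv, stateVariable = svv,
               orientation = if ("orientation" %in% names(at))
                 at[["orientation"]] else NA_character_,
               ports = ports, extension = ext)
  out <- list(g)
  for (ch in xml2::xml_find_all(node, "./glyph"))
    out <- c(out, .parseGlyphNode(ch, at[["id"]]))
  out
}

#' Read an SBGN-ML Process Description file
#'
#' Parses milestone-2 files (and, tolerantly, milestone-3 namespaces) into a
#' [PDMap]. Every glyph (including nested auxiliary units and complex
#' members), port, arc, bend point, label, state, clone marker and extension
#' payload is captured. Consumption/production arcs pointing the wrong way
#' relative to ports are normalised (endpoints swapped); pass a reporter to
#' see these repairs.
#'
#' @param x file path, or a string containing the XML document.
#' @return a [PDMap].
#' @export
readSbgnMl <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e)
    stop(sprintf("SBGN-ML parse error: %s", conditionMessage(e)),
         call. = FALSE))
  ns <- xml2::xml_ns(doc)
  rootNs <- tryCatch(unname(ns[["d1"]]), error = function(e) NA_character_)
  if (!is.na(rootNs) && !rootNs %in% c(SBGN_NS_M2, SBGN_NS_M3) &&
      grepl("sbgn", rootNs, fixed = TRUE) == FALSE)
    stop(sprintf("unsupported XML namespace '%s'", rootNs), call. = FALSE)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbgn")
    stop("not an SBGN-ML document (root element is not <sbgn>)",
         call. = FALSE)
  mapNode <- xml2::xml_find_first(doc, "./map")
  if (inherits(mapNode, "xml_missing"))
    stop("SBGN-ML document has no <map>", call. = FALSE)
  lang <- xml2::xml_attr(mapNode, "language")
  if (!is.na(lang) && lang != "process description")
    stop(sprintf("unsupported SBGN language '%s' (only process description)",
                 lang), call. = FALSE)
  glyphs <- list()
  for (gn in xml2::xml_find_all(mapNode, "./glyph"))
    glyphs <- c(glyphs, .parseGlyphNode(gn, NA_character_))
  arcs <- lapply(xml2::xml_find_all(mapNode, "./arc"), function(an) {
    bends <- NULL
    nx <- xml2::xml_find_all(an, "./next")
    if (length(nx))
      bends <- cbind(x = as.numeric(xml2::xml_attr(nx, "x")),
                     y = as.numeric(xml2::xml_attr(nx, "y")))
    pdArc(xml2::xml_attr(an, "id"), xml2::xml_attr(an, "class"),
          xml2::xml_attr(an, "source"), xml2::xml_attr(an, "target"),
          bends = bends, extension = .parseExtension(an))
  })
  map <- pdMap(glyphs, arcs)
  # reference check + direction normalisation
  pidx <- portIndex(map)
  known <- c(names(map@glyphs), pidx$port)
  if (length(map@arcs)) {
    ends <- c(vapply(map@arcs, function(a) a$source, character(1)),
              vapply(map@arcs, function(a) a$target, character(1)))
    bad <- which(!ends %in% known)
    if (length(bad)) {
      i <- (bad[1] - 1L) %% length(map@arcs) + 1L
      stop(sprintf("arc '%s' references unknown id '%s'",
                   map@arcs[[i]]$id, ends[bad[1]]), call. = FALSE)
    }
  }
  normalizeArcDirections(map)
}

# swap endpoints of consumption arcs written port->entity and production arcs
# written entity->port (hand-drawn files are messy; the converter repairs)
normalizeArcDirections <- function(map, rep = NULL) {
  pidx <- portIndex(map)
  if (!nrow(pidx) || !length(map@arcs)) return(map)
  ports <- pidx$port
  cls <- vapply(map@arcs, function(a) a$cls, character(1), USE.NAMES = FALSE)
  srcP <- vapply(map@arcs, function(a) a$source, character(1),
                 USE.NAMES = FALSE) %in% ports
  tgtP <- vapply(map@arcs, function(a) a$target, character(1),
                 USE.NAMES = FALSE) %in% ports
  swaps <- (cls == "consumption" & srcP & !tgtP) |
    (cls == "production" & tgtP & !srcP)
  for (i in which(swaps)) {
    a <- map@arcs[[i]]
    {
      s <- a$source
      a$source <- a$target
      a$target <- s
      a$bends <- a$bends[rev(seq_len(nrow(a$bends))), , drop = FALSE]
      map@arcs[[i]] <- a
      if (!is.null(rep))
        note(rep, "warning", "arc-direction-normalised", a$id,
             "endpoints swapped to match PD port convention")
    }
  }
  map
}

#' Path to the shipped SBGN-ML structural schema
#'
#' A converter-owned XSD describing the structure of the milestone-2 dialect
#' this package emits (glyph/arc/port/bbox/label/state/clone/extension). It
#' is authored for this package — a structural subset, not the official
#' libSBGN schema — and is what [validateSbgnFile()] checks against.
#'
#' @return file path of the XSD.
#' @export
sbgnSchemaPath <- function() {
  system.file("extdata", "sbgn-pd-m2-subset.xsd", package = "sbgnyed",
              mustWork = TRUE)
}

#' Validate an SBGN-ML file against the shipped schema
#'
#' @param path file path (or XML string).
#' @return \code{TRUE} if the document validates; otherwise \code{FALSE} with
#'   the schema errors in attribute \code{"errors"}.
#' @export
validateSbgnFile <- function(path) {
  doc <- xml2::read_xml(path)
  schema <- xml2::read_xml(sbgnSchemaPath())
  xml2::xml_validate(doc, schema)
}
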