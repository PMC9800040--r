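# yEd-flavoured GraphML reader and writer.
#
# Compartments are emitted as yEd group nodes (nested <graph> elements); bend
# points are absolute <y:Point> coordinates inside <y:Path>, matching the
# SBGN bbox coordinates so geometry is identical across formats. Auxiliary
# unit references are a converter-owned <data> key ("auxRefs",
# space-separated node ids) on the carrying node.

# canonical style vector (fixed key order so read/write round-trips are
# field-identical)
makeStyle <- function(mcount = NA, inverse = NA, clone = NA, cloneLabel = NA,
                      fill = NA, border = NA) {
  d <- graphmlDialect()
  v <- c(mcount, inverse, clone, cloneLabel, fill, border)
  names(v) <- c(d$mcountKey, d$inverseKey, d$cloneKey, d$cloneLabelKey,
                "fill", "border")
  out <- as.character(v)
  names(out) <- names(v)
  out[!is.na(out)]
}

nodeGraphicsXml <- function(n, indent) {
  d <- graphmlDialect()
  b <- n$bbox
  tag <- if (n$isGroup) "y:GroupNode" else
    sprintf('y:GenericNode configuration="%s"', xmlEscape(n$configuration))
  closeTag <- if (n$isGroup) "y:GroupNode" else "y:GenericNode"
  lines <- sprintf("%s<%s>", indent, tag)
  lines <- c(lines, sprintf(
    '%s  <y:Geometry height="%s" width="%s" x="%s" y="%s"/>', indent,
    fmtNum(b[["h"]]), fmtNum(b[["w"]]), fmtNum(b[["x"]]), fmtNum(b[["y"]])))
  st <- n$style
  if (!is.na(st["fill"]))
    lines <- c(lines, sprintf('%s  <y:Fill color="%s" transparent="false"/>',
                              indent, xmlEscape(st[["fill"]])))
  if (!is.na(st["border"]))
    lines <- c(lines, sprintf(
      '%s  <y:BorderStyle color="%s" type="line" width="1.0"/>', indent,
      xmlEscape(st[["border"]])))
  if (!is.na(n$label))
    lines <- c(lines, sprintf("%s  <y:NodeLabel>%s</y:NodeLabel>", indent,
                              xmlEscape(n$label)))
  propKeys <- c(d$mcountKey, d$inverseKey, d$cloneKey, d$cloneLabelKey)
  propCls <- c("java.lang.Integer", "java.lang.Boolean", "java.lang.Boolean",
               "java.lang.String")
  present <- !is.na(st[propKeys])
  if (any(present)) {
    lines <- c(lines, paste0(indent, "  <y:StyleProperties>"))
    for (i in which(present))
      lines <- c(lines, sprintf(
        '%s    <y:Property class="%s" name="%s" value="%s"/>', indent,
        propCls[i], propKeys[i], xmlEscape(st[[propKeys[i]]])))
    lines <- c(lines, paste0(indent, "  </y:StyleProperties>"))
  }
  c(lines, sprintf("%s</%s>", indent, closeTag))
}

nodeXml <- function(n, childrenOf, nodes, keys, indent) {
  attrs <- sprintf('id="%s"', xmlEscape(n$id))
  if (n$isGroup) attrs <- paste0(attrs, ' yfiles.foldertype="group"')
  lines <- sprintf("%s<node %s>", indent, attrs)
  if (length(n$auxRefs))
    lines <- c(lines, sprintf('%s  <data key="%s">%s</data>', indent,
                              keys[["auxRefs"]],
                              xmlEscape(paste(n$auxRefs, collapse = " "))))
  lines <- c(lines, sprintf('%s  <data key="%s">', indent,
                            keys[["nodegraphics"]]),
             nodeGraphicsXml(n, paste0(indent, "    ")),
             paste0(indent, "  </data>"))
  kids <- childrenOf[[n$id]]
  if (n$isGroup && length(kids)) {
    kidLines <- lapply(nodes[kids], nodeXml, childrenOf = childrenOf,
                       nodes = nodes, keys = keys,
                       indent = paste0(indent, "    "))
    lines <- c(lines, sprintf('%s  <graph edgedefault="directed" id="%s:">',
                              indent, xmlEscape(n$id)),
               unlist(kidLines, use.names = FALSE),
               paste0(indent, "  </graph>"))
  }
  c(lines, paste0(indent, "</node>"))
}

edgeXml <- function(e, keys, indent) {
  lines <- c(sprintf('%s<edge id="%s" source="%s" target="%s">', indent,
                     xmlEscape(e$id), xmlEscape(e$source),
                     xmlEscape(e$target)),
             sprintf('%s  <data key="%s">', indent, keys[["edgegraphics"]]),
             paste0(indent, "    <y:PolyLineEdge>"))
  if (nrow(e$bends)) {
    lines <- c(lines,
               paste0(indent, '      <y:Path sx="0.0" sy="0.0" tx="0.0" ty="0.0">'),
               sprintf('%s        <y:Point x="%s" y="%s"/>', indent,
                       fmtNum(e$bends[, "x"]), fmtNum(e$bends[, "y"])),
               paste0(indent, "      </y:Path>"))
  }
  if (!is.na(e$colour))
    lines <- c(lines, sprintf(
      '%s      <y:LineStyle color="%s" type="line" width="1.0"/>', indent,
      xmlEscape(e$colour)))
  lines <- c(lines, sprintf('%s      <y:Arrows source="%s" target="%s"/>',
                            indent, e$sourceArrow, e$targetArrow))
  if (!is.na(e$label))
    lines <- c(lines, sprintf("%s      <y:EdgeLabel>%s</y:EdgeLabel>", indent,
                              xmlEscape(e$label)))
  c(lines, paste0(indent, "    </y:PolyLineEdge>"),
    paste0(indent, "  </data>"), paste0(indent, "</edge>"))
}

#' Serialise a YedGraph to GraphML
#'
#' \code{graphmlString} renders the XML text; [writeGraphml()] writes it to a
#' file after an integrity check. Group nodes become nested \code{<graph>}
#' elements; every \code{<data>} element references a declared \code{<key>}.
#'
#' @param graph a [YedGraph].
#' @return a single XML string.
#' @export
graphmlString <- function(graph) {
  stopifnot(is(graph, "YedGraph"))
  d <- graphmlDialect()
  nodes <- graph@nodes
  parent <- vapply(nodes, function(n) n$parentGroup, character(1))
  childrenOf <- split(names(nodes)[!is.na(parent)], parent[!is.na(parent)])
  top <- names(nodes)[is.na(parent)]
  lines <- c('<?xml version="1.0" encoding="UTF-8" standalone="no"?>',
             sprintf(paste0('<graphml xmlns="%s" xmlns:y="%s">'),
                     d$graphmlNs, d$yfilesNs),
             sprintf('  <key for="node" id="%s" yfiles.type="nodegraphics"/>',
                     d$keys[["nodegraphics"]]),
             sprintf('  <key for="edge" id="%s" yfiles.type="edgegraphics"/>',
                     d$keys[["edgegraphics"]]),
             sprintf('  <key attr.name="auxRefs" attr.type="string" for="node" id="%s"/>',
                     d$keys[["auxRefs"]]),
             '  <graph edgedefault="directed" id="G">')
  nodeLines <- lapply(nodes[top], nodeXml, childrenOf = childrenOf,
                      nodes = nodes, keys = d$keys, indent = "    ")
  edgeLines <- lapply(graph@edges, edgeXml, keys = d$keys, indent = "    ")
  paste(c(lines, unlist(nodeLines, use.names = FALSE),
          unlist(edgeLines, use.names = FALSE), "  </graph>", "</graphml>",
          ""), collapse = "\n")
}

#' Write a YedGraph as a GraphML file
#'
#' @param graph a [YedGraph].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @seealso [readGraphml()], [graphmlString()]
#' @export
writeGraphml <- function(graph, path) {
  nid <- names(graph@nodes)
  for (e in graph@edges) {
    bad <- setdiff(c(e$source, e$target), nid)
    if (length(bad))
      stop(sprintf("edge '%s' references unknown node '%s'", e$id, bad[1]),
           call. = FALSE)
  }
  for (n in graph@nodes) {
    bad <- setdiff(n$auxRefs, nid)
    if (length(bad))
      stop(sprintf("node '%s' auxRefs reference unknown node '%s'", n$id,
                   bad[1]), call. = FALSE)
    if (!is.na(n$parentGroup) && !n$parentGroup %in% nid)
      stop(sprintf("node '%s' references unknown group '%s'", n$id,
                   n$parentGroup), call. = FALSE)
  }
  writeLines(graphmlString(graph), path, sep = "")
  invisible(path)
}

#' Read a yEd-flavoured GraphML file
#'
#' Parses a GraphML document into a [YedGraph]: nodes (including nested group
#' nodes, recorded via \code{parentGroup}), geometry, labels, style
#' properties, colours, edges with their bend points and arrowhead tokens,
#' and auxiliary-unit references. Nodes without a recognised SBGN palette
#' configuration are kept (with their raw configuration string); they fail
#' classification later in [yedToSbgn()], which records the error and
#' continues.
#'
#' @param x file path, or a string containing the XML document.
#' @return a [YedGraph].
#' @export
readGraphml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e)
    stop(sprintf("GraphML parse error: %s", conditionMessage(e)),
         call. = FALSE))
  xml2::xml_ns_strip(doc)
  # yFiles elements carry a prefixed namespace that xml_ns_strip leaves in
  # place, so all style lookups go through local-name()
  ln1 <- function(node, path) {
    steps <- strsplit(path, "/", fixed = TRUE)[[1]]
    xml2::xml_find_first(node, paste0("./", paste(sprintf(
      "*[local-name()='%s']", steps), collapse = "/")))
  }
  lnAll <- function(node, path) {
    steps <- strsplit(path, "/", fixed = TRUE)[[1]]
    xml2::xml_find_all(node, paste0("./", paste(sprintf(
      "*[local-name()='%s']", steps), collapse = "/")))
  }
  if (xml2::xml_name(doc) != "graphml")
    stop("not a GraphML document (root element is not <graphml>)",
         call. = FALSE)
  d <- graphmlDialect()
  # resolve key ids from the declarations (other emitters use other ids)
  keyNodes <- xml2::xml_find_all(doc, "./key")
  auxKey <- NA_character_
  for (k in keyNodes) {
    if (identical(xml2::xml_attr(k, "attr.name"), "auxRefs"))
      auxKey <- xml2::xml_attr(k, "id")
  }
  nodeEls <- xml2::xml_find_all(doc, ".//node")
  nodes <- lapply(nodeEls, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    anc <- xml2::xml_find_first(nd, "ancestor::node[1]")
    parentGroup <- if (inherits(anc, "xml_missing")) NA_character_ else
      xml2::xml_attr(anc, "id")
    gfx <- xml2::xml_find_first(
      nd, paste0("./*[local-name()='data']/*[local-name()='GenericNode'",
                 " or local-name()='GroupNode' or local-name()='ShapeNode']"))
    isGroup <- !inherits(gfx, "xml_missing") &&
      xml2::xml_name(gfx) == "GroupNode"
    conf <- if (inherits(gfx, "xml_missing")) "unknown" else
      if (isGroup) "y:GroupNode" else
        xml2::xml_attr(gfx, "configuration", default = "unknown")
    geo <- if (!inherits(gfx, "xml_missing")) ln1(gfx, "Geometry") else gfx
    bb <- if (!inherits(geo, "xml_missing"))
      bbox(as.numeric(xml2::xml_attr(geo, "x")),
           as.numeric(xml2::xml_attr(geo, "y")),
           as.numeric(xml2::xml_attr(geo, "width")),
           as.numeric(xml2::xml_attr(geo, "height")))
    else bbox(0, 0, 1, 1)
    lab <- if (!inherits(gfx, "xml_missing")) ln1(gfx, "NodeLabel") else gfx
    label <- if (inherits(lab, "xml_missing")) NA_character_ else
      xml2::xml_text(lab)
    props <- if (!inherits(gfx, "xml_missing"))
      lnAll(gfx, "StyleProperties/Property") else xml2::xml_find_all(nd, "nothing")
    pv <- structure(xml2::xml_attr(props, "value"),
                    names = xml2::xml_attr(props, "name"))
    fill <- if (!inherits(gfx, "xml_missing")) {
      f <- ln1(gfx, "Fill")
      if (inherits(f, "xml_missing")) NA_character_ else
        xml2::xml_attr(f, "color")
    } else NA_character_
    border <- if (!inherits(gfx, "xml_missing")) {
      b <- ln1(gfx, "BorderStyle")
      if (inherits(b, "xml_missing")) NA_character_ else
        xml2::xml_attr(b, "color")
    } else NA_character_
    getp <- function(k) if (k %in% names(pv)) pv[[k]] else NA
    auxRefs <- character()
    if (!is.na(auxKey)) {
      dn <- xml2::xml_find_first(
        nd, sprintf("./*[local-name()='data'][@key='%s']", auxKey))
      if (!inherits(dn, "xml_missing")) {
        txt <- trimws(xml2::xml_text(dn))
        if (nzchar(txt)) auxRefs <- strsplit(txt, "\\s+")[[1]]
      }
    }
    yedNode(id, configuration = conf, bbox = bb, label = label,
            isGroup = isGroup, parentGroup = parentGroup, auxRefs = auxRefs,
            style = makeStyle(mcount = getp(d$mcountKey),
                              inverse = getp(d$inverseKey),
                              clone = getp(d$cloneKey),
                              cloneLabel = getp(d$cloneLabelKey),
                              fill = fill, border = border))
  })
  edgeEls <- xml2::xml_find_all(doc, ".//edge")
  edges <- lapply(edgeEls, function(ed) {
    gfx <- xml2::xml_find_first(
      ed, paste0("./*[local-name()='data']/*[local-name()='PolyLineEdge'",
                 " or local-name()='GenericEdge']"))
    bends <- NULL
    sArrow <- tArrow <- "none"
    colour <- NA_character_
    label <- NA_character_
    if (!inherits(gfx, "xml_missing")) {
      pts <- lnAll(gfx, "Path/Point")
      if (length(pts))
        bends <- cbind(x = as.numeric(xml2::xml_attr(pts, "x")),
                       y = as.numeric(xml2::xml_attr(pts, "y")))
      ar <- ln1(gfx, "Arrows")
      if (!inherits(ar, "xml_missing")) {
        sArrow <- xml2::xml_attr(ar, "source", default = "none")
        tArrow <- xml2::xml_attr(ar, "target", default = "none")
      }
      ls <- ln1(gfx, "LineStyle")
      if (!inherits(ls, "xml_missing")) colour <- xml2::xml_attr(ls, "color")
      lb <- ln1(gfx, "EdgeLabel")
      if (!inherits(lb, "xml_missing")) label <- xml2::xml_text(lb)
    }
    yedEdge(xml2::xml_attr(ed, "id"), xml2::xml_attr(ed, "source"),
            xml2::xml_attr(ed, "target"), sourceArrow = sArrow,
            targetArrow = tArrow, bends = bends, label = label,
            colour = colour)
  })
  yedGraph(nodes, edges)
}
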