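# yEd GraphML object model: SBGN palette configurations, arrow vocabulary,
# node/edge constructors, classification back to SBGN classes.

# Table of direct glyph-class <-> palette-configuration pairs. Classes with
# indirect encodings (compartment = group node, omitted/uncertain process =
# Process + label, operators = Operator + label, tag orientation = inverse
# attribute) are handled in code.
.CONF <- c(
  "complex"               = "com.yworks.sbgn.Complex",
  "macromolecule"         = "com.yworks.sbgn.Macromolecule",
  "nucleic acid feature"  = "com.yworks.sbgn.NucleicAcidFeature",
  "simple chemical"       = "com.yworks.sbgn.SimpleChemical",
  "unspecified entity"    = "com.yworks.sbgn.UnspecifiedEntity",
  "perturbing agent"      = "com.yworks.sbgn.PerturbingAgent",
  "phenotype"             = "com.yworks.sbgn.Phenotype",
  "source and sink"       = "com.yworks.sbgn.EmptySet",
  "process"               = "com.yworks.sbgn.Process",
  "submap"                = "com.yworks.sbgn.Submap",
  "tag"                   = "com.yworks.sbgn.Tag",
  "state variable"        = "com.yworks.sbgn.StateVariable",
  "unit of information"   = "com.yworks.sbgn.UnitOfInformation"
)

# arrowhead pair (source, target) per arc class; the token spellings are the
# frozen dialect of this package's GraphML emitter (see graphmlDialect()).
.ARROWS <- list(
  "consumption"           = c(source = "none", target = "none"),
  "production"            = c(source = "none", target = "standard"),
  "catalysis"             = c(source = "none", target = "circle"),
  "stimulation"           = c(source = "none", target = "white_delta"),
  "inhibition"            = c(source = "none", target = "t_shape"),
  "modulation"            = c(source = "none", target = "white_diamond"),
  "necessary stimulation" = c(source = "none", target = "white_delta_bar")
)

# style-attribute keys (yFiles ones per the palette; clone keys are
# converter-owned, see graphmlDialect())
.MCOUNT_KEY <- "com.yworks.sbgn.style.mcount"
.INVERSE_KEY <- "com.yworks.sbgn.style.inverse"
.CLONE_KEY <- "com.ysbgn.style.clone"
.CLONE_LABEL_KEY <- "com.ysbgn.style.cloneLabel"

#' The frozen GraphML dialect
#'
#' One place holding every vocabulary string the GraphML reader and writer
#' agree on: XML namespaces, \code{<key>} declarations, the SBGN palette
#' configuration strings, the arrowhead tokens per arc class, and the
#' converter-owned style-property names (clone marker, clone label) and data
#' key (auxiliary-unit references). Arrow token spellings vary across yEd
#' releases; adjusting them for another release means editing only this
#' table.
#'
#' @return named list of dialect constants.
#' @export
graphmlDialect <- function() {
  list(
    graphmlNs = "http://graphml.graphdrawing.org/xmlns",
    yfilesNs = "http://www.yworks.com/xml/graphml",
    keys = c(nodegraphics = "d0", edgegraphics = "d1", auxRefs = "d2"),
    configurations = .CONF,
    groupConfiguration = "y:GroupNode",
    arrows = .ARROWS,
    mcountKey = .MCOUNT_KEY,
    inverseKey = .INVERSE_KEY,
    cloneKey = .CLONE_KEY,
    cloneLabelKey = .CLONE_LABEL_KEY,
    omittedLabel = "\\\\",
    uncertainLabel = "?"
  )
}

#' yEd node record constructor
#'
#' @param id unique node id.
#' @param configuration yEd SBGN palette configuration string (e.g.
#'   \code{"com.yworks.sbgn.Macromolecule"}); ignored when
#'   \code{isGroup = TRUE} (group nodes encode compartments).
#' @param bbox geometry, from [bbox()].
#' @param label optional node label.
#' @param isGroup logical; compartments are group nodes.
#' @param parentGroup optional id of the enclosing group node.
#' @param auxRefs character vector of node ids of auxiliary-unit nodes
#'   (state variables / units of information) decorating this node.
#' @param style named character vector of style attributes: the palette's
#'   \code{com.yworks.sbgn.style.mcount} and \code{com.yworks.sbgn.style.inverse},
#'   the converter-owned clone keys, and \code{fill} / \code{border} colours.
#' @return node record (named list).
#' @export
yedNode <- function(id, configuration = NA_character_, bbox, label = NA_character_,
                    isGroup = FALSE, parentGroup = NA_character_,
                    auxRefs = character(), style = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!isTRUE(isGroup)) {
    if (is.na(configuration))
      stop("non-group nodes need a palette configuration")
  } else {
    configuration <- "y:GroupNode"
  }
  mc <- style[.MCOUNT_KEY]
  if (!is.na(mc) && as.integer(mc) < 2L)
    stop("mcount must be >= 2")
  list(id = id, configuration = as.character(configuration),
       isGroup = isTRUE(isGroup), bbox = bbox, label = as.character(label),
       parentGroup = as.character(parentGroup),
       auxRefs = as.character(auxRefs), style = style)
}

#' yEd edge record constructor
#'
#' @param id unique edge id.
#' @param source,target node ids.
#' @param sourceArrow,targetArrow arrowhead tokens (see [graphmlDialect()]).
#' @param bends optional matrix of bend points (columns x, y).
#' @param label optional edge label.
#' @param colour optional line colour.
#' @return edge record (named list).
#' @export
yedEdge <- function(id, source, target, sourceArrow = "none",
                    targetArrow = "none", bends = NULL,
                    label = NA_character_, colour = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(bends)) bends <- matrix(numeric(), ncol = 2L,
                                      dimnames = list(NULL, c("x", "y")))
  bends <- matrix(canonNum(bends), ncol = 2L,
                  dimnames = list(NULL, c("x", "y")))
  list(id = id, source = as.character(source), target = as.character(target),
       sourceArrow = as.character(sourceArrow),
       targetArrow = as.character(targetArrow), bends = bends,
       label = as.character(label), colour = as.character(colour))
}

#' Assemble a YedGraph
#'
#' As in [pdMap()], container order is canonical (ids sorted bytewise):
#' GraphML nests group members inside their group, so document order cannot
#' carry information anyway.
#'
#' @param nodes list of node records.
#' @param edges list of edge records.
#' @return a [YedGraph].
#' @export
yedGraph <- function(nodes = list(), edges = list()) {
  names(nodes) <- vapply(nodes, function(n) n$id, character(1))
  names(edges) <- vapply(edges, function(e) e$id, character(1))
  nodes <- nodes[order(names(nodes), method = "radix")]
  edges <- edges[order(names(edges), method = "radix")]
  new("YedGraph", nodes = nodes, edges = edges)
}

classificationError <- function(message, element = NA_character_) {
  structure(class = c("sbgnyedClassificationError", "error", "condition"),
            list(message = message, call = sys.call(-1), element = element))
}

#' Classify a yEd node back to its SBGN glyph class
#'
#' Inverts the palette mapping: group nodes are compartments; a
#' \code{com.yworks.sbgn.Process} node is disambiguated by its label (a
#' double-backslash label means omitted process, \code{"?"} means uncertain
#' process); a \code{com.yworks.sbgn.Operator} node reads the operator kind
#' (AND/OR/NOT) from its label; every other configuration maps directly.
#' Multimer variants keep the base class — the cardinality travels in the
#' \code{mcount} style attribute — and a tag node's left/right orientation
#' travels in the \code{inverse} style attribute, both read by [yedToSbgn()].
#'
#' @param node a node record from [yedNode()] or [readGraphml()].
#' @return a glyph class string (see [glyphClasses()]).
#' @examples
#' n <- yedNode("n1", "com.yworks.sbgn.SimpleChemical", bbox(0, 0, 40, 40))
#' nodeClassOf(n)
#' @export
nodeClassOf <- function(node) {
  if (isTRUE(node$isGroup)) return("compartment")
  conf <- node$configuration
  if (identical(conf, "com.yworks.sbgn.Process")) {
    lab <- node$label
    if (!is.na(lab) && lab == graphmlDialect()$omittedLabel)
      return("omitted process")
    if (!is.na(lab) && lab == "?") return("uncertain process")
    return("process")
  }
  if (identical(conf, "com.yworks.sbgn.Operator")) {
    lab <- toupper(trimws(ifelse(is.na(node$label), "", node$label)))
    if (lab %in% c("AND", "OR", "NOT")) return(tolower(lab))
    stop(classificationError(
      sprintf("operator node '%s' has unrecognised label '%s'",
              node$id, lab), node$id))
  }
  hit <- names(.CONF)[match(conf, .CONF)]
  if (is.na(hit))
    stop(classificationError(
      sprintf("node '%s' has unrecognised configuration '%s'",
              node$id, conf), node$id))
  hit
}

#' Classify a yEd edge back to its SBGN arc class
#'
#' Inverts the arrowhead bijection: a plain line is consumption, a regular
#' arrow production, an empty circle catalysis, an empty triangle stimulation,
#' a T-shape inhibition, an empty diamond modulation, and an empty triangle
#' with a bar necessary stimulation.
#'
#' @param edge an edge record from [yedEdge()] or [readGraphml()].
#' @return an arc class string (see [arcClasses()]).
#' @export
edgeClassOf <- function(edge) {
  for (cls in names(.ARROWS)) {
    a <- .ARROWS[[cls]]
    if (identical(unname(a[["source"]]), edge$sourceArrow) &&
        identical(unname(a[["target"]]), edge$targetArrow))
      return(cls)
  }
  stop(classificationError(
    sprintf("edge '%s' has unrecognised arrow pair (%s, %s)",
            edge$id, edge$sourceArrow, edge$targetArrow), edge$id))
}

# tag orientation from the inverse style attribute
tagOrientationOf <- function(node) {
  inv <- node$style[.INVERSE_KEY]
  if (!is.na(inv) && tolower(inv) %in% c("true", "1")) "right" else "left"
}
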