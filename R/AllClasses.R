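#' @import methods
NULL

#' In-memory SBGN Process Description map
#'
#' A \code{PDMap} holds the glyphs and arcs of one SBGN-ML Process Description
#' document. Glyphs and arcs are stored as named lists of records built by
#' [pdGlyph()] and [pdArc()]; names are the element ids. Containment
#' (compartments, complexes, auxiliary units) is expressed through the
#' \code{compartmentRef} and \code{parent} fields of the glyph records, so the
#' glyph table is flat regardless of nesting depth in the XML.
#'
#' Structural integrity (names match ids, ids unique) is enforced by the S4
#' validity method; the full Process Description rules (port typing, port
#' occupancy, reference resolution, geometry) are checked by [validatePD()],
#' which returns violations as data rather than failing.
#'
#' @slot glyphs named list of glyph records (see [pdGlyph()]).
#' @slot arcs named list of arc records (see [pdArc()]).
#'
#' @seealso [pdMap()], [validatePD()], [readSbgnMl()], [sbgnToYed()]
#' @export
setClass("PDMap", representation(glyphs = "list", arcs = "list"))

setValidity("PDMap", function(object) {
  msgs <- character()
  gl <- object@glyphs
  ar <- object@arcs
  if (length(gl) && (is.null(names(gl)) || any(!nzchar(names(gl)))))
    msgs <- c(msgs, "glyphs must be a named list")
  if (length(ar) && (is.null(names(ar)) || any(!nzchar(names(ar)))))
    msgs <- c(msgs, "arcs must be a named list")
  gid <- vapply(gl, function(g) g$id, character(1), USE.NAMES = FALSE)
  aid <- vapply(ar, function(a) a$id, character(1), USE.NAMES = FALSE)
  if (length(gl) && !identical(unname(names(gl)), gid))
    msgs <- c(msgs, "glyph list names must equal glyph ids")
  if (length(ar) && !identical(unname(names(ar)), aid))
    msgs <- c(msgs, "arc list names must equal arc ids")
  if (anyDuplicated(c(gid, aid)))
    msgs <- c(msgs, "glyph/arc ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' In-memory yEd-flavoured GraphML document
#'
#' A \code{YedGraph} holds the nodes and edges of one GraphML document
#' restricted to the yEd SBGN palette vocabulary: generic nodes carrying a
#' \code{com.yworks.sbgn.*} configuration string, group nodes (compartments),
#' and polyline edges whose arrowhead pair encodes the SBGN arc class.
#' Records are built by [yedNode()] and [yedEdge()].
#'
#' @slot nodes named list of node records.
#' @slot edges named list of edge records.
#'
#' @seealso [yedGraph()], [readGraphml()], [yedToSbgn()]
#' @export
setClass("YedGraph", representation(nodes = "list", edges = "list"))

setValidity("YedGraph", function(object) {
  msgs <- character()
  nid <- vapply(object@nodes, function(n) n$id, character(1), USE.NAMES = FALSE)
  eid <- vapply(object@edges, function(e) e$id, character(1), USE.NAMES = FALSE)
  if (length(object@nodes) && !identical(unname(names(object@nodes)), nid))
    msgs <- c(msgs, "node list names must equal node ids")
  if (length(object@edges) && !identical(unname(names(object@edges)), eid))
    msgs <- c(msgs, "edge list names must equal edge ids")
  if (anyDuplicated(nid)) msgs <- c(msgs, "node ids must be unique")
  if (anyDuplicated(eid)) msgs <- c(msgs, "edge ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Structured conversion log
#'
#' Every conversion returns a \code{ConversionReport} alongside its output.
#' The report records, one row per event: palette degradations (association /
#' dissociation shown as plain processes, up/down tags re-oriented left),
#' port-assignment repairs, orphan auxiliary units, classification failures,
#' and direction normalisations. Severities follow a three-level scheme:
#' \code{notification} (a change the converter made by design),
#' \code{warning} (input repaired or information dropped), and
#' \code{error} (an element that could not be converted; conversion of the
#' remaining elements continues).
#'
#' @slot records data.frame with columns \code{severity}, \code{rule},
#'   \code{element}, \code{message}.
#' @export
setClass("ConversionReport", representation(records = "data.frame"))

setValidity("ConversionReport", function(object) {
  need <- c("severity", "rule", "element", "message")
  if (!all(need %in% names(object@records)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  bad <- setdiff(unique(object@records$severity),
                 c("notification", "warning", "error"))
  if (length(bad))
    return(sprintf("unknown severity: %s", paste(bad, collapse = ", ")))
  TRUE
})

#' @describeIn PDMap number of glyphs
#' @param x,object a \code{PDMap}
#' @export
setMethod("length", "PDMap", function(x) length(x@glyphs))

setMethod("show", "PDMap", function(object) {
  cls <- vapply(object@glyphs, function(g) g$cls, character(1))
  nproc <- sum(cls %in% processClasses())
  cat(sprintf("PDMap: %d glyphs (%d processes), %d arcs\n",
              length(object@glyphs), nproc, length(object@arcs)))
  if (length(cls)) {
    tab <- sort(table(cls), decreasing = TRUE)
    cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
        "\n")
  }
})

setMethod("show", "YedGraph", function(object) {
  ng <- sum(vapply(object@nodes, function(n) isTRUE(n$isGroup), logical(1)))
  cat(sprintf("YedGraph: %d nodes (%d groups), %d edges\n",
              length(object@nodes), ng, length(object@edges)))
})

setMethod("show", "ConversionReport", function(object) {
  r <- object@records
  cat(sprintf("ConversionReport: %d notifications, %d warnings, %d errors\n",
              sum(r$severity == "notification"),
              sum(r$severity == "warning"),
              sum(r$severity == "error")))
  if (nrow(r)) {
    tab <- sort(table(r$rule), decreasing = TRUE)
    cat("  rules:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
        "\n")
  }
})

#' @rdname accessors
#' @export
setGeneric("glyphs", function(x) standardGeneric("glyphs"))
#' @rdname accessors
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))
#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("reportRecords", function(x) standardGeneric("reportRecords"))

#' Accessors for converter containers
#'
#' Accessor functions for the element tables of [PDMap], [YedGraph] and
#' [ConversionReport] objects; user code should use these instead of reaching
#' into slots.
#'
#' @param x a \code{PDMap}, \code{YedGraph} or \code{ConversionReport}.
#' @return \code{glyphs}/\code{arcs}/\code{nodes}/\code{edges}: named list of
#'   element records. \code{reportRecords}: a data.frame of log rows.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("glyphs", "PDMap", function(x) x@glyphs)
#' @rdname accessors
#' @export
setMethod("arcs", "PDMap", function(x) x@arcs)
#' @rdname accessors
#' @export
setMethod("nodes", "YedGraph", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("edges", "YedGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("reportRecords", "ConversionReport", function(x) x@records)
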