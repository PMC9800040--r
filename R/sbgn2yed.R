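# Forward converter: PDMap -> YedGraph.
#
# Every glyph becomes one node (compartments become group nodes, auxiliary
# units become satellite nodes referenced from their carrier), every arc one
# edge. Process ports have no native yEd shape, so arcs keep their visual
# convergence on the antenna tips through an extra bend point at the port
# position, while the edge endpoint connects to the process box itself.
# Palette gaps degrade with a logged notification: association/dissociation
# become plain processes, up/down tags become left tags.

DEFAULT_ANTENNA <- 10

# port positions on the side midpoints, offset outward along the
# orientation axis
portPositions <- function(b, orientation, antenna = DEFAULT_ANTENNA) {
  cx <- b[["x"]] + b[["w"]] / 2
  cy <- b[["y"]] + b[["h"]] / 2
  if (identical(orientation, "vertical")) {
    rbind(p1 = c(x = cx, y = b[["y"]] - antenna),
          p2 = c(x = cx, y = b[["y"]] + b[["h"]] + antenna))
  } else {
    rbind(p1 = c(x = b[["x"]] - antenna, y = cy),
          p2 = c(x = b[["x"]] + b[["w"]] + antenna, y = cy))
  }
}

#' Map one glyph to a yEd node
#'
#' Applies the palette mapping for a single non-auxiliary glyph: geometry and
#' label are copied, multimer cardinality becomes the \code{mcount} style
#' attribute, omitted/uncertain processes become a Process node labelled with
#' a double backslash or \code{"?"}, operators become an Operator node
#' labelled AND/OR/NOT, and clone flag plus fill/stroke colours travel as
#' style attributes. Association and dissociation have no palette shape and
#' degrade to a plain Process node; up/down tags degrade to left tags; both
#' degradations are returned so the caller can log them.
#'
#' @param g a glyph record ([pdGlyph()]); passing a state variable or unit of
#'   information is a contract error (those are emitted by the auxiliary-unit
#'   pass of [sbgnToYed()]).
#' @param parentGroup id of the enclosing group node, if any.
#' @return list with elements \code{node} (a [yedNode()] record) and
#'   \code{degradation} (\code{NULL}, or a list with \code{rule} and
#'   \code{message}).
#' @export
mapGlyph <- function(g, parentGroup = NA_character_) {
  if (g$cls %in% auxUnitClasses())
    stop("auxiliary-unit glyphs are mapped by the attach pass, not mapGlyph")
  d <- graphmlDialect()
  degradation <- NULL
  label <- g$label
  isGroup <- FALSE
  inverse <- NA
  conf <- d$configurations[g$cls]
  if (g$cls == "compartment") {
    isGroup <- TRUE
    conf <- d$groupConfiguration
  } else if (g$cls %in% c("and", "or", "not")) {
    conf <- "com.yworks.sbgn.Operator"
    label <- toupper(g$cls)
  } else if (g$cls == "omitted process") {
    conf <- d$configurations[["process"]]
    label <- d$omittedLabel
  } else if (g$cls == "uncertain process") {
    conf <- d$configurations[["process"]]
    label <- d$uncertainLabel
  } else if (g$cls %in% c("association", "dissociation")) {
    conf <- d$configurations[["process"]]
    degradation <- list(
      rule = if (g$cls == "association") "assoc_to_process" else
        "dissoc_to_process",
      message = sprintf("%s '%s' has no yEd palette shape; shown as a generic process",
                        g$cls, g$id))
  } else if (g$cls == "tag") {
    ori <- g$orientation
    if (!is.na(ori) && ori == "right") {
      inverse <- "true"
    } else if (!is.na(ori) && ori %in% c("up", "down")) {
      degradation <- list(
        rule = "updown_tag_to_left",
        message = sprintf("%s-oriented tag '%s' has no yEd palette shape; shown left-oriented",
                          ori, g$id))
    }
  }
  if (is.na(conf)) conf <- "unknown"
  node <- yedNode(g$id, configuration = unname(conf), bbox = g$bbox,
                  label = label, isGroup = isGroup, parentGroup = parentGroup,
                  style = makeStyle(
                    mcount = if (is.na(g$multimer)) NA else g$multimer,
                    inverse = inverse,
                    clone = if (isTRUE(g$clone)) "true" else NA,
                    cloneLabel = g$cloneLabel,
                    fill = unname(g$extension["fill"]),
                    border = unname(g$extension["stroke"])))
  list(node = node, degradation = degradation)
}

#' Map one arc to a yEd edge
#'
#' Applies the arrowhead bijection and collapses port endpoints onto the
#' owning process node; existing bend points are copied unchanged (the port
#' bend is added separately, see [renderPorts()]).
#'
#' @param a an arc record ([pdArc()]).
#' @param map the [PDMap] the arc belongs to (for port ownership).
#' @return a [yedEdge()] record.
#' @export
mapArc <- function(a, map) {
  d <- graphmlDialect()
  arrows <- d$arrows[[a$cls]]
  pidx <- portIndex(map)
  src <- a$source
  tgt <- a$target
  i <- match(src, pidx$port)
  if (!is.na(i)) src <- pidx$owner[i]
  j <- match(tgt, pidx$port)
  if (!is.na(j)) tgt <- pidx$owner[j]
  yedEdge(a$id, src, tgt, sourceArrow = unname(arrows[["source"]]),
          targetArrow = unname(arrows[["target"]]), bends = a$bends,
          colour = unname(a$extension["stroke"]))
}

#' Bend-point edits that visualise process ports
#'
#' yEd has no port shape, so each arc attached to a port gains one extra bend
#' at the port position: a first bend when the port is on the arc's source
#' side, a last bend otherwise. All edges of one port then visually converge
#' on the antenna tip while connecting to the process box itself. Existing
#' bends are preserved; the port bend is prepended or appended.
#'
#' @param process a process-family glyph record carrying 2 ports.
#' @param incident list of arc records incident to the process.
#' @return list of edits, each \code{list(arc, where, point)} with
#'   \code{where} \code{"prepend"} or \code{"append"}.
#' @export
renderPorts <- function(process, incident) {
  pid <- vapply(process$ports, `[[`, character(1), "id")
  px <- vapply(process$ports, `[[`, numeric(1), "x")
  py <- vapply(process$ports, `[[`, numeric(1), "y")
  edits <- list()
  for (a in incident) {
    i <- match(a$source, pid)
    if (!is.na(i))
      edits[[length(edits) + 1L]] <-
        list(arc = a$id, where = "prepend", point = c(x = px[i], y = py[i]))
    j <- match(a$target, pid)
    if (!is.na(j))
      edits[[length(edits) + 1L]] <-
        list(arc = a$id, where = "append", point = c(x = px[j], y = py[j]))
  }
  edits
}

#' Convert a Process Description map to a yEd graph
#'
#' The forward direction: one node per glyph (compartments as group nodes,
#' auxiliary units as satellite nodes referenced through the carrier's
#' \code{auxRefs}), one edge per arc with port endpoints collapsed onto the
#' process node and the port position preserved as an extra bend point.
#' Colours and annotations are carried into style attributes. Conversion
#' never aborts on a single bad element: per-element problems are collected
#' in the report.
#'
#' @param map a [PDMap].
#' @param antenna antenna length in canvas units, used only to synthesise
#'   positions for ports stored without coordinates.
#' @param strict if \code{TRUE}, stop when [validatePD()] finds violations;
#'   default warns into the report and continues.
#' @return list with elements \code{graph} (a [YedGraph]) and \code{report}
#'   (a [ConversionReport]).
#' @export
sbgnToYed <- function(map, antenna = DEFAULT_ANTENNA, strict = FALSE) {
  stopifnot(is(map, "PDMap"))
  rep <- newReporter()
  v <- validatePD(map)
  if (nrow(v)) {
    if (strict)
      stop(sprintf("map has %d validation violation(s)", nrow(v)),
           call. = FALSE)
    for (i in seq_len(nrow(v)))
      note(rep, "warning", paste0("invalid-input:", v$rule[i]), v$element[i],
           v$message[i])
  }
  gl <- map@glyphs
  gcls <- vapply(gl, function(g) g$cls, character(1))
  gparent <- vapply(gl, function(g) g$parent, character(1))
  gcomp <- vapply(gl, function(g) g$compartmentRef, character(1))
  # effective compartment: complex members inherit their container's
  inherited <- is.na(gcomp) & !is.na(gparent) &
    !gcls %in% auxUnitClasses()
  gcomp[inherited] <- gcomp[gparent[inherited]]

  # synthesise missing port coordinates from orientation
  for (gid in names(gl)[gcls %in% processClasses()]) {
    g <- gl[[gid]]
    if (length(g$ports) == 2L &&
        any(vapply(g$ports, function(p) is.na(p$x) || is.na(p$y),
                   logical(1)))) {
      ori <- if (is.na(g$orientation)) "horizontal" else g$orientation
      pp <- portPositions(g$bbox, ori, antenna)
      for (k in 1:2) {
        gl[[gid]]$ports[[k]]$x <- pp[k, "x"]
        gl[[gid]]$ports[[k]]$y <- pp[k, "y"]
      }
      note(rep, "notification", "port-position-synthesised", gid,
           sprintf("port coordinates synthesised on the %s axis, antenna %g",
                   ori, antenna))
    }
  }
  mapFixed <- pdMap(gl, map@arcs)

  isAux <- gcls %in% auxUnitClasses() & !is.na(gparent)
  auxByParent <- split(names(gl)[isAux], gparent[isAux])

  nodes <- vector("list", length(gl))
  for (i in seq_along(gl)) {
    g <- gl[[i]]
    if (isAux[i]) {
      label <- if (g$cls == "state variable") {
        if (!is.na(g$stateVariable))
          paste0(ifelse(is.na(g$stateValue), "", g$stateValue), "@",
                 g$stateVariable)
        else g$stateValue
      } else g$label
      nodes[[i]] <- yedNode(g$id,
                            configuration = unname(graphmlDialect()$configurations[g$cls]),
                            bbox = g$bbox, label = label,
                            style = makeStyle(fill = unname(g$extension["fill"]),
                                              border = unname(g$extension["stroke"])))
    } else {
      m <- mapGlyph(g, parentGroup = gcomp[i])
      nd <- m$node
      refs <- auxByParent[[g$id]]
      if (!is.null(refs)) nd$auxRefs <- refs
      nodes[[i]] <- nd
      if (!is.null(m$degradation))
        note(rep, "notification", m$degradation$rule, g$id,
             m$degradation$message)
    }
  }

  # arcs: vectorised port collapse + port bend injection
  pidx <- portIndex(mapFixed)
  ar <- mapFixed@arcs
  edges <- vector("list", length(ar))
  if (length(ar)) {
    src <- vapply(ar, function(a) a$source, character(1), USE.NAMES = FALSE)
    tgt <- vapply(ar, function(a) a$target, character(1), USE.NAMES = FALSE)
    si <- match(src, pidx$port)
    ti <- match(tgt, pidx$port)
    d <- graphmlDialect()
    for (i in seq_along(ar)) {
      a <- ar[[i]]
      bends <- a$bends
      s <- src[i]
      t <- tgt[i]
      if (!is.na(si[i])) {
        s <- pidx$owner[si[i]]
        bends <- rbind(c(pidx$x[si[i]], pidx$y[si[i]]), bends)
      }
      if (!is.na(ti[i])) {
        t <- pidx$owner[ti[i]]
        bends <- rbind(bends, c(pidx$x[ti[i]], pidx$y[ti[i]]))
      }
      arrows <- d$arrows[[a$cls]]
      edges[[i]] <- yedEdge(a$id, s, t,
                            sourceArrow = unname(arrows[["source"]]),
                            targetArrow = unname(arrows[["target"]]),
                            bends = bends,
                            colour = unname(a$extension["stroke"]))
    }
  }
  list(graph = yedGraph(nodes, edges), report = freezeReport(rep))
}
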