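# Reverse converter: YedGraph -> PDMap.
#
# yEd draws arcs straight onto the process box, so the Process Description
# port structure has to be reconstructed. For every process the converter:
# (1) classifies reversibility from the incident flux arcs (irreversible =
# consumption and production both present; reversible = all production),
# (2) computes each arc's anchor (the bend point adjacent to the process if
# any, else the far endpoint's box centre) and its side of the process,
# (3) infers the orientation from the side majority (ties: horizontal, the
# initial assumption), places the two ports on the side midpoints offset by
# the antenna length, and
# (4) assigns arcs to ports: by arc type for irreversible processes (the
# consumption port picked by side majority), by Euclidean nearest-port
# distance for reversible ones, with a single farthest-arc repair whenever
# one port would end up empty.
# Modulation-family arcs never attach to ports; they stay on the glyph body.

#' Classify a process as reversible or irreversible
#'
#' A process is irreversible when at least one incident flux arc is a
#' consumption and another a production; it is reversible when all flux arcs
#' share one type (the drawing convention uses production on both sides).
#' Modulation-family arcs (catalysis, stimulation, inhibition, modulation,
#' necessary stimulation) are ignored: they attach to the process body, not
#' to ports.
#'
#' @param arcs list of arc/edge records, or a character vector of arc
#'   classes.
#' @return \code{"reversible"} or \code{"irreversible"}.
#' @examples
#' classifyReversibility(c("consumption", "consumption", "production"))
#' classifyReversibility(c("production", "production"))
#' classifyReversibility(c("production", "catalysis"))
#' @export
classifyReversibility <- function(arcs) {
  cls <- if (is.character(arcs)) arcs else
    vapply(arcs, function(a) a$cls, character(1))
  flux <- cls[cls %in% fluxArcClasses()]
  if (!length(flux)) stop("no flux arcs to classify", call. = FALSE)
  if (any(flux == "consumption") && any(flux == "production"))
    "irreversible"
  else
    "reversible"
}

#' Anchor point and side of an arc relative to a process
#'
#' The arc position is the bend point adjacent to the process end when the
#' edge has bends, otherwise the far endpoint (taken as the centre of the
#' non-process node's box). The side is the axis of largest displacement from
#' the process box centre; ties between |dx| and |dy| go to the horizontal
#' axis (the initial orientation assumption), and an anchor coincident with
#' the centre defaults to the left side.
#'
#' @param bends bend-point matrix of the edge (columns x, y; may have 0
#'   rows).
#' @param processEnd \code{"source"} or \code{"target"}: which edge end
#'   touches the process.
#' @param farPoint centre of the node at the other end, \code{c(x, y)}.
#' @param processBBox the process box ([bbox()]).
#' @param antenna antenna length for the candidate port positions.
#' @return list with \code{point} (the anchor), \code{side}
#'   (left/right/top/bottom), and \code{distLeft}/\code{distRight}: Euclidean
#'   distances from the anchor to the two horizontal-assumption port
#'   candidates.
#' @export
arcAnchor <- function(bends, processEnd, farPoint, processBBox,
                      antenna = DEFAULT_ANTENNA) {
  pt <- if (nrow(bends)) {
    if (identical(processEnd, "source")) bends[1L, ] else
      bends[nrow(bends), ]
  } else as.numeric(farPoint)
  ctr <- bboxCenter(processBBox)
  dx <- pt[[1]] - ctr[["x"]]
  dy <- pt[[2]] - ctr[["y"]]
  side <- if (dx == 0 && dy == 0) "left"
  else if (abs(dx) >= abs(dy)) {
    if (dx < 0) "left" else "right"
  } else {
    if (dy < 0) "top" else "bottom"
  }
  pp <- portPositions(processBBox, "horizontal", antenna)
  list(point = c(x = unname(pt[[1]]), y = unname(pt[[2]])), side = side,
       distLeft = sqrt((pt[[1]] - pp["p1", "x"])^2 + (pt[[2]] - pp["p1", "y"])^2),
       distRight = sqrt((pt[[1]] - pp["p2", "x"])^2 + (pt[[2]] - pp["p2", "y"])^2))
}

#' Infer process orientation from arc sides
#'
#' Majority vote over the anchor sides: horizontal when the left+right count
#' is at least the top+bottom count (ties keep the initial horizontal
#' assumption), vertical otherwise.
#'
#' @param sides character vector of sides from [arcAnchor()].
#' @return \code{"horizontal"} or \code{"vertical"}.
#' @examples
#' computeOrientation(c("left", "right", "left"))
#' computeOrientation(c("top", "bottom", "top"))
#' @export
computeOrientation <- function(sides) {
  lr <- sum(sides %in% c("left", "right"))
  tb <- sum(sides %in% c("top", "bottom"))
  if (lr >= tb) "horizontal" else "vertical"
}

#' Port assignment for an irreversible process
#'
#' Consumption arcs go to one port and production arcs to the other, which
#' satisfies the one-type-per-port rule by construction. The physical side of
#' the consumption port is the majority side of the consumption anchors along
#' the orientation axis; ties put consumption on the left (horizontal) or top
#' (vertical) port. Port 1 is always the left/top port.
#'
#' @param arcIds arc ids, in stable order.
#' @param arcCls arc classes, parallel to \code{arcIds} (consumption /
#'   production only).
#' @param anchors numeric matrix of anchor points (columns x, y).
#' @param center process box centre \code{c(x, y)}.
#' @param orientation \code{"horizontal"} or \code{"vertical"}.
#' @return list with \code{port1Arcs}, \code{port2Arcs}, \code{repairs} (0),
#'   and \code{consumptionPort} (1 or 2).
#' @export
assignPortsIrreversible <- function(arcIds, arcCls, anchors, center,
                                    orientation = "horizontal") {
  cons <- arcCls == "consumption"
  coord <- if (orientation == "horizontal") anchors[, 1L] else anchors[, 2L]
  cc <- if (orientation == "horizontal") center[[1]] else center[[2]]
  nearSide1 <- coord[cons] < cc   # left of / above the centre
  consumptionPort <- if (sum(nearSide1) >= sum(!nearSide1)) 1L else 2L
  p1 <- arcIds[if (consumptionPort == 1L) cons else !cons]
  p2 <- arcIds[if (consumptionPort == 1L) !cons else cons]
  list(port1Arcs = p1, port2Arcs = p2, repairs = 0L,
       consumptionPort = consumptionPort)
}

#' Port assignment for a reversible process
#'
#' Each arc is assigned to its Euclidean-nearest port (ties to port 1, the
#' left/top port, in stable arc order). If one port ends up empty — all arcs
#' were closer to the other — the arc farthest from the occupied port is
#' re-assigned to the empty port, so each port keeps at least one arc. The
#' algorithm moves at most one arc (\code{repairs} is 0 or 1).
#'
#' @param arcIds arc ids, in stable order.
#' @param anchors numeric matrix of anchor points (columns x, y).
#' @param portPos 2x2 matrix of port positions, rows \code{p1} and
#'   \code{p2}, columns x and y.
#' @return list with \code{port1Arcs}, \code{port2Arcs}, \code{repairs}, and
#'   \code{moved} (the re-assigned arc id, or \code{NA}).
#' @export
assignPortsReversible <- function(arcIds, anchors, portPos) {
  d1 <- sqrt((anchors[, 1L] - portPos["p1", 1L])^2 +
               (anchors[, 2L] - portPos["p1", 2L])^2)
  d2 <- sqrt((anchors[, 1L] - portPos["p2", 1L])^2 +
               (anchors[, 2L] - portPos["p2", 2L])^2)
  onP1 <- d1 <= d2
  repairs <- 0L
  moved <- NA_character_
  if (length(arcIds) >= 2L) {
    if (all(onP1)) {
      k <- max(which(d1 == max(d1)))   # farthest from the occupied port
      onP1[k] <- FALSE
      repairs <- 1L
      moved <- arcIds[k]
    } else if (all(!onP1)) {
      k <- max(which(d2 == max(d2)))
      onP1[k] <- TRUE
      repairs <- 1L
      moved <- arcIds[k]
    }
  }
  list(port1Arcs = arcIds[onP1], port2Arcs = arcIds[!onP1],
       repairs = repairs, moved = moved)
}

#' Detect clone markers
#'
#' Entity pools drawn more than once in one map (typically ubiquitous
#' metabolites such as ATP) should carry a clone marker in Process
#' Description. Pools are grouped by a composite key — normalised label
#' (case- and whitespace-insensitive), glyph class, multimer cardinality, the
#' multiset of decorating state variables, and (under the default
#' \code{"per-compartment"} policy) the containing compartment, since the
#' same species in two compartments is two distinct pools, not a clone. Every
#' member of a group of size two or more is marked.
#'
#' @param map a [PDMap].
#' @param policy \code{"per-compartment"} (default) or \code{"global"}.
#' @return character vector of glyph ids to mark as clones.
#' @export
detectClones <- function(map, policy = c("per-compartment", "global")) {
  policy <- match.arg(policy)
  gl <- map@glyphs
  cls <- vapply(gl, function(g) g$cls, character(1))
  parent <- vapply(gl, function(g) g$parent, character(1))
  lab <- vapply(gl, function(g) g$label, character(1))
  # state-variable multiset per carrier
  isSv <- cls == "state variable" & !is.na(parent)
  svKey <- character()
  if (any(isSv)) {
    sv <- vapply(which(isSv), function(i) {
      g <- gl[[i]]
      paste0(ifelse(is.na(g$stateValue), "", g$stateValue), "@",
             ifelse(is.na(g$stateVariable), "", g$stateVariable))
    }, character(1))
    svKey <- vapply(split(sv, parent[isSv]), function(z)
      paste(sort(z), collapse = "|"), character(1))
  }
  pool <- cls %in% entityPoolClasses() & is.na(parent) & !is.na(lab) &
    nzchar(lab)
  idxPool <- which(pool)
  if (!length(idxPool)) return(character())
  ids <- names(gl)[idxPool]
  comp <- vapply(gl[idxPool], function(g) g$compartmentRef, character(1))
  mult <- vapply(gl[idxPool], function(g) as.character(g$multimer),
                 character(1))
  svPart <- rep("", length(ids))
  hit <- match(ids, names(svKey))
  svPart[!is.na(hit)] <- svKey[hit[!is.na(hit)]]
  key <- paste(tolower(trimws(lab[idxPool])), cls[idxPool],
               if (policy == "per-compartment") comp else "",
               mult, svPart, sep = "\r")
  counts <- table(key)
  unname(ids[counts[key] >= 2L])
}

rectIntersects <- function(a, b) {
  a[["x"]] < b[["x"]] + b[["w"]] && a[["x"]] + a[["w"]] > b[["x"]] &&
    a[["y"]] < b[["y"]] + b[["h"]] && a[["y"]] + a[["h"]] > b[["y"]]
}

rectContains <- function(outer, inner) {
  inner[["x"]] >= outer[["x"]] && inner[["y"]] >= outer[["y"]] &&
    inner[["x"]] + inner[["w"]] <= outer[["x"]] + outer[["w"]] &&
    inner[["y"]] + inner[["h"]] <= outer[["y"]] + outer[["h"]]
}

rectGrow <- function(b, m) {
  c(x = b[["x"]] - m, y = b[["y"]] - m, w = b[["w"]] + 2 * m,
    h = b[["h"]] + 2 * m)
}

#' Attach auxiliary-unit nodes to their carriers
#'
#' yEd stores state variables and units of information as free-standing
#' nodes referenced by id from the carrying node; SBGN nests them as child
#' glyphs. This pass resolves each auxiliary node to a parent: first through
#' the explicit \code{auxRefs} references, then — for hand-drawn files
#' lacking them — through a geometric fallback that attaches any auxiliary
#' node intersecting a candidate's boundary band (the frame of width
#' \code{2 * margin} around the box border); among several geometric
#' candidates the nearest centre wins. Auxiliary nodes with no parent at all
#' are orphans and stay standalone, with a warning.
#'
#' @param graph a [YedGraph].
#' @param margin half-width of the boundary band, canvas units.
#' @return data.frame with columns \code{aux}, \code{parent} (\code{NA} for
#'   orphans) and \code{method} (\code{"refs"}, \code{"geometry"} or
#'   \code{"orphan"}).
#' @export
attachAuxUnits <- function(graph, margin = 10) {
  nodes <- graph@nodes
  auxConf <- c("com.yworks.sbgn.StateVariable",
               "com.yworks.sbgn.UnitOfInformation")
  isAux <- vapply(nodes, function(n)
    !n$isGroup && n$configuration %in% auxConf, logical(1))
  if (!any(isAux))
    return(data.frame(aux = character(), parent = character(),
                      method = character(), stringsAsFactors = FALSE))
  # explicit references
  refParent <- character()
  for (n in nodes[!isAux]) {
    for (r in n$auxRefs) refParent[r] <- n$id
  }
  auxIds <- names(nodes)[isAux]
  candIds <- names(nodes)[!isAux]
  res <- lapply(auxIds, function(aid) {
    if (aid %in% names(refParent))
      return(list(aux = aid, parent = refParent[[aid]], method = "refs"))
    ab <- nodes[[aid]]$bbox
    hits <- character()
    dists <- numeric()
    ac <- bboxCenter(ab)
    for (cid in candIds) {
      cb <- nodes[[cid]]$bbox
      if (rectIntersects(ab, rectGrow(cb, margin)) &&
          !rectContains(rectGrow(cb, -margin), ab)) {
        cc <- bboxCenter(cb)
        hits <- c(hits, cid)
        dists <- c(dists, sqrt(sum((ac - cc)^2)))
      }
    }
    if (length(hits))
      return(list(aux = aid, parent = hits[which.min(dists)],
                  method = "geometry"))
    list(aux = aid, parent = NA_character_, method = "orphan")
  })
  data.frame(aux = vapply(res, `[[`, character(1), "aux"),
             parent = vapply(res, `[[`, character(1), "parent"),
             method = vapply(res, `[[`, character(1), "method"),
             stringsAsFactors = FALSE)
}

# parse a state-variable node label: "P@Ser15" -> value/variable, bare -> value
parseStateLabel <- function(label) {
  if (is.na(label) || !nzchar(label))
    return(c(value = NA_character_, variable = NA_character_))
  if (grepl("@", label, fixed = TRUE)) {
    parts <- strsplit(label, "@", fixed = TRUE)[[1]]
    c(value = parts[1], variable = if (length(parts) > 1L) parts[2] else
      NA_character_)
  } else c(value = label, variable = NA_character_)
}

#' Convert a yEd graph to a Process Description map
#'
#' The reverse direction, implementing the conversion algorithms that make a
#' hand-drawn yEd diagram a valid Process Description map: node and edge
#' classification back to SBGN classes, compartment reconstruction from
#' group nesting, auxiliary-unit attachment ([attachAuxUnits()]), clone
#' detection ([detectClones()]), and — for every process — reversibility
#' classification, orientation inference and arc-port assignment (see
#' [assignPortsReversible()], [assignPortsIrreversible()]). Per-element
#' problems are recorded in the report and conversion continues; a single
#' unclassifiable element never aborts the run.
#'
#' Processes with fewer than two flux arcs cannot satisfy the rule that both
#' ports carry an arc; they are emitted without ports (arcs attached to the
#' glyph body) and reported.
#'
#' @param graph a [YedGraph].
#' @param antenna antenna length in canvas units for the reconstructed port
#'   positions.
#' @param clonePolicy clone-key policy, see [detectClones()].
#' @param auxMargin boundary-band half-width for the geometric
#'   auxiliary-unit fallback.
#' @return list with elements \code{map} (a [PDMap]) and \code{report}
#'   (a [ConversionReport]).
#' @export
yedToSbgn <- function(graph, antenna = DEFAULT_ANTENNA,
                      clonePolicy = c("per-compartment", "global"),
                      auxMargin = 10) {
  stopifnot(is(graph, "YedGraph"))
  clonePolicy <- match.arg(clonePolicy)
  rep <- newReporter()
  nodes <- graph@nodes
  d <- graphmlDialect()

  att <- attachAuxUnits(graph, margin = auxMargin)
  auxParent <- structure(att$parent, names = att$aux)

  glyphs <- vector("list", length(nodes))
  dropped <- character()
  gi <- 0L
  for (n in nodes) {
    cls <- tryCatch(nodeClassOf(n), error = function(e) {
      note(rep, "error", "unclassifiable-node", n$id, conditionMessage(e))
      NA_character_
    })
    if (is.na(cls)) {
      dropped <- c(dropped, n$id)
      next
    }
    compRef <- NA_character_
    if (!is.na(n$parentGroup)) {
      pg <- nodes[[n$parentGroup]]
      if (!is.null(pg) && pg$isGroup) compRef <- n$parentGroup
    }
    label <- n$label
    orientation <- NA_character_
    stateValue <- stateVariable <- NA_character_
    parent <- NA_character_
    if (cls %in% c("omitted process", "uncertain process", "and", "or",
                   "not"))
      label <- NA_character_
    if (cls == "tag") orientation <- tagOrientationOf(n)
    if (cls == "state variable") {
      st <- parseStateLabel(n$label)
      stateValue <- st[["value"]]
      stateVariable <- st[["variable"]]
      label <- NA_character_
    }
    if (cls %in% auxUnitClasses()) {
      p <- auxParent[n$id]
      if (!is.na(p) && !p %in% dropped) {
        parent <- unname(p)
        compRef <- NA_character_
      } else {
        note(rep, "warning", "orphan-aux-unit", n$id,
             "auxiliary unit has no carrier; emitted standalone")
      }
    }
    mc <- n$style[d$mcountKey]
    clone <- n$style[d$cloneKey]
    gi <- gi + 1L
    glyphs[[gi]] <- pdGlyph(
      n$id, cls, n$bbox, label = label, compartmentRef = compRef,
      parent = parent,
      clone = !is.na(clone) && tolower(clone) %in% c("true", "1"),
      cloneLabel = unname(n$style[d$cloneLabelKey]),
      multimer = if (is.na(mc)) NA_integer_ else as.integer(mc),
      stateValue = stateValue, stateVariable = stateVariable,
      orientation = orientation,
      extension = {
        e <- character()
        if (!is.na(n$style["fill"])) e["fill"] <- n$style[["fill"]]
        if (!is.na(n$style["border"])) e["stroke"] <- n$style[["border"]]
        e
      })
  }

  glyphs <- glyphs[seq_len(gi)]
  names(glyphs) <- vapply(glyphs, function(g) g$id, character(1))

  arcs <- vector("list", length(graph@edges))
  ai <- 0L
  for (e in graph@edges) {
    cls <- tryCatch(edgeClassOf(e), error = function(err) {
      note(rep, "error", "unclassifiable-edge", e$id, conditionMessage(err))
      NA_character_
    })
    if (is.na(cls)) next
    if (e$source %in% dropped || e$target %in% dropped) {
      note(rep, "error", "endpoint-dropped", e$id,
           "edge endpoint could not be converted; edge skipped")
      next
    }
    ext <- character()
    if (!is.na(e$colour)) ext["stroke"] <- e$colour
    ai <- ai + 1L
    arcs[[ai]] <- pdArc(e$id, cls, e$source, e$target, bends = e$bends,
                        extension = ext)
  }
  arcs <- arcs[seq_len(ai)]
  names(arcs) <- vapply(arcs, function(a) a$id, character(1))

  # ---- arc-port assignment ----------------------------------------------
  procIds <- names(glyphs)[vapply(glyphs, function(g)
    g$cls %in% processClasses(), logical(1))]
  if (length(arcs) && length(procIds)) {
    aid <- names(arcs)
    src <- vapply(arcs, function(a) a$source, character(1), USE.NAMES = FALSE)
    tgt <- vapply(arcs, function(a) a$target, character(1), USE.NAMES = FALSE)
    acl <- vapply(arcs, function(a) a$cls, character(1), USE.NAMES = FALSE)
    isFlux <- acl %in% fluxArcClasses()
    srcProc <- src %in% procIds
    tgtProc <- tgt %in% procIds

    # normalise flux direction relative to the process
    for (i in which(isFlux)) {
      swap <- (acl[i] == "consumption" && srcProc[i] && !tgtProc[i]) ||
        (acl[i] == "production" && tgtProc[i] && !srcProc[i])
      if (swap) {
        a <- arcs[[i]]
        s <- a$source
        a$source <- a$target
        a$target <- s
        a$bends <- a$bends[rev(seq_len(nrow(a$bends))), , drop = FALSE]
        arcs[[i]] <- a
        tmp <- src[i]; src[i] <- tgt[i]; tgt[i] <- tmp
        tmp <- srcProc[i]; srcProc[i] <- tgtProc[i]; tgtProc[i] <- tmp
        note(rep, "warning", "arc-direction-normalised", aid[i],
             "endpoints swapped to match PD flux direction")
      }
    }

    # owning process of each flux arc (consumption: target; production:
    # source; fall back to whichever end is a process)
    procOf <- rep(NA_character_, length(arcs))
    for (i in which(isFlux)) {
      if (srcProc[i] && tgtProc[i]) {
        note(rep, "error", "flux-between-processes", aid[i],
             "flux arc connects two processes; left unassigned")
      } else if (acl[i] == "consumption") {
        procOf[i] <- if (tgtProc[i]) tgt[i] else NA_character_
      } else {
        procOf[i] <- if (srcProc[i]) src[i] else NA_character_
      }
    }

    # vectorised anchor ingredients
    ctrs <- t(vapply(glyphs, function(g) bboxCenter(g$bbox), numeric(2)))
    farId <- ifelse(!is.na(procOf) & procOf == src, tgt, src)
    farIdx <- match(farId, names(glyphs))
    byProc <- split(which(!is.na(procOf)), procOf[!is.na(procOf)])
    procPos <- match(names(byProc), names(glyphs))

    for (k in seq_along(byProc)) {
      pid <- names(byProc)[k]
      pj <- procPos[k]
      idx <- byProc[[k]]
      idx <- idx[order(aid[idx])]          # stable arc-id order
      g <- glyphs[[pj]]
      if (length(idx) < 2L) {
        note(rep, "warning", "port-occupancy-unsatisfiable", pid,
             "process has a single flux arc; both-ports-occupied rule cannot hold; emitted without ports")
        next
      }
      anchors <- t(vapply(idx, function(i) {
        a <- arcs[[i]]
        atSource <- identical(a$source, pid)
        if (nrow(a$bends)) {
          if (atSource) a$bends[1L, ] else a$bends[nrow(a$bends), ]
        } else ctrs[farIdx[i], ]
      }, numeric(2)))
      ctr <- bboxCenter(g$bbox)
      dx <- anchors[, 1L] - ctr[["x"]]
      dy <- anchors[, 2L] - ctr[["y"]]
      sides <- ifelse(abs(dx) >= abs(dy),
                      ifelse(dx < 0, "left", "right"),
                      ifelse(dy < 0, "top", "bottom"))
      orientation <- computeOrientation(sides)
      if (orientation == "vertical")
        note(rep, "notification", "orientation-vertical", pid,
             "side majority on top/bottom; ports placed vertically and assignment re-run")
      pp <- portPositions(g$bbox, orientation, antenna)
      kind <- classifyReversibility(acl[idx])
      if (kind == "irreversible") {
        asg <- assignPortsIrreversible(aid[idx], acl[idx], anchors, ctr,
                                       orientation)
      } else {
        if (all(acl[idx] == "consumption"))
          note(rep, "warning", "degenerate-process", pid,
               "all flux arcs are consumptions; assigned by distance as a best effort")
        asg <- assignPortsReversible(aid[idx], anchors, pp)
        if (asg$repairs > 0L)
          note(rep, "notification", "port-repair", asg$moved,
               sprintf("arc re-assigned to the empty port of process '%s'",
                       pid))
      }
      p1 <- pdPort(paste0(pid, ".p1"), pp["p1", "x"], pp["p1", "y"])
      p2 <- pdPort(paste0(pid, ".p2"), pp["p2", "x"], pp["p2", "y"])
      g$ports <- list(p1, p2)
      g$orientation <- orientation
      glyphs[[pj]] <- g
      for (i in idx) {
        port <- if (aid[i] %in% asg$port1Arcs) p1$id else p2$id
        a <- arcs[[i]]
        if (identical(a$source, pid)) a$source <- port else a$target <- port
        arcs[[i]] <- a
      }
    }
  }

  cloneIds <- detectClones(pdMap(glyphs, arcs), clonePolicy)
  newClones <- 0L
  for (j in match(cloneIds, names(glyphs))) {
    if (!glyphs[[j]]$clone) {
      glyphs[[j]]$clone <- TRUE
      newClones <- newClones + 1L
    }
  }
  if (newClones > 0L)
    note(rep, "notification", "clone-detected", NA_character_,
         sprintf("%d entity pools newly marked with clone markers", newClones))
  map <- pdMap(glyphs, arcs)
  # final verification pass: the whole point of the reverse direction is a
  # valid Process Description output, so any residual violation is surfaced
  v <- validatePD(map)
  for (i in seq_len(nrow(v)))
    note(rep, "warning", paste0("output-invalid:", v$rule[i]), v$element[i],
         v$message[i])
  list(map = map, report = freezeReport(rep))
}
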