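# Deterministic synthetic-map generator.
#
# Emulates the shape of a drawn metabolic map — compartments, entity pools
# with clones, multimers and state variables, reversible and irreversible
# processes with their flux and catalysis arcs — on a jittered grid whose
# spacing keeps anchor sides unambiguous. Scaling the counts up reproduces
# genome-scale map sizes. The generator is seeded and platform-deterministic:
# the same spec always serialises to the same bytes.

withFixtureSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Specification for a synthetic map
#'
#' Collects the generator parameters: element counts, the fraction of
#' reversible processes, and the fractions of pools that are cloned, carry a
#' state variable, or are multimers. The defaults describe a small mixed map
#' exercising every conversion path; counts scale to genome-map sizes
#' (thousands of species and processes) without changing anything else.
#'
#' @param nCompartments number of compartments (vertical strips).
#' @param nPools number of entity pools.
#' @param nProcesses number of processes, each with 1-3 consumption plus 1-3
#'   production arcs (irreversible) or 2-4 production arcs (reversible).
#' @param reversibleFraction probability that a process is reversible.
#' @param cloneFraction fraction of pools duplicated as clone pairs.
#' @param auxUnitFraction fraction of pools decorated with a state variable.
#' @param multimerFraction fraction of multimer-capable pools given a
#'   cardinality.
#' @param degradationElements include elements that degrade in the yEd
#'   direction: an association, a dissociation, and up/down tags.
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @param canvas optional canvas [bbox()]; by default sized from the counts.
#' @return a \code{fixtureSpec} list.
#' @export
fixtureSpec <- function(nCompartments = 2, nPools = 12, nProcesses = 6,
                        reversibleFraction = 0.3, cloneFraction = 0.1,
                        auxUnitFraction = 0.2, multimerFraction = 0.1,
                        degradationElements = FALSE, seed = 1L,
                        canvas = NULL) {
  fr <- c(reversibleFraction, cloneFraction, auxUnitFraction,
          multimerFraction)
  stopifnot(all(fr >= 0 & fr <= 1), nCompartments >= 0, nPools >= 0,
            nProcesses >= 0)
  structure(list(nCompartments = as.integer(nCompartments),
                 nPools = as.integer(nPools),
                 nProcesses = as.integer(nProcesses),
                 reversibleFraction = reversibleFraction,
                 cloneFraction = cloneFraction,
                 auxUnitFraction = auxUnitFraction,
                 multimerFraction = multimerFraction,
                 degradationElements = isTRUE(degradationElements),
                 seed = as.integer(seed), canvas = canvas),
            class = "fixtureSpec")
}

POOL_CLASSES <- c("simple chemical", "macromolecule", "nucleic acid feature",
                  "complex", "unspecified entity")
POOL_WEIGHTS <- c(0.45, 0.3, 0.1, 0.1, 0.05)
FILL_PALETTE <- c("#CCFFCC", "#FFE4B5", "#ADD8E6", "#FFCCCC")

#' Generate a synthetic Process Description map
#'
#' Produces a [validatePD()]-clean [PDMap] per the spec: every process has
#' two horizontal ports with consumption arcs entering port 1 and production
#' arcs leaving port 2 (reversible processes carry production arcs on both
#' ports), clone pairs share the full clone-detection key, and geometry lies
#' on a jittered grid (0.1-unit resolution) so that serialisation is exact
#' and anchor sides are unambiguous.
#'
#' @param spec a [fixtureSpec()].
#' @return a [PDMap].
#' @export
generatePD <- function(spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  withFixtureSeed(spec$seed, {
    nClones <- round(spec$cloneFraction * spec$nPools)
    nExtra <- if (spec$degradationElements) 4L else 0L
    total <- spec$nPools + nClones + spec$nProcesses + nExtra
    cols <- max(2L, ceiling(sqrt(total * 1.4)))
    rows <- max(2L, ceiling(total / cols))
    dxc <- 160; dyc <- 120
    canvas <- spec$canvas
    if (is.null(canvas))
      canvas <- bbox(0, 0, cols * dxc + 120, rows * dyc + 120)
    cellIdx <- sample.int(cols * rows)[seq_len(total)]
    jx <- round(stats::runif(total, -15, 15), 1)
    jy <- round(stats::runif(total, -12, 12), 1)
    cellX <- canvas[["x"]] + 90 + ((cellIdx - 1L) %% cols) * dxc + jx
    cellY <- canvas[["y"]] + 80 + ((cellIdx - 1L) %/% cols) * dyc + jy
    nextCell <- 0L
    takeCell <- function() {
      nextCell <<- nextCell + 1L
      c(cellX[nextCell], cellY[nextCell])
    }

    # preallocated collectors (maps can be genome-scale)
    glyphBuf <- vector("list", 2L * total + spec$nCompartments + 4L)
    gN <- 0L
    addGlyph <- function(g) {
      gN <<- gN + 1L
      glyphBuf[[gN]] <<- g
    }
    arcBuf <- vector("list", 8L * (spec$nProcesses + 2L) + 8L)
    aN <- 0L
    addArc <- function(cls, source, target) {
      aN <<- aN + 1L
      arcBuf[[aN]] <<- pdArc(sprintf("a%05d", aN), cls, source, target)
    }

    compIds <- character()
    if (spec$nCompartments > 0) {
      sw <- canvas[["w"]] / spec$nCompartments
      for (k in seq_len(spec$nCompartments)) {
        cid <- sprintf("comp%02d", k)
        compIds <- c(compIds, cid)
        addGlyph(pdGlyph(
          cid, "compartment",
          bbox(round(canvas[["x"]] + (k - 1) * sw + 4, 1), canvas[["y"]] + 4,
               round(sw - 8, 1), canvas[["h"]] - 8),
          label = sprintf("compartment %d", k)))
      }
    }
    compOf <- function(cx) {
      if (!length(compIds)) return(NA_character_)
      k <- min(length(compIds),
               max(1L, 1L + (cx - canvas[["x"]]) %/%
                     (canvas[["w"]] / length(compIds))))
      compIds[k]
    }

    poolIds <- character(spec$nPools)
    poolSlot <- integer(spec$nPools)
    hasAux <- logical(spec$nPools)
    for (i in seq_len(spec$nPools)) {
      pid <- sprintf("pool%04d", i)
      poolIds[i] <- pid
      cls <- sample(POOL_CLASSES, 1L, prob = POOL_WEIGHTS)
      ctr <- takeCell()
      w <- if (cls == "simple chemical") 60 else 90
      b <- bbox(round(ctr[1] - w / 2, 1), round(ctr[2] - 20, 1), w, 40)
      multimer <- if (cls %in% multimerClasses() &&
                      stats::runif(1) < spec$multimerFraction)
        sample(2:4, 1L) else NA_integer_
      ext <- character()
      if (stats::runif(1) < 0.3)
        ext["fill"] <- sample(FILL_PALETTE, 1L)
      addGlyph(pdGlyph(pid, cls, b, label = sprintf("M%04d", i),
                       compartmentRef = compOf(ctr[1]),
                       multimer = multimer, extension = ext))
      poolSlot[i] <- gN
      if (stats::runif(1) < spec$auxUnitFraction) {
        hasAux[i] <- TRUE
        addGlyph(pdGlyph(
          sprintf("%s.sv1", pid), "state variable",
          bbox(round(b[["x"]] + 8, 1), round(b[["y"]] - 8, 1), 24, 16),
          parent = pid, stateValue = sample(c("P", "Ub", "Me"), 1L),
          stateVariable = sample(c("Ser12", "Thr45", "Tyr9"), 1L)))
      }
    }

    if (nClones > 0 && any(!hasAux)) {
      pick <- which(!hasAux)
      pick <- pick[sample.int(length(pick))[seq_len(min(nClones,
                                                        length(pick)))]]
      for (i in pick) {
        orig <- glyphBuf[[poolSlot[i]]]
        orig$clone <- TRUE
        glyphBuf[[poolSlot[i]]] <- orig
        cid <- sprintf("%s.c", orig$id)
        ctr <- takeCell()
        addGlyph(pdGlyph(
          cid, orig$cls,
          bbox(round(ctr[1] - orig$bbox[["w"]] / 2, 1), round(ctr[2] - 20, 1),
               orig$bbox[["w"]], orig$bbox[["h"]]),
          label = orig$label, compartmentRef = orig$compartmentRef,
          clone = TRUE, multimer = orig$multimer,
          extension = orig$extension))
        poolIds <- c(poolIds, cid)
      }
    }

    addProcess <- function(pid, cls) {
      ctr <- takeCell()
      b <- bbox(round(ctr[1] - 12, 1), round(ctr[2] - 12, 1), 24, 24)
      pp <- portPositions(b, "horizontal")
      addGlyph(pdGlyph(
        pid, cls, b, orientation = "horizontal",
        ports = list(pdPort(paste0(pid, ".p1"), pp["p1", "x"], pp["p1", "y"]),
                     pdPort(paste0(pid, ".p2"), pp["p2", "x"],
                            pp["p2", "y"]))))
    }
    connect <- function(pid, nCons, nProd, reversible) {
      if (reversible) {
        k <- nCons + nProd
        onP1 <- ceiling(k / 2)
        partners <- sample(poolIds, k, replace = TRUE)
        for (t in partners[seq_len(onP1)])
          addArc("production", paste0(pid, ".p1"), t)
        for (t in partners[-seq_len(onP1)])
          addArc("production", paste0(pid, ".p2"), t)
      } else {
        for (s in sample(poolIds, nCons, replace = TRUE))
          addArc("consumption", s, paste0(pid, ".p1"))
        for (t in sample(poolIds, nProd, replace = TRUE))
          addArc("production", paste0(pid, ".p2"), t)
      }
      if (stats::runif(1) < 0.25)
        addArc("catalysis", sample(poolIds, 1L), pid)
    }
    if (spec$nProcesses > 0 && length(poolIds)) {
      for (j in seq_len(spec$nProcesses)) {
        pid <- sprintf("proc%04d", j)
        rev <- stats::runif(1) < spec$reversibleFraction
        addProcess(pid, "process")
        if (rev) connect(pid, 1L, sample(1:3, 1L), TRUE)
        else connect(pid, sample(1:3, 1L), sample(1:3, 1L), FALSE)
      }
    }

    if (spec$degradationElements && length(poolIds)) {
      addProcess("assoc01", "association")
      connect("assoc01", 2L, 1L, FALSE)
      addProcess("dissoc01", "dissociation")
      connect("dissoc01", 1L, 2L, FALSE)
      ctr <- takeCell()
      addGlyph(pdGlyph(
        "tagUp01", "tag", bbox(round(ctr[1], 1), round(ctr[2], 1), 60, 30),
        label = "to mito", orientation = "up"))
      addGlyph(pdGlyph(
        "tagDown01", "tag",
        bbox(round(ctr[1] + 70, 1), round(ctr[2], 1), 60, 30),
        label = "from ER", orientation = "down"))
    }
    pdMap(glyphBuf[seq_len(gN)], arcBuf[seq_len(aN)])
  })
}

#' Generate a synthetic yEd graph
#'
#' The same synthetic map as [generatePD()], expressed in yEd vocabulary
#' \emph{without} ports: edges attach straight to the process boxes, so
#' converting the result back genuinely exercises the reverse converter's
#' reversibility, anchor and port-assignment algorithms. Edges of every
#' third process additionally lose their bend points, exercising the
#' far-endpoint anchor path.
#'
#' @param spec a [fixtureSpec()].
#' @return a [YedGraph].
#' @export
generateYed <- function(spec) {
  m <- generatePD(spec)
  g <- sbgnToYed(m)$graph
  procIds <- names(m@glyphs)[vapply(m@glyphs, function(x)
    x$cls %in% processClasses(), logical(1))]
  strip <- procIds[seq_along(procIds) %% 3L == 0L]
  if (length(strip)) {
    for (i in seq_along(g@edges)) {
      e <- g@edges[[i]]
      if ((e$source %in% strip || e$target %in% strip) && nrow(e$bends)) {
        e$bends <- e$bends[0L, , drop = FALSE]
        g@edges[[i]] <- e
      }
    }
  }
  g
}

#' The three canonical process scenarios
#'
#' Small hand-laid yEd graphs of the three textbook process drawings: (a) a
#' reversible process (production arcs on both sides), (b) an irreversible
#' process with horizontal orientation (consumptions left, production
#' right), and (c) an irreversible process with vertical orientation
#' (consumptions above, production below). Used to pin down the
#' orientation and assignment behaviour of [yedToSbgn()].
#'
#' @return named list of three [YedGraph] objects:
#'   \code{reversible}, \code{irreversibleHorizontal},
#'   \code{irreversibleVertical}.
#' @export
fig2Fixtures <- function() {
  pool <- function(id, x, y, label)
    yedNode(id, "com.yworks.sbgn.SimpleChemical", bbox(x, y, 60, 30),
            label = label)
  proc <- function(id, x, y)
    yedNode(id, "com.yworks.sbgn.Process", bbox(x, y, 20, 20))
  prodArrow <- graphmlDialect()$arrows[["production"]]
  prod <- function(id, s, t)
    yedEdge(id, s, t, sourceArrow = prodArrow[["source"]],
            targetArrow = prodArrow[["target"]])
  cons <- function(id, s, t) yedEdge(id, s, t)

  reversible <- yedGraph(
    list(pool("L", 80, 195, "A"), pool("R", 340, 195, "B"),
         proc("P", 200, 200)),
    list(prod("e1", "P", "L"), prod("e2", "P", "R")))

  irreversibleHorizontal <- yedGraph(
    list(pool("A", 60, 140, "A"), pool("B", 60, 250, "B"),
         pool("C", 360, 195, "C"), proc("P", 200, 200)),
    list(cons("e1", "A", "P"), cons("e2", "B", "P"), prod("e3", "P", "C")))

  irreversibleVertical <- yedGraph(
    list(pool("A", 140, 60, "A"), pool("B", 250, 60, "B"),
         pool("C", 180, 360, "C"), proc("P", 200, 200)),
    list(cons("e1", "A", "P"), cons("e2", "B", "P"), prod("e3", "P", "C")))

  list(reversible = reversible,
       irreversibleHorizontal = irreversibleHorizontal,
       irreversibleVertical = irreversibleVertical)
}
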