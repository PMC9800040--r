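# Process Description object model: class enumerations, element constructors,
# semantic validation, incidence queries.

#' SBGN Process Description vocabularies
#'
#' Closed enumerations of the glyph and arc classes handled by the converter.
#' Unknown class strings in input files are a parse error, never silently
#' remapped.
#'
#' @return character vector of class names.
#' @examples
#' glyphClasses()
#' arcClasses()
#' @export
glyphClasses <- function() {
  c("compartment", "complex", "macromolecule", "nucleic acid feature",
    "simple chemical", "unspecified entity", "perturbing agent", "phenotype",
    "source and sink", "process", "omitted process", "uncertain process",
    "association", "dissociation", "and", "or", "not", "submap", "tag",
    "state variable", "unit of information")
}

#' @rdname glyphClasses
#' @export
arcClasses <- function() {
  c("consumption", "production", "catalysis", "stimulation", "inhibition",
    "modulation", "necessary stimulation")
}

#' @rdname glyphClasses
#' @export
processClasses <- function() {
  c("process", "omitted process", "uncertain process", "association",
    "dissociation")
}

#' @rdname glyphClasses
#' @export
entityPoolClasses <- function() {
  c("macromolecule", "simple chemical", "nucleic acid feature", "complex",
    "unspecified entity", "perturbing agent")
}

#' @rdname glyphClasses
#' @export
auxUnitClasses <- function() c("state variable", "unit of information")

# classes that may carry a multimer cardinality
multimerClasses <- function() {
  c("simple chemical", "macromolecule", "complex", "nucleic acid feature")
}

# flux arcs attach to process ports; the modulation family attaches to the body
fluxArcClasses <- function() c("consumption", "production")

#' Bounding box constructor
#'
#' Geometry follows the shared convention of SBGN-ML \code{bbox} and yFiles
#' \code{Geometry}: top-left origin, y grows downward, unitless canvas
#' coordinates. Because both formats agree, conversion is coordinate-identity
#' and no axis flipping happens anywhere in the package.
#'
#' @param x,y top-left corner.
#' @param w,h width and height, both strictly positive.
#' @return named numeric vector \code{c(x, y, w, h)}.
#' @examples
#' bboxCenter(bbox(100, 100, 20, 20))
#' @export
bbox <- function(x, y, w, h) {
  v <- c(x = canonNum(x), y = canonNum(y), w = canonNum(w), h = canonNum(h))
  if (any(!is.finite(v))) stop("bbox coordinates must be finite")
  if (v[["w"]] <= 0 || v[["h"]] <= 0) stop("bbox width/height must be > 0")
  v
}

#' @rdname bbox
#' @param b a bbox vector.
#' @export
bboxCenter <- function(b) {
  c(x = unname(b[["x"]] + b[["w"]] / 2), y = unname(b[["y"]] + b[["h"]] / 2))
}

# canonical coordinate: the double that the 6-decimal serialisation parses
# back to, so write-then-read is bit-exact on every constructed element
canonNum <- function(x) {
  x <- as.numeric(x)
  ok <- is.finite(x)
  x[ok] <- as.numeric(sprintf("%.6f", x[ok]))
  x
}

#' Process port record
#'
#' @param id unique port id.
#' @param x,y port position (the antenna tip, outside the owner's box).
#' @return port record (named list).
#' @export
pdPort <- function(id, x, y) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  list(id = id, x = canonNum(x), y = canonNum(y))
}

#' Glyph record constructor
#'
#' Builds one SBGN PD glyph. Containment is by reference: \code{compartmentRef}
#' names the compartment a top-level glyph lies in; \code{parent} names the
#' carrying glyph for auxiliary units (state variables, units of information)
#' and complex members. Process-family glyphs may carry two ports ([pdPort()]).
#'
#' @param id unique glyph id.
#' @param cls one of [glyphClasses()].
#' @param bbox geometry, from [bbox()].
#' @param label optional label text.
#' @param compartmentRef optional id of the containing compartment glyph.
#' @param parent optional id of the carrying glyph (auxiliary units, complex
#'   members).
#' @param clone logical clone-marker flag.
#' @param cloneLabel optional clone-marker label.
#' @param multimer optional multimer cardinality (integer >= 2); only
#'   meaningful on simple chemical, macromolecule, complex and nucleic acid
#'   feature glyphs.
#' @param stateValue,stateVariable state-variable payload (state-variable
#'   glyphs only), e.g. value \code{"P"}, variable \code{"Ser15"}.
#' @param orientation \code{"horizontal"}/\code{"vertical"} for processes,
#'   \code{"left"}/\code{"right"}/\code{"up"}/\code{"down"} for tags.
#' @param ports list of 0 or 2 port records.
#' @param extension named character vector of conserved styling/annotation
#'   (keys \code{fill}, \code{stroke} are understood; anything else is carried
#'   verbatim).
#' @return glyph record (named list).
#' @examples
#' g <- pdGlyph("m1", "macromolecule", bbox(0, 0, 80, 40), label = "PKM2")
#' @export
pdGlyph <- function(id, cls, bbox, label = NA_character_,
                    compartmentRef = NA_character_, parent = NA_character_,
                    clone = FALSE, cloneLabel = NA_character_,
                    multimer = NA_integer_, stateValue = NA_character_,
                    stateVariable = NA_character_,
                    orientation = NA_character_, ports = list(),
                    extension = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!cls %in% glyphClasses())
    stop(sprintf("unknown glyph class '%s'", cls), call. = FALSE)
  if (!is.na(multimer)) {
    multimer <- as.integer(multimer)
    if (multimer < 2L) stop("multimer cardinality must be >= 2")
  }
  if (!length(extension)) extension <- character()
  list(id = id, cls = cls, label = as.character(label), bbox = bbox,
       compartmentRef = as.character(compartmentRef),
       parent = as.character(parent), clone = isTRUE(clone),
       cloneLabel = as.character(cloneLabel), multimer = multimer,
       stateValue = as.character(stateValue),
       stateVariable = as.character(stateVariable),
       orientation = as.character(orientation), ports = ports,
       extension = extension)
}

#' Arc record constructor
#'
#' Arcs connect glyphs, or glyphs and process ports. By Process Description
#' convention consumption arcs point entity -> port and production arcs point
#' port -> entity; [readSbgnMl()] and [yedToSbgn()] normalise files that
#' violate this, with a logged warning.
#'
#' @param id unique arc id.
#' @param cls one of [arcClasses()].
#' @param source,target glyph id or port id; must differ.
#' @param bends optional matrix of bend points, columns x and y.
#' @param extension named character vector, as in [pdGlyph()].
#' @return arc record (named list).
#' @export
pdArc <- function(id, cls, source, target, bends = NULL,
                  extension = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!cls %in% arcClasses())
    stop(sprintf("unknown arc class '%s'", cls), call. = FALSE)
  if (identical(source, target)) stop("arc source must differ from target")
  if (is.null(bends)) bends <- matrix(numeric(), ncol = 2L,
                                      dimnames = list(NULL, c("x", "y")))
  bends <- matrix(canonNum(bends), ncol = 2L,
                  dimnames = list(NULL, c("x", "y")))
  if (!length(extension)) extension <- character()
  list(id = id, cls = cls, source = as.character(source),
       target = as.character(target), bends = bends, extension = extension)
}

#' Assemble a PDMap
#'
#' Element order inside the container is canonical (ids sorted bytewise), so
#' maps built element-for-element from different sources — a generator, a
#' parser walking the XML in document order, a converter — compare equal
#' when their elements do.
#'
#' @param glyphs list of glyph records.
#' @param arcs list of arc records.
#' @return a [PDMap].
#' @export
pdMap <- function(glyphs = list(), arcs = list()) {
  names(glyphs) <- vapply(glyphs, function(g) g$id, character(1))
  names(arcs) <- vapply(arcs, function(a) a$id, character(1))
  glyphs <- glyphs[order(names(glyphs), method = "radix")]
  arcs <- arcs[order(names(arcs), method = "radix")]
  new("PDMap", glyphs = glyphs, arcs = arcs)
}

# flat port index: data.frame(port, owner, x, y)
portIndex <- function(map) {
  gl <- map@glyphs
  np <- vapply(gl, function(g) length(g$ports), integer(1),
               USE.NAMES = FALSE)
  tot <- sum(np)
  port <- owner <- character(tot)
  x <- y <- numeric(tot)
  k <- 0L
  for (i in which(np > 0L)) {
    g <- gl[[i]]
    for (p in g$ports) {
      k <- k + 1L
      port[k] <- p$id
      owner[k] <- g$id
      x[k] <- p$x
      y[k] <- p$y
    }
  }
  data.frame(port = port, owner = owner, x = x, y = y,
             stringsAsFactors = FALSE)
}

violation <- function(rule, element, message) {
  data.frame(rule = rule, element = element, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a Process Description map
#'
#' Checks the semantic rules of the Process Description dialect this package
#' reads and writes, and returns every violation as a data row rather than an
#' exception. The central rules are the two port rules that drive the reverse
#' converter's arc-port assignment:
#' \itemize{
#'   \item \emph{port rule 1} (\code{port-arc-type}): all arcs attached to one
#'     port carry the same arc class;
#'   \item \emph{port rule 2} (\code{port-occupancy}): every port of every
#'     process has at least one attached arc.
#' }
#' Further rules: id reference resolution (\code{dangling-ref}), id uniqueness
#' (\code{dup-id}), port count on processes (\code{port-count}: 0 or 2),
#' multimer cardinality restricted to the four multimer-capable classes
#' (\code{multimer-class}), state payload only on state variables
#' (\code{state-class}), non-container children restricted to auxiliary units
#' (\code{child-class}), consumption/production arc direction relative to
#' ports (\code{arc-direction}), and degenerate arcs (\code{arc-loop}).
#'
#' \code{validatePD} is pure: the same map always yields the same violation
#' table, and an empty table means the map is PD-valid under these rules.
#'
#' @param map a [PDMap].
#' @return data.frame with columns \code{rule}, \code{element},
#'   \code{message}; zero rows iff valid.
#' @examples
#' validatePD(pdMap())  # empty map is vacuously valid
#' @export
validatePD <- function(map) {
  stopifnot(is(map, "PDMap"))
  gl <- map@glyphs
  ar <- map@arcs
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v

  pidx <- portIndex(map)
  gids <- names(gl)
  allIds <- c(gids, pidx$port, names(ar))
  if (anyDuplicated(allIds)) {
    for (d in unique(allIds[duplicated(allIds)]))
      add(violation("dup-id", d, "id used more than once"))
  }

  for (g in gl) {
    if (!is.na(g$compartmentRef) && !g$compartmentRef %in% gids)
      add(violation("dangling-ref", g$id,
                    sprintf("compartmentRef '%s' does not resolve",
                            g$compartmentRef)))
    if (!is.na(g$parent)) {
      if (!g$parent %in% gids) {
        add(violation("dangling-ref", g$id,
                      sprintf("parent '%s' does not resolve", g$parent)))
      } else {
        pcls <- gl[[g$parent]]$cls
        if (!pcls %in% c("complex", "compartment", "submap") &&
            !g$cls %in% auxUnitClasses())
          add(violation("child-class", g$id,
                        sprintf("child of non-container '%s' must be an auxiliary unit",
                                g$parent)))
      }
    }
    if (!is.na(g$multimer) && !g$cls %in% multimerClasses())
      add(violation("multimer-class", g$id,
                    sprintf("multimer cardinality not allowed on class '%s'",
                            g$cls)))
    if (!is.na(g$stateValue) && g$cls != "state variable")
      add(violation("state-class", g$id,
                    "state payload only allowed on state variable glyphs"))
    if (g$cls %in% processClasses() && !length(g$ports) %in% c(0L, 2L))
      add(violation("port-count", g$id,
                    sprintf("process carries %d ports; expected 0 or 2",
                            length(g$ports))))
    if (length(g$ports) && !g$cls %in% processClasses())
      add(violation("port-count", g$id,
                    sprintf("ports not allowed on class '%s'", g$cls)))
  }

  # vectorised endpoint checks (maps can be genome-scale)
  if (length(ar)) {
    aid <- names(ar)
    src <- vapply(ar, function(a) a$source, character(1), USE.NAMES = FALSE)
    tgt <- vapply(ar, function(a) a$target, character(1), USE.NAMES = FALSE)
    cls <- vapply(ar, function(a) a$cls, character(1), USE.NAMES = FALSE)
    known <- c(gids, pidx$port)
    for (i in which(!src %in% known))
      add(violation("dangling-ref", aid[i],
                    sprintf("endpoint '%s' does not resolve", src[i])))
    for (i in which(!tgt %in% known))
      add(violation("dangling-ref", aid[i],
                    sprintf("endpoint '%s' does not resolve", tgt[i])))
    for (i in which(src == tgt))
      add(violation("arc-loop", aid[i], "arc source equals target"))
    srcIsPort <- src %in% pidx$port
    tgtIsPort <- tgt %in% pidx$port
    for (i in which(cls == "consumption" & srcIsPort))
      add(violation("arc-direction", aid[i],
                    "consumption arc must point entity -> port"))
    for (i in which(cls == "production" & tgtIsPort & !srcIsPort))
      add(violation("arc-direction", aid[i],
                    "production arc must point port -> entity"))

    onPort <- c(src[srcIsPort], tgt[tgtIsPort])
    onPortCls <- c(cls[srcIsPort], cls[tgtIsPort])
    mixed <- tapply(onPortCls, onPort, function(z) length(unique(z)))
    for (p in names(mixed)[mixed > 1L])
      add(violation("port-arc-type", p, "port carries mixed arc classes"))
    occupied <- unique(onPort)
  } else {
    occupied <- character()
  }
  if (nrow(pidx)) {
    for (i in which(!pidx$port %in% occupied))
      add(violation("port-occupancy", pidx$port[i],
                    sprintf("port of process '%s' has no attached arc",
                            pidx$owner[i])))
  }

  if (!length(out))
    return(data.frame(rule = character(), element = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Arcs incident to a process
#'
#' Returns every arc whose source or target is the given process glyph or one
#' of its ports, in stable arc-id order.
#'
#' @param map a [PDMap].
#' @param processId id of a process-family glyph.
#' @return named list of arc records.
#' @export
incidentArcs <- function(map, processId) {
  stopifnot(is(map, "PDMap"))
  g <- map@glyphs[[processId]]
  if (is.null(g))
    stop(sprintf("unknown glyph id '%s'", processId), call. = FALSE)
  if (!g$cls %in% processClasses())
    stop(sprintf("glyph '%s' is not a process-family glyph", processId),
         call. = FALSE)
  ends <- c(g$id, vapply(g$ports, `[[`, character(1), "id"))
  hit <- vapply(map@arcs, function(a) a$source %in% ends || a$target %in% ends,
                logical(1))
  sel <- map@arcs[hit]
  sel[order(names(sel))]
}
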