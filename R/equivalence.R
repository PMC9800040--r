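# Round-trip equivalence between PD maps.
#
# A full field-for-field identity is the wrong target for PD -> yEd -> PD:
# port ids and exact port positions are reconstructed, bend lists gain the
# port-visualisation bends, glyph orientation is re-inferred from geometry,
# and element ids may be renamed by other tools. The documented equivalence
# therefore compares canonical signatures: glyph class, label, compartment
# membership (by compartment signature), clone flag, multimer cardinality
# and the multiset of auxiliary units per carrier; and per arc the class
# plus the signatures of its endpoints with ports collapsed onto the owning
# process. Two maps are equivalent when both signature multisets coincide.

glyphSignatures <- function(map) {
  gl <- map@glyphs
  cls <- vapply(gl, function(g) g$cls, character(1))
  parent <- vapply(gl, function(g) g$parent, character(1))
  lab <- vapply(gl, function(g) g$label, character(1))

  isAux <- cls %in% auxUnitClasses() & !is.na(parent)
  auxSig <- vapply(which(isAux), function(i) {
    g <- gl[[i]]
    if (g$cls == "state variable")
      paste0("sv:", ifelse(is.na(g$stateValue), "", g$stateValue), "@",
             ifelse(is.na(g$stateVariable), "", g$stateVariable))
    else paste0("ui:", ifelse(is.na(g$label), "", g$label))
  }, character(1))
  auxByParent <- vapply(split(auxSig, parent[isAux]), function(z)
    paste(sort(z), collapse = "&"), character(1))

  compLabel <- ifelse(is.na(lab), "", lab)
  sig <- character(length(gl))
  for (i in seq_along(gl)) {
    g <- gl[[i]]
    comp <- if (is.na(g$compartmentRef)) "" else
      compLabel[[g$compartmentRef]]
    aux <- if (g$id %in% names(auxByParent)) auxByParent[[g$id]] else ""
    sig[i] <- paste(g$cls, ifelse(is.na(g$label), "", g$label), comp,
                    as.integer(isTRUE(g$clone)),
                    ifelse(is.na(g$multimer), "", g$multimer), aux,
                    sep = "\r")
  }
  names(sig) <- names(gl)
  sig[!isAux]
}

#' Test two PD maps for round-trip equivalence
#'
#' Implements the package's documented map-equivalence relation (a signature
#' multiset comparison, see the conversion vignette): classes, labels,
#' compartment membership, clone flags, multimer cardinalities and
#' state-variable payloads must be preserved, as must every arc's class and
#' endpoint signatures (ports collapsed to their process). Port ids and
#' positions, bend lists, glyph ids and inferred orientations are outside
#' the relation.
#'
#' @param a,b two [PDMap] objects.
#' @return \code{TRUE} or \code{FALSE}; on \code{FALSE} the attribute
#'   \code{"why"} holds a short description of the first difference.
#' @export
pdEquivalent <- function(a, b) {
  fail <- function(why) structure(FALSE, why = why)
  sa <- glyphSignatures(a)
  sb <- glyphSignatures(b)
  if (length(sa) != length(sb))
    return(fail(sprintf("glyph counts differ: %d vs %d", length(sa),
                        length(sb))))
  if (!identical(sort(unname(sa)), sort(unname(sb)))) {
    d <- setdiff(unname(sa), unname(sb))
    return(fail(sprintf("glyph signatures differ, e.g. %s",
                        gsub("\r", "/", d[1]))))
  }
  arcSig <- function(map, sig) {
    pidx <- portIndex(map)
    own <- structure(pidx$owner, names = pidx$port)
    endSig <- function(id) {
      if (id %in% names(own)) id <- own[[id]]
      unname(sig[id])
    }
    vapply(map@arcs, function(x)
      paste(x$cls, endSig(x$source), endSig(x$target), sep = "\r"),
      character(1))
  }
  # signatures indexed by id incl. aux glyphs for endpoint lookup
  fullSig <- function(map) {
    s <- glyphSignatures(map)
    gl <- map@glyphs
    miss <- setdiff(names(gl), names(s))
    extra <- vapply(gl[miss], function(g)
      paste(g$cls, ifelse(is.na(g$label), "", g$label), sep = "\r"),
      character(1))
    c(s, extra)
  }
  aa <- sort(unname(arcSig(a, fullSig(a))))
  bb <- sort(unname(arcSig(b, fullSig(b))))
  if (length(aa) != length(bb))
    return(fail(sprintf("arc counts differ: %d vs %d", length(aa),
                        length(bb))))
  if (!identical(aa, bb)) {
    d <- setdiff(aa, bb)
    return(fail(sprintf("arc signatures differ, e.g. %s",
                        gsub("\r", "/", d[1]))))
  }
  TRUE
}
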