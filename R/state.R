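## Hierarchical state model + diff-only synchronization. The tree is flat
## internally: slash-separated paths name typed leaves; the hierarchy is the
## path structure. Diffs are the only state traffic and serialize to XML.

#' Construct a state model
#'
#' @param leaves named list mapping slash-separated paths (e.g.
#'   \code{"view/wl/center"}) to scalar number, string or boolean values.
#' @param revision starting revision (default 0).
#' @return a [StateModel-class].
#' @rdname stateModel
#' @export
stateModel <- function(leaves = list(), revision = 0L) {
  new("StateModel", leaves = leaves, revision = as.integer(revision))
}

#' @rdname stateModel
#' @export
setMethod("stateRevision", "StateModel", function(x, ...) x@revision)

#' @rdname stateModel
#' @export
setMethod("stateLeaves", "StateModel", function(x, ...) x@leaves)

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel: %d leaves, revision %d\n",
              length(object@leaves), object@revision))
  for (p in sort(names(object@leaves)))
    cat(sprintf("  %s = %s\n", p, format(object@leaves[[p]])))
})

#' Read or mutate single leaves
#'
#' \code{setLeaf}/\code{deleteLeaf} return a new model with the revision
#' bumped; models are immutable values.
#'
#' @param model a [StateModel-class].
#' @param path slash-separated leaf path.
#' @param value scalar number, string or boolean.
#' @rdname stateLeaf
#' @export
getLeaf <- function(model, path) model@leaves[[path]]

#' @rdname stateLeaf
#' @export
setLeaf <- function(model, path, value) {
  leaves <- model@leaves
  leaves[[path]] <- value
  new("StateModel", leaves = leaves, revision = model@revision + 1L)
}

#' @rdname stateLeaf
#' @export
deleteLeaf <- function(model, path) {
  if (!path %in% names(model@leaves)) stop("unknown path: ", path)
  leaves <- model@leaves
  leaves[[path]] <- NULL
  new("StateModel", leaves = leaves, revision = model@revision + 1L)
}

#' Compute the minimal diff between two state models
#'
#' Upserts are the paths that are new or whose values changed; deletes are
#' the paths present only in the old tree. The diff is empty (no upserts, no
#' deletes) iff the trees hold identical leaves.
#'
#' @param old,new [StateModel-class] objects.
#' @return a [StateDiff-class] based at \code{old}'s revision.
#' @rdname stateDiff
#' @export
computeDiff <- function(old, new) {
  oldL <- old@leaves; newL <- new@leaves
  up <- list()
  for (p in names(newL)) {
    if (!p %in% names(oldL) || !identical(oldL[[p]], newL[[p]]))
      up[[p]] <- newL[[p]]
  }
  dels <- as.character(setdiff(names(oldL), names(newL)))
  new("StateDiff", upserts = up, deletes = dels,
      baseRevision = old@revision,
      newRevision = max(new@revision, old@revision + 1L))
}

#' Apply a diff to a state model
#'
#' The diff must be based at the tree's current revision, otherwise the
#' caller is stale and must request a full resync. A full-state diff (NA
#' base revision, from [fullStateDiff()]) replaces all leaves and applies to
#' any tree.
#'
#' @param model a [StateModel-class].
#' @param diff a [StateDiff-class].
#' @return the updated [StateModel-class] at \code{diff@newRevision}.
#' @rdname stateDiff
#' @export
applyDiff <- function(model, diff) {
  if (is.na(diff@baseRevision)) {        # full resync keyframe
    return(new("StateModel", leaves = diff@upserts,
               revision = diff@newRevision))
  }
  if (diff@baseRevision != model@revision)
    stop("stale diff: base revision ", diff@baseRevision,
         " does not match tree revision ", model@revision)
  leaves <- model@leaves
  for (p in diff@deletes) {
    if (!p %in% names(leaves)) stop("unknown path: ", p)
    leaves[[p]] <- NULL
  }
  for (p in names(diff@upserts)) leaves[[p]] <- diff@upserts[[p]]
  new("StateModel", leaves = leaves, revision = diff@newRevision)
}

#' Full-state resync diff
#'
#' A keyframe diff carrying every leaf; applying it to any tree yields the
#' source tree exactly.
#'
#' @param model a [StateModel-class].
#' @return a [StateDiff-class] with NA base revision.
#' @rdname stateDiff
#' @export
fullStateDiff <- function(model) {
  new("StateDiff", upserts = model@leaves, deletes = character(0),
      baseRevision = NA_integer_,
      newRevision = max(model@revision, 1L))
}

.leafType <- function(v) {
  if (is.logical(v)) "boolean" else if (is.numeric(v)) "number" else "string"
}

.formatLeaf <- function(v) {
  if (is.logical(v)) if (v) "true" else "false"
  else if (is.numeric(v)) format(v, digits = 17, scientific = FALSE, trim = TRUE)
  else as.character(v)
}

.parseLeaf <- function(type, s) {
  switch(type,
    boolean = identical(s, "true"),
    number = as.numeric(s),
    string = s,
    stop("parse error: unknown leaf type '", type, "'"))
}

#' Serialize a state diff to XML, and parse it back
#'
#' The document schema is shipped at
#' \code{system.file("extdata", "state_diff.xsd", package = "teleCT")}.
#' \code{parseDiff(serializeDiff(d))} is structurally equal to \code{d}.
#'
#' @param diff a [StateDiff-class].
#' @return \code{serializeDiff}: a character scalar (XML document);
#'   \code{parseDiff}: a [StateDiff-class].
#' @rdname serializeDiff
#' @export
serializeDiff <- function(diff) {
  doc <- xml2::xml_new_root("stateDiff")
  if (is.na(diff@baseRevision)) {
    xml2::xml_set_attr(doc, "resync", "true")
  } else {
    xml2::xml_set_attr(doc, "baseRevision", as.character(diff@baseRevision))
  }
  xml2::xml_set_attr(doc, "newRevision", as.character(diff@newRevision))
  for (p in names(diff@upserts)) {
    v <- diff@upserts[[p]]
    node <- xml2::xml_add_child(doc, "upsert", .formatLeaf(v))
    xml2::xml_set_attr(node, "path", p)
    xml2::xml_set_attr(node, "type", .leafType(v))
  }
  for (p in diff@deletes) {
    node <- xml2::xml_add_child(doc, "delete")
    xml2::xml_set_attr(node, "path", p)
  }
  as.character(doc)
}

#' @rdname serializeDiff
#' @param document XML text produced by \code{serializeDiff}.
#' @export
parseDiff <- function(document) {
  doc <- tryCatch(xml2::read_xml(document), error = function(e)
    stop("parse error: ", conditionMessage(e), call. = FALSE))
  if (xml2::xml_name(doc) != "stateDiff")
    stop("parse error: root element must be <stateDiff>, got <",
         xml2::xml_name(doc), ">")
  resync <- identical(xml2::xml_attr(doc, "resync"), "true")
  base <- if (resync) NA_integer_ else {
    b <- xml2::xml_attr(doc, "baseRevision")
    if (is.na(b)) stop("parse error: missing baseRevision on <stateDiff>")
    as.integer(b)
  }
  newRev <- as.integer(xml2::xml_attr(doc, "newRevision"))
  if (is.na(newRev)) stop("parse error: missing newRevision on <stateDiff>")
  up <- list()
  for (node in xml2::xml_find_all(doc, "./upsert")) {
    p <- xml2::xml_attr(node, "path")
    ty <- xml2::xml_attr(node, "type")
    if (is.na(p) || is.na(ty))
      stop("parse error: <upsert> requires path and type attributes")
    up[[p]] <- .parseLeaf(ty, xml2::xml_text(node))
  }
  dels <- vapply(xml2::xml_find_all(doc, "./delete"), function(node) {
    p <- xml2::xml_attr(node, "path")
    if (is.na(p)) stop("parse error: <delete> requires a path attribute")
    p
  }, character(1))
  new("StateDiff", upserts = up, deletes = dels,
      baseRevision = base, newRevision = newRev)
}

#' JSON form of a diff for the wire
#'
#' The XML schema is the canonical mapping; JSON is the compact equivalent
#' used by the session wire. Round-trips exactly like the XML form.
#'
#' @param diff a [StateDiff-class].
#' @return \code{diffToJson}: a JSON string; \code{diffFromJson}: a
#'   [StateDiff-class].
#' @rdname serializeDiff
#' @export
diffToJson <- function(diff) {
  ups <- lapply(diff@upserts, function(v)
    list(type = .leafType(v), value = .formatLeaf(v)))
  jsonlite::toJSON(list(
    baseRevision = if (is.na(diff@baseRevision)) "resync"
                   else diff@baseRevision,
    newRevision = diff@newRevision,
    upserts = ups,
    deletes = as.list(diff@deletes)), auto_unbox = TRUE)
}

#' @rdname serializeDiff
#' @param json JSON text produced by \code{diffToJson}.
#' @export
diffFromJson <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  up <- lapply(x$upserts, function(u) .parseLeaf(u$type, u$value))
  base <- if (identical(x$baseRevision, "resync")) NA_integer_
          else as.integer(x$baseRevision)
  new("StateDiff", upserts = up,
      deletes = as.character(unlist(x$deletes)),
      baseRevision = base, newRevision = as.integer(x$newRevision))
}

setMethod("show", "StateDiff", function(object) {
  cat(sprintf("StateDiff %s -> %d: %d upsert(s), %d delete(s)\n",
              if (is.na(object@baseRevision)) "resync"
              else as.character(object@baseRevision),
              object@newRevision, length(object@upserts),
              length(object@deletes)))
})
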