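#' @title Reading and writing networks and region maps
#' @name pialnet-io
#' @description GraphML I/O for [PialNetwork] objects and GeoJSON I/O for
#'   [RegionMap] objects.  Writing is bit-stable: attribute order is fixed
#'   and decimals are formatted locale-independently, so
#'   write-read-write produces byte-identical files.
NULL

NODE_ATTRS <- c(x_mm = "double", y_mm = "double", kind = "string")
EDGE_ATTRS <- c(kind = "string", territory_a = "string",
                territory_b = "string", polyline = "string")

xmlEscape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  s <- gsub("\"", "&quot;", s, fixed = TRUE)
  s
}

fmtNum <- function(x) sprintf("%.17g", x)

#' Write a pial network as GraphML
#'
#' Emits node attributes `x_mm`, `y_mm`, `kind` and edge attributes `kind`,
#' `territory_a`, `territory_b`, `polyline` plus graph-level metadata
#' (scalar character entries of the network metadata), in a fixed attribute
#' order with locale-independent decimal formatting.  The network is
#' validated first; nothing is written for an invalid network.
#'
#' @param net a [PialNetwork].
#' @param path output file path.
#' @param rm optional [RegionMap] for geometric validation.
#' @return invisibly, `path`.
#' @seealso [readNetwork()]
#' @export
writeNetwork <- function(net, path, rm = NULL) {
  stopifnot(is(net, "PialNetwork"))
  validObject(net)
  f <- validateNetwork(net, rm)
  if (nrow(f))
    stop("invalid network, refusing to write: ", f$message[1])
  nd <- net@nodes; ed <- net@edges
  L <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
         "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">")
  keys <- character(0)
  ki <- 0
  keyId <- c()
  for (a in names(NODE_ATTRS)) {
    id <- sprintf("d%d", ki); ki <- ki + 1
    keyId[paste0("node.", a)] <- id
    keys <- c(keys, sprintf(
      "  <key id=\"%s\" for=\"node\" attr.name=\"%s\" attr.type=\"%s\"/>",
      id, a, NODE_ATTRS[[a]]))
  }
  for (a in names(EDGE_ATTRS)) {
    id <- sprintf("d%d", ki); ki <- ki + 1
    keyId[paste0("edge.", a)] <- id
    keys <- c(keys, sprintf(
      "  <key id=\"%s\" for=\"edge\" attr.name=\"%s\" attr.type=\"%s\"/>",
      id, a, EDGE_ATTRS[[a]]))
  }
  meta <- net@metadata
  meta <- meta[vapply(meta, function(v)
    is.character(v) && length(v) == 1 || is.numeric(v) && length(v) == 1,
    logical(1))]
  mi <- 0
  for (a in names(meta)) {
    id <- sprintf("m%d", mi); mi <- mi + 1
    keyId[paste0("graph.", a)] <- id
    keys <- c(keys, sprintf(
      "  <key id=\"%s\" for=\"graph\" attr.name=\"%s\" attr.type=\"string\"/>",
      id, xmlEscape(a)))
  }
  L <- c(L, keys,
         sprintf("  <graph id=\"%s\" edgedefault=\"undirected\">",
                 xmlEscape(if (is.na(net@slabId)) "slab" else net@slabId)))
  for (a in names(meta))
    L <- c(L, sprintf("    <data key=\"%s\">%s</data>",
                      keyId[paste0("graph.", a)],
                      xmlEscape(as.character(meta[[a]]))))
  nodeLines <- sprintf(paste0(
    "    <node id=\"%s\"><data key=\"%s\">%s</data>",
    "<data key=\"%s\">%s</data><data key=\"%s\">%s</data></node>"),
    xmlEscape(nd$id),
    keyId["node.x_mm"], fmtNum(nd$x_mm),
    keyId["node.y_mm"], fmtNum(nd$y_mm),
    keyId["node.kind"], xmlEscape(nd$kind))
  pl <- ifelse(is.na(ed$polyline), "", xmlEscape(ed$polyline))
  edgeLines <- sprintf(paste0(
    "    <edge id=\"%s\" source=\"%s\" target=\"%s\">",
    "<data key=\"%s\">%s</data><data key=\"%s\">%s</data>",
    "<data key=\"%s\">%s</data><data key=\"%s\">%s</data></edge>"),
    xmlEscape(ed$id), xmlEscape(ed$node_a), xmlEscape(ed$node_b),
    keyId["edge.kind"], xmlEscape(ed$kind),
    keyId["edge.territory_a"], xmlEscape(ed$territory_a),
    keyId["edge.territory_b"], xmlEscape(ed$territory_b),
    keyId["edge.polyline"], pl)
  L <- c(L, nodeLines, edgeLines, "  </graph>", "</graphml>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(L, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a pial network from GraphML
#'
#' Expects node attributes `x_mm`, `y_mm`, `kind` and edge attributes
#' `kind` (optionally `territory_a`, `territory_b`, `polyline`).  Unknown
#' graph-level attributes become metadata entries; unknown node/edge
#' attributes are preserved in `metadata$unknownNodeAttrs` /
#' `metadata$unknownEdgeAttrs`.
#'
#' @param path GraphML file path.
#' @param format only `"graphml"` is supported.
#' @return a validated [PialNetwork].  A disconnected graph or an element
#'   lacking a required attribute raises an error naming the element.
#' @export
readNetwork <- function(path, format = c("graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keyNodes <- xml2::xml_find_all(doc, ".//key")
  keyFor <- xml2::xml_attr(keyNodes, "for")
  keyName <- xml2::xml_attr(keyNodes, "attr.name")
  keyIds <- xml2::xml_attr(keyNodes, "id")
  lookup <- setNames(keyName, keyIds)
  graph <- xml2::xml_find_first(doc, ".//graph")
  if (inherits(graph, "xml_missing")) stop("no <graph> element in ", path)
  slabId <- xml2::xml_attr(graph, "id")

  getData <- function(el) {
    ds <- xml2::xml_find_all(el, "./data")
    v <- xml2::xml_text(ds)
    names(v) <- lookup[xml2::xml_attr(ds, "key")]
    v
  }
  gmeta <- as.list(getData(graph))

  nodeEls <- xml2::xml_find_all(graph, "./node")
  ids <- xml2::xml_attr(nodeEls, "id")
  ndat <- lapply(nodeEls, getData)
  getReq <- function(dat, id, attr, what) {
    v <- unname(dat[attr])
    if (length(v) != 1 || is.na(v) || !nzchar(v))
      stop(sprintf("%s '%s' lacks required attribute '%s'", what, id, attr))
    v
  }
  nodes <- data.frame(
    id = ids,
    x_mm = vapply(seq_along(ids), function(i)
      as.numeric(getReq(ndat[[i]], ids[i], "x_mm", "node")), numeric(1)),
    y_mm = vapply(seq_along(ids), function(i)
      as.numeric(getReq(ndat[[i]], ids[i], "y_mm", "node")), numeric(1)),
    kind = vapply(seq_along(ids), function(i)
      getReq(ndat[[i]], ids[i], "kind", "node"), character(1)),
    stringsAsFactors = FALSE)

  edgeEls <- xml2::xml_find_all(graph, "./edge")
  eids <- xml2::xml_attr(edgeEls, "id")
  if (length(eids) && anyNA(eids))
    eids <- ifelse(is.na(eids), sprintf("e%d", seq_along(eids)), eids)
  edat <- lapply(edgeEls, getData)
  opt <- function(dat, attr, default) {
    v <- unname(dat[attr])
    if (length(v) != 1 || is.na(v) || !nzchar(v)) default else v
  }
  edges <- data.frame(
    id = eids,
    node_a = xml2::xml_attr(edgeEls, "source"),
    node_b = xml2::xml_attr(edgeEls, "target"),
    kind = vapply(seq_along(eids), function(i)
      getReq(edat[[i]], eids[i], "kind", "edge"), character(1)),
    territory_a = vapply(edat, opt, character(1), attr = "territory_a",
                         default = "unknown"),
    territory_b = vapply(edat, opt, character(1), attr = "territory_b",
                         default = "unknown"),
    polyline = vapply(edat, opt, character(1), attr = "polyline",
                      default = NA_character_),
    stringsAsFactors = FALSE)

  knownN <- names(NODE_ATTRS); knownE <- names(EDGE_ATTRS)
  unkN <- lapply(ndat, function(d) d[setdiff(names(d), knownN)])
  unkE <- lapply(edat, function(d) d[setdiff(names(d), knownE)])
  meta <- gmeta
  if (any(lengths(unkN) > 0))
    meta$unknownNodeAttrs <- setNames(unkN, nodes$id)
  if (any(lengths(unkE) > 0))
    meta$unknownEdgeAttrs <- setNames(unkE, edges$id)

  net <- pialNetwork(nodes, edges, slabId = slabId, metadata = meta)
  f <- validateNetwork(net)
  structural <- f[f$rule %in% c("connected", "nonempty"), , drop = FALSE]
  if (nrow(structural)) stop("invalid network in ", path, ": ",
                             structural$message[1])
  net
}

regionFeature <- function(coords, props) {
  ring <- rbind(coords, coords[1, , drop = FALSE])
  list(type = "Feature", properties = props,
       geometry = list(type = "Polygon",
                       coordinates = list(lapply(seq_len(nrow(ring)),
                                                 function(i) ring[i, ]))))
}

#' Write a region map as GeoJSON
#'
#' One FeatureCollection: a slab feature with property `role = "slab"` and
#' one feature per region with property `region_id`.
#'
#' @param rm a [RegionMap].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeRegions <- function(rm, path) {
  stopifnot(is(rm, "RegionMap"))
  validObject(rm)
  feats <- c(list(regionFeature(rm@slab,
                                list(role = "slab", id = rm@slabId))),
             lapply(names(rm@regions), function(r)
               regionFeature(rm@regions[[r]], list(region_id = r))))
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a region map from GeoJSON
#'
#' @param path GeoJSON file path (FeatureCollection with one slab feature
#'   and up to five region features).
#' @return a validated [RegionMap].  Overlapping regions beyond the 1e-9
#'   mm^2 tolerance raise a validation error naming the pair.
#' @export
readRegions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  slab <- NULL; slabId <- NA_character_; regions <- list()
  for (ft in fc$features) {
    coords <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p))))
    props <- ft$properties
    if (identical(props$role, "slab")) {
      slab <- m
      if (!is.null(props$id)) slabId <- as.character(props$id)
    } else if (!is.null(props$region_id)) {
      regions[[as.character(props$region_id)]] <- m
    } else stop("feature with neither role='slab' nor region_id in ", path)
  }
  if (is.null(slab)) stop("no slab feature (role='slab') in ", path)
  if (length(regions) > 5) stop("more than 5 region features in ", path)
  regionMap(slab, regions, slabId = slabId)
}
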