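#' Read a network from a file
#'
#' Supports tab/whitespace-separated edge lists (two or three columns:
#' source, target, optional weight), GML and Pajek NET files. The format
#' is auto-detected from the file extension (`.gml`, `.net`/`.paj`,
#' anything else as edge list). Duplicate edges are summed into weights
#' and self-loops follow the doubled-diagonal convention. Directed input
#' is an error unless `symmetrize = TRUE`.
#'
#' @param path file path.
#' @param format `"auto"`, `"edgelist"`, `"gml"` or `"pajek"`.
#' @param symmetrize treat a directed graph as undirected instead of
#'   erroring.
#' @return an [nlc_network].
#' @export
read_network <- function(path, format = c("auto", "edgelist", "gml", "pajek"),
                         symmetrize = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gml = "gml", net = "pajek", paj = "pajek",
                     "edgelist")
  }
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines) == 0L) stop("empty edge list: ", path)
    parts <- strsplit(trimws(lines), "\\s+")
    ncols <- lengths(parts)
    if (any(ncols < 2L | ncols > 3L))
      stop("parse error in ", path, " at line ",
           which(ncols < 2L | ncols > 3L)[1L],
           ": expected 2 or 3 whitespace-separated fields")
    a <- vapply(parts, `[[`, character(1), 1L)
    b <- vapply(parts, `[[`, character(1), 2L)
    w <- vapply(parts, function(p) {
      if (length(p) >= 3L) as.numeric(p[[3L]]) else 1
    }, numeric(1))
    if (anyNA(w)) stop("parse error in ", path, " at line ",
                       which(is.na(w))[1L], ": bad weight")
    return(nlc_network(data.frame(a = a, b = b, w = w)))
  }
  g <- igraph::read_graph(path, format = format)
  if (igraph::is_directed(g)) {
    if (!symmetrize)
      stop("directed graph in ", path,
           "; pass symmetrize = TRUE to fold it into an undirected network")
    g <- igraph::as_undirected(g, mode = "each")
  }
  from_igraph(g)
}

#' Read a ground-truth cover file
#'
#' One community per line, whitespace-separated node labels.
#'
#' @param path file path.
#' @param net the [nlc_network] whose labels the file refers to.
#' @return an [nlc_cover].
#' @export
read_cover <- function(path, net) {
  stopifnot(inherits(net, "nlc_network"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  mods <- strsplit(trimws(lines), "\\s+")
  bad <- !unlist(mods) %in% net$labels
  if (any(bad)) stop("unknown node label in cover: ", unlist(mods)[bad][1L])
  nlc_cover(mods, net$n, labels = net$labels)
}

.structure_schema <- c("version", "c", "scheme", "method", "types",
                       "communities", "background_nodes",
                       "background_links", "mdl", "loglik")

#' Serialize a detection result to JSON
#'
#' Writes the typed communities (node labels for node communities,
#' endpoint label pairs for link communities), background lists, MDL,
#' log-likelihood, seed and optionally the soft membership matrices. The
#' document round-trips losslessly through [read_structure()].
#'
#' @param result an `nlc_result` from [detect_communities()].
#' @param path output file path.
#' @param memberships also store the soft membership matrices `S` and
#'   `R`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(result, path, memberships = FALSE) {
  stopifnot(inherits(result, "nlc_result"))
  net <- result$network
  st <- result$structure
  comms <- lapply(seq_along(st$types), function(k) {
    if (st$types[k] == "node") {
      list(type = "node", nodes = as.list(net$labels[st$node_sets[[k]]]))
    } else {
      es <- st$link_sets[[k]]
      list(type = "link",
           links = lapply(es, function(e) list(net$labels[net$ei[e]],
                                               net$labels[net$ej[e]])))
    }
  })
  doc <- list(
    version = as.character(utils::packageVersion("nlcomm")),
    c = result$c, scheme = result$scheme, method = result$method,
    types = as.list(st$types), communities = comms,
    background_nodes = as.list(net$labels[st$background_nodes]),
    background_links = lapply(st$background_links, function(e)
      list(net$labels[net$ei[e]], net$labels[net$ej[e]])),
    mdl = result$mdl, loglik = result$loglik,
    seed = if (is.null(result$seed)) NULL else result$seed
  )
  if (memberships) {
    doc$S <- result$S
    doc$R <- unclass(result$R)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_structure
#' @return `read_structure`: the parsed document as a list; errors when a
#'   required key is missing.
#' @export
read_structure <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  missing <- setdiff(.structure_schema, names(doc))
  if (length(missing))
    stop("invalid structure file ", path, ": missing key(s) ",
         paste(missing, collapse = ", "))
  doc$types <- unlist(doc$types)
  doc
}
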