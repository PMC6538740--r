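#' Interaction networks
#'
#' An `interaction_network` is a simple undirected graph of typed nodes
#' (compound, target or protein). Edges are stored as canonically ordered
#' unordered pairs; duplicates and self-loops are dropped at construction,
#' and every edge endpoint must be a declared node.
#'
#' @param nodes data frame with columns `id` (unique character) and `kind`.
#' @param edges data frame with columns `from` and `to`.
#' @return An object of class `interaction_network` with elements `nodes`
#'   and `edges`.
#' @export
interaction_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), all(c("id", "kind") %in% names(nodes)))
  nodes <- data.frame(id = as.character(nodes$id), kind = as.character(nodes$kind),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("from", "to") %in% names(edges)))
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    a <- pmin(from, to); b <- pmax(from, to)
    key <- paste(a, b, sep = "\r")
    dup <- duplicated(key)
    edges <- data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE)
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
    if (length(missing))
      stop("edge endpoints not declared as nodes: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  ord <- order(edges$from, edges$to)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat("Interaction network: ", nrow(x$nodes), " nodes (",
      paste(names(kinds), kinds, sep = ": ", collapse = ", "), "), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @rdname interaction_network
#' @param net an `interaction_network`.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname interaction_network
#' @export
n_edges <- function(net) nrow(net$edges)

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

network_degrees <- function(net) {
  deg <- setNames(integer(nrow(net$nodes)), net$nodes$id)
  tab <- table(c(net$edges$from, net$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Build a bipartite compound-target network
#'
#' Nodes are the compounds plus the union of their targets; edges connect
#' each compound to each of its targets, so no compound-compound or
#' target-target edge can arise.
#'
#' @param mapping named list (compound id -> character vector of targets) or
#'   a data frame with columns `compound_id` and `target`.
#' @return An [interaction_network] with node kinds `compound` and `target`.
#' @export
build_bipartite <- function(mapping) {
  mapping <- as_target_list(mapping)
  mapping <- mapping[lengths(mapping) > 0L]
  if (!length(mapping)) {
    return(interaction_network(
      data.frame(id = character(0), kind = character(0)), NULL))
  }
  compounds <- names(mapping)
  targets <- sort(unique(unlist(mapping, use.names = FALSE)))
  clash <- intersect(compounds, targets)
  if (length(clash)) stop("ids used as both compound and target: ",
                          paste(utils::head(clash, 5), collapse = ", "))
  nodes <- data.frame(
    id = c(compounds, targets),
    kind = c(rep("compound", length(compounds)), rep("target", length(targets))),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = rep(compounds, lengths(mapping)),
    to = unlist(mapping, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  interaction_network(nodes, edges)
}

as_target_list <- function(mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(all(c("compound_id", "target") %in% names(mapping)))
    mapping <- split(as.character(mapping$target), mapping$compound_id)
  }
  lapply(mapping, function(v) unique(as.character(v)))
}

#' Build a PPI network around seed proteins from an interaction edge list
#'
#' With `expand_neighbors = TRUE` (the default, matching the usual
#' first-neighbour expansion of interactome screens) the network contains
#' the seeds plus all their direct interactors, with every edge-list edge
#' among the included nodes. Otherwise the induced subgraph on the seeds is
#' returned. Seeds absent from the edge list are retained as isolated nodes
#' with a warning.
#'
#' @param seeds character vector of seed protein ids.
#' @param edge_list data frame whose first two columns are interacting ids
#'   (e.g. from [read_edge_list()]).
#' @param expand_neighbors logical; include first neighbours of seeds.
#' @return An [interaction_network] of kind `protein`.
#' @export
build_ppi <- function(seeds, edge_list, expand_neighbors = TRUE) {
  seeds <- unique(as.character(seeds))
  a <- as.character(edge_list[[1]])
  b <- as.character(edge_list[[2]])
  known <- unique(c(a, b))
  orphan <- setdiff(seeds, known)
  if (length(orphan))
    warning(length(orphan), " seed(s) absent from the edge list kept as isolated nodes")
  if (expand_neighbors) {
    touch <- a %in% seeds | b %in% seeds
    include <- unique(c(seeds, a[touch], b[touch]))
  } else {
    include <- seeds
  }
  keep <- a %in% include & b %in% include
  interaction_network(
    nodes = data.frame(id = include, kind = "protein", stringsAsFactors = FALSE),
    edges = data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
  )
}

#' Intersect (or merge) two interaction networks
#'
#' `intersect` keeps the node ids present in both networks and the edges
#' present, with both endpoints, in both; `merge` takes the union of nodes
#' and edges. When the same id carries different kinds the first network's
#' kind wins.
#'
#' @param a,b [interaction_network] objects.
#' @param mode `"intersect"` (default) or `"merge"`.
#' @return An [interaction_network].
#' @export
intersect_networks <- function(a, b, mode = c("intersect", "merge")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "interaction_network"), inherits(b, "interaction_network"))
  ekey <- function(net) paste(net$edges$from, net$edges$to, sep = "\r")
  if (mode == "intersect") {
    ids <- intersect(a$nodes$id, b$nodes$id)
    keep <- ekey(a) %in% ekey(b) & a$edges$from %in% ids & a$edges$to %in% ids
    nodes <- a$nodes[a$nodes$id %in% ids, , drop = FALSE]
    edges <- a$edges[keep, , drop = FALSE]
  } else {
    extra <- b$nodes[!(b$nodes$id %in% a$nodes$id), , drop = FALSE]
    nodes <- rbind(a$nodes, extra)
    edges <- rbind(a$edges, b$edges)
  }
  interaction_network(nodes, edges)
}

#' Node centralities with table medians
#'
#' Computes, per node: degree (DC); shortest-path betweenness normalised by
#' `(n-1)(n-2)/2` (BC); closeness per connected component as
#' `(n_comp - 1) / sum(distances)` scaled by `(n_comp - 1)/(n - 1)`
#' (the Wasserman-Faust adjustment, making values comparable across
#' components; isolated nodes score 0); and mean neighbour degree (NC,
#' "network centrality"; 0 for isolated nodes). Medians over all nodes are
#' attached and serve as the default hub cutoffs.
#'
#' @param net a non-empty [interaction_network].
#' @return A data frame (class `centrality_table`) with columns
#'   `node, dc, bc, cc, nc`, rows ordered by node id, and attribute
#'   `medians` (named numeric of the four column medians).
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  n <- n_nodes(net)
  if (n == 0L) stop("cannot compute centralities of an empty network")
  g <- as_igraph(net)
  ids <- igraph::V(g)$name

  dc <- igraph::degree(g)
  bc <- if (n < 3L) rep(0, n) else
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)

  d <- igraph::distances(g)
  comp <- igraph::components(g)$membership
  cc <- numeric(n)
  for (i in seq_len(n)) {
    same <- comp == comp[i]
    nc_comp <- sum(same)
    if (nc_comp > 1L) {
      cc[i] <- ((nc_comp - 1) / sum(d[i, same])) * ((nc_comp - 1) / (n - 1))
    }
  }

  knn <- igraph::knn(g)$knn
  knn[!is.finite(knn)] <- 0

  out <- data.frame(node = ids, dc = as.numeric(dc), bc = as.numeric(bc),
                    cc = cc, nc = as.numeric(knn), stringsAsFactors = FALSE)
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "medians") <- c(dc = median(out$dc), bc = median(out$bc),
                            cc = median(out$cc), nc = median(out$nc))
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' @export
print.centrality_table <- function(x, ...) {
  med <- attr(x, "medians")
  cat("Centrality table: ", nrow(x), " nodes\n", sep = "")
  cat(sprintf("  medians: DC %g, BC %.9g, CC %.7g, NC %.4g\n",
              med["dc"], med["bc"], med["cc"], med["nc"]))
  NextMethod()
}

#' Extract hub nodes above centrality cutoffs
#'
#' A node is a hub when its degree, betweenness and closeness all strictly
#' exceed their cutoffs (the table medians by default, the conventional
#' median-threshold screen). The mean-neighbour-degree median can be added
#' as a fourth condition with `use_nc = TRUE`; it is reported either way.
#'
#' @param ct a [centralities()] table.
#' @param dc_cutoff,bc_cutoff,cc_cutoff,nc_cutoff numeric cutoffs;
#'   `NULL` means the corresponding table median.
#' @param use_nc logical; also require `nc > nc_cutoff`.
#' @param strict logical; strict `>` (default) versus `>=`.
#' @return A list with `hubs` (lexicographically sorted character vector)
#'   and `cutoffs` (named numeric of the cutoffs applied).
#' @export
extract_hubs <- function(ct, dc_cutoff = NULL, bc_cutoff = NULL,
                         cc_cutoff = NULL, nc_cutoff = NULL,
                         use_nc = FALSE, strict = TRUE) {
  stopifnot(inherits(ct, "centrality_table"), nrow(ct) > 0L)
  med <- attr(ct, "medians")
  cuts <- c(dc = dc_cutoff %||% med[["dc"]],
            bc = bc_cutoff %||% med[["bc"]],
            cc = cc_cutoff %||% med[["cc"]],
            nc = nc_cutoff %||% med[["nc"]])
  gt <- if (strict) `>` else `>=`
  keep <- gt(ct$dc, cuts["dc"]) & gt(ct$bc, cuts["bc"]) & gt(ct$cc, cuts["cc"])
  if (use_nc) keep <- keep & gt(ct$nc, cuts["nc"])
  list(hubs = sort(ct$node[keep]),
       cutoffs = if (use_nc) cuts else cuts[c("dc", "bc", "cc")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an interaction edge list
#'
#' Accepts 2-column TSV (`nodeA  nodeB`) or 3-column SIF-style files
#' (`nodeA  interaction  nodeB`; the middle column is ignored). Lines are
#' not deduplicated here; network constructors do that.
#'
#' @param path file path.
#' @return Data frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  if (ncol(x) >= 3L) x <- x[, c(1L, 3L)]
  if (ncol(x) < 2L) stop("edge list must have at least two columns: ", path)
  setNames(x[, 1:2], c("from", "to"))
}

#' Write a centrality table as TSV
#'
#' @param ct a [centralities()] table.
#' @param path output path; columns `node,dc,bc,cc,nc`.
#' @export
write_centrality_table <- function(ct, path) {
  utils::write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
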