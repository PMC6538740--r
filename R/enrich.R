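#' Gene-set collections
#'
#' A collection holds named member sets (pathways, metabolite sets, ...)
#' with optional descriptions and a background universe. The universe
#' defaults to the union of all members; members outside a supplied
#' universe are dropped with a warning so the containment invariant holds.
#'
#' @param sets named list of character member vectors; names are term ids.
#' @param descriptions optional named character vector of term names.
#' @param universe optional character vector of background ids.
#' @return Object of class `gene_set_collection` with elements `sets`,
#'   `descriptions`, `universe`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be a non-empty list with unique names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(as.character(universe))
    out <- vapply(sets, function(s) sum(!(s %in% universe)), integer(1))
    if (sum(out) > 0) {
      warning(sum(out), " member id(s) outside the universe dropped")
      sets <- lapply(sets, function(s) s[s %in% universe])
    }
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(names(sets), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
    descriptions[is.na(descriptions)] <- names(sets)[is.na(descriptions)]
    names(descriptions) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection: ", length(x$sets), " terms, universe of ",
      length(x$universe), " ids\n", sep = "")
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ hypergeometric: `k` of the `n` drawn ids fall in a
#' category of size `K` within a universe of size `N`. Returns 1 when
#' `k = 0`. This is the standard over-representation p-value.
#'
#' @param k overlap count; `0 <= k <= min(K, n)`.
#' @param K category (term) size; `n` query size; `N` universe size.
#' @param n,N see above; `K <= N`, `n <= N`.
#' @return The upper-tail probability in (0, 1].
#' @examples
#' hypergeom_tail(5, 5, 5, 10)  # 1/choose(10, 5)
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(!is.finite(c(k, K, n, N))) || k < 0 || K < 0 || n < 0 ||
      K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric parameters (need 0 <= k <= min(K, n), K, n <= N)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment, returned in input order (a thin wrapper over
#' `stats::p.adjust(method = "BH")` with input validation).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis (ORA)
#'
#' Tests a query id set against every term of a collection with the
#' hypergeometric upper tail (optionally DAVID's EASE variant, which
#' discounts one overlapping id), adjusts across the tested terms with
#' Benjamini-Hochberg, and flags terms with q below the cutoff. Terms with
#' zero overlap are not tested and do not count towards the number of
#' tests. Query ids outside the universe are dropped with a warning.
#'
#' @param query character vector of query ids.
#' @param collection a [gene_set_collection()].
#' @param ease logical; use the EASE score (tail at k - 1).
#' @param q_cutoff enrichment call threshold on the q-value.
#' @return Data frame `term_id, term_name, k, K, n, N, p, q, enriched`,
#'   sorted by q then p then term id.
#' @export
ora <- function(query, collection, ease = FALSE, q_cutoff = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- !(query %in% collection$universe)
  if (any(outside)) {
    warning(sum(outside), " query id(s) outside the universe dropped")
    query <- query[!outside]
  }
  if (!length(query)) stop("empty query after universe filtering")

  N <- length(collection$universe)
  n <- length(query)
  k <- vapply(collection$sets, function(s) sum(query %in% s), integer(1))
  K <- lengths(collection$sets)
  tested <- k >= 1L
  if (!any(tested))
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      enriched = logical(0)))
  kk <- k[tested]
  if (ease) kk <- pmax(kk - 1L, 0L)
  p <- mapply(hypergeom_tail, kk, K[tested], MoreArgs = list(n = n, N = N))
  q <- bh_adjust(p)
  out <- data.frame(
    term_id = names(collection$sets)[tested],
    term_name = unname(collection$descriptions[tested]),
    k = k[tested], K = unname(K[tested]), n = n, N = N,
    p = unname(p), q = q, enriched = q < q_cutoff,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$q, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write GMT gene-set files
#'
#' GMT is tab-separated: term id, description, then member ids. The reader
#' keeps the description column (which is why a dedicated reader is used);
#' the writer emits the same dialect.
#'
#' @param path file path.
#' @param universe optional universe passed to [gene_set_collection()].
#' @return `read_gmt`: a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("GMT lines need at least 3 fields: ", path)
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- setNames(vapply(parts, `[[`, character(1), 2L), ids)
  sets <- setNames(lapply(parts, function(f) f[-(1:2)]), ids)
  gene_set_collection(sets, descriptions = desc, universe = universe)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()] to write.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an ORA result table as TSV
#'
#' @param result an [ora()] result.
#' @param path output path.
#' @export
write_ora <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
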