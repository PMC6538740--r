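#' ADME screening of herbal compound tables
#'
#' Retains compounds whose oral bioavailability (OB, percent) and
#' drug-likeness (DL) both exceed their thresholds — by default the
#' conventional OB > 30% and DL > 0.18 screen, with strict inequalities.
#' Tables are in long format (one row per compound-herb pair; a compound
#' shared by several herbs repeats with identical OB/DL), so per-herb
#' retained counts may sum to more than the distinct retained total.
#' Rows with missing OB or DL are excluded with a warning and counted.
#'
#' @param table data frame with columns `compound_id`, `name`, `herb`,
#'   `ob`, `dl`.
#' @param ob_threshold,dl_threshold screening thresholds.
#' @param strict logical; strict `>` (default) or `>=` comparisons.
#' @return An object of class `adme_screen`: list with `retained` (the
#'   retained rows, input order preserved), `compounds` (distinct retained
#'   compound ids, first-appearance order), `herb_counts` (named integer,
#'   one count per herb a retained compound belongs to), `n_input`,
#'   `n_retained`, `n_excluded_missing` and `criteria`.
#' @examples
#' tab <- data.frame(compound_id = c("a", "b"), name = c("a", "b"),
#'                   herb = "h", ob = c(35, 30), dl = c(0.2, 0.5))
#' screen_compounds(tab)$compounds  # "a" only: OB = 30 fails strict >
#' @export
screen_compounds <- function(table, ob_threshold = 30, dl_threshold = 0.18,
                             strict = TRUE) {
  req <- c("compound_id", "herb", "ob", "dl")
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("compound table must be a non-empty data frame")
  if (!all(req %in% names(table)))
    stop("compound table needs columns: ", paste(req, collapse = ", "))
  per_herb_key <- paste(table$compound_id, table$herb, sep = "\r")
  if (anyDuplicated(per_herb_key))
    stop("duplicate compound_id within a herb")
  stopifnot(is.finite(ob_threshold), is.finite(dl_threshold))

  missing <- !is.finite(table$ob) | !is.finite(table$dl)
  if (any(missing)) {
    warning(sum(missing), " row(s) with missing OB or DL excluded from screening")
    table_ok <- table[!missing, , drop = FALSE]
  } else {
    table_ok <- table
  }

  gt <- if (strict) `>` else `>=`
  keep <- gt(table_ok$ob, ob_threshold) & gt(table_ok$dl, dl_threshold)
  retained <- table_ok[keep, , drop = FALSE]
  compounds <- unique(retained$compound_id)
  herb_counts <- if (nrow(retained)) {
    tab <- table(retained$herb)
    setNames(as.integer(tab), names(tab))
  } else {
    setNames(integer(0), character(0))
  }

  structure(
    list(retained = retained,
         compounds = compounds,
         herb_counts = herb_counts,
         n_input = length(unique(table$compound_id)),
         n_retained = length(compounds),
         n_excluded_missing = sum(missing),
         criteria = list(ob_threshold = ob_threshold,
                         dl_threshold = dl_threshold, strict = strict)),
    class = "adme_screen"
  )
}

#' @export
print.adme_screen <- function(x, ...) {
  op <- if (x$criteria$strict) ">" else ">="
  cat("ADME screen: OB ", op, " ", x$criteria$ob_threshold,
      "%, DL ", op, " ", x$criteria$dl_threshold, "\n", sep = "")
  cat("  ", x$n_retained, " of ", x$n_input, " compounds retained\n", sep = "")
  if (length(x$herb_counts))
    cat("  per herb: ", paste(names(x$herb_counts), x$herb_counts,
                              sep = " = ", collapse = ", "), "\n", sep = "")
  if (x$n_excluded_missing)
    cat("  ", x$n_excluded_missing, " row(s) excluded for missing OB/DL\n", sep = "")
  invisible(x)
}

#' Union of targets over retained compounds
#'
#' @param screen an [screen_compounds()] result, or a character vector of
#'   compound ids.
#' @param mapping compound-to-target mapping: named list or data frame with
#'   columns `compound_id`, `target`.
#' @return List with `targets` (sorted deduplicated union) and `covered`
#'   (number of retained compounds having at least one target).
#' @export
union_compound_targets <- function(screen, mapping) {
  ids <- if (inherits(screen, "adme_screen")) screen$compounds
         else unique(as.character(screen))
  mapping <- as_target_list(mapping)
  hit <- mapping[intersect(ids, names(mapping))]
  hit <- hit[lengths(hit) > 0L]
  list(targets = sort(as.character(unique(unlist(hit, use.names = FALSE)))),
       covered = length(hit))
}

#' Read a compound table (CSV or TSV)
#'
#' Requires columns `compound_id,name,herb,ob,dl`; multiple rows per
#' compound are allowed (one per herb). The separator is inferred from the
#' file extension (`.tsv`/`.tab` = tab, otherwise comma).
#'
#' @param path file path.
#' @return Data frame in the long compound-herb format.
#' @export
read_compound_table <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  x <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, quote = "\"")
  req <- c("compound_id", "name", "herb", "ob", "dl")
  if (!all(req %in% names(x)))
    stop("compound table ", path, " needs columns: ", paste(req, collapse = ", "))
  x
}
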