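#' Abundance bookkeeping for richness estimators
#'
#' Summarises one sample's counts into the quantities the nonparametric
#' richness estimators use: observed taxa `S_obs`, total count `N`, the
#' frequency-of-frequencies `F_i` (number of taxa observed exactly `i`
#' times), and the rare/abundant partition at `rare_cutoff` (`N_rare`,
#' `S_rare`, `S_abund`). Identities `sum(F_i) = S_obs` and
#' `sum(i * F_i) = N` hold by construction.
#'
#' @param x nonnegative integer vector of counts for one sample.
#' @param rare_cutoff abundance at or below which a taxon counts as rare.
#' @return List with `S_obs`, `N`, `F` (named vector, names are `i`),
#'   `N_rare`, `S_rare`, `S_abund`, `rare_cutoff`.
#' @export
abundance_summary <- function(x, rare_cutoff = 10) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("counts must be nonnegative integers")
  x <- x[x > 0]
  if (!length(x)) stop("sample has no nonzero counts")
  tab <- table(x)
  f <- setNames(as.integer(tab), names(tab))
  rare <- x <= rare_cutoff
  list(S_obs = length(x), N = sum(x), F = f,
       N_rare = sum(x[rare]), S_rare = sum(rare), S_abund = sum(!rare),
       rare_cutoff = rare_cutoff)
}

f_of <- function(summ, i) {
  v <- unname(summ$F[as.character(i)])
  ifelse(is.na(v), 0L, v)
}

#' Shannon diversity index
#'
#' `H = -sum (x_i/N) * log(x_i/N)` over nonzero counts; natural log by
#' default (the mothur convention), log2 via `base = 2`.
#'
#' @param x nonnegative counts for one sample (at least one nonzero).
#' @param base logarithm base.
#' @return The Shannon index.
#' @examples
#' shannon_index(rep(5, 8))  # log(8)
#' @export
shannon_index <- function(x, base = exp(1)) {
  if (any(!is.finite(x)) || any(x < 0)) stop("counts must be nonnegative")
  x <- x[x > 0]
  if (!length(x)) stop("sample has no nonzero counts")
  p <- x / sum(x)
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimator
#'
#' Bias-corrected by default (the mothur default):
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))`; the classic form
#' `S_obs + F1^2 / (2 * F2)` (requiring `F2 > 0`) via
#' `bias_corrected = FALSE`. With no singletons the estimate is `S_obs`.
#'
#' @param x counts for one sample, or an [abundance_summary()].
#' @param bias_corrected logical.
#' @return The Chao1 estimate (always >= `S_obs`).
#' @examples
#' chao1(c(1, 1, 2), bias_corrected = FALSE)  # 5
#' chao1(c(1, 1, 2))                          # 3.5
#' @export
chao1 <- function(x, bias_corrected = TRUE) {
  summ <- if (is.list(x)) x else abundance_summary(x)
  f1 <- f_of(summ, 1L)
  f2 <- f_of(summ, 2L)
  if (f1 == 0) return(as.numeric(summ$S_obs))
  if (bias_corrected) {
    summ$S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) summ$S_obs + f1 * (f1 - 1) / 2  # classic form degenerates; Chao's limit
    else summ$S_obs + f1^2 / (2 * f2)
  }
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator with rare cutoff 10 (the standard
#' choice): sample coverage `C = 1 - F1/N_rare`, coefficient of variation
#' `gamma^2 = max(S_rare * sum(i*(i-1)*F_i) / (C * N_rare * (N_rare - 1)) - 1, 0)`
#' over the rare taxa, and `ACE = S_abund + S_rare/C + (F1/C) * gamma^2`.
#' When every rare taxon is a singleton the coverage is 0 and the function
#' falls back to [chao1()] with a warning. With no rare taxa, ACE equals
#' the observed richness.
#'
#' @param x counts for one sample, or an [abundance_summary()].
#' @param rare_cutoff rare-taxon abundance cutoff (ignored if `x` is
#'   already a summary).
#' @return The ACE estimate.
#' @export
ace <- function(x, rare_cutoff = 10) {
  summ <- if (is.list(x)) x else abundance_summary(x, rare_cutoff)
  if (summ$S_rare == 0) return(as.numeric(summ$S_obs))
  f1 <- f_of(summ, 1L)
  C <- 1 - f1 / summ$N_rare
  if (C == 0) {
    warning("all rare taxa are singletons (coverage 0); falling back to Chao1")
    return(chao1(summ))
  }
  i <- seq_len(summ$rare_cutoff)
  fi <- vapply(i, function(j) as.numeric(f_of(summ, j)), numeric(1))
  denom <- C * summ$N_rare * (summ$N_rare - 1)
  g2 <- if (denom > 0) max(summ$S_rare * sum(i * (i - 1) * fi) / denom - 1, 0) else 0
  summ$S_abund + summ$S_rare / C + (f1 / C) * g2
}

#' Per-sample alpha diversity of a count table
#'
#' @param ct a `count_table` (see [gen_otu_table()] or [read_count_table()]).
#' @param rare_cutoff ACE rare cutoff.
#' @param base Shannon logarithm base.
#' @return Data frame `sample_id, group, S_obs, N, shannon, chao1, ace`.
#' @export
alpha_diversity <- function(ct, rare_cutoff = 10, base = exp(1)) {
  stopifnot(inherits(ct, "count_table"))
  rows <- lapply(seq_len(nrow(ct$counts)), function(s) {
    x <- ct$counts[s, ]
    summ <- abundance_summary(x, rare_cutoff)
    data.frame(sample_id = ct$samples$sample_id[s],
               group = ct$samples$group[s],
               S_obs = summ$S_obs, N = summ$N,
               shannon = shannon_index(x, base = base),
               chao1 = chao1(summ),
               ace = ace(summ),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

aggregate_to_rank <- function(ct, rank) {
  if (rank == "taxon_id" || rank == "otu") return(ct$counts)
  if (!(rank %in% names(ct$taxonomy)))
    stop("rank '", rank, "' absent from the taxonomy lineage")
  lin <- ct$taxonomy[[rank]][match(colnames(ct$counts), ct$taxonomy$taxon_id)]
  if (anyNA(lin)) stop("taxa missing lineage at rank '", rank, "'")
  t(rowsum(t(ct$counts), group = lin))
}

#' Group-wise differential abundance by Wilcoxon rank-sum
#'
#' Aggregates counts to the requested taxonomic rank, converts to
#' per-sample relative abundances, and tests each taxon between the two
#' groups with a two-sided Wilcoxon rank-sum test: exact when both groups
#' have at most 10 samples and the abundances carry no ties, otherwise the
#' normal approximation with tie and continuity correction. P-values are
#' Benjamini-Hochberg adjusted; the effect direction is the difference of
#' group mean relative abundances (A minus B). A Kruskal-Wallis test
#' across more than two groups is available via `method = "kruskal"`.
#'
#' @param ct a `count_table`.
#' @param rank lineage rank to aggregate to (`"species"`, `"genus"`, ...,
#'   or `"otu"` for no aggregation).
#' @param group_a,group_b the two group labels to compare.
#' @param method `"wilcoxon"` (two groups) or `"kruskal"` (all groups).
#' @param exact_max largest per-group size at which the exact test is used.
#' @return Data frame `taxon, p, q, mean_a, mean_b, direction` sorted by q
#'   then p (for `kruskal`: `taxon, statistic, df, p, q`).
#' @export
diff_abundance <- function(ct, rank = "species", group_a = "treatment",
                           group_b = "control",
                           method = c("wilcoxon", "kruskal"),
                           exact_max = 10L) {
  method <- match.arg(method)
  stopifnot(inherits(ct, "count_table"))
  counts <- aggregate_to_rank(ct, rank)
  rel <- counts / rowSums(counts)

  if (method == "kruskal") {
    g <- factor(ct$samples$group)
    if (nlevels(g) < 2L) stop("need at least 2 groups")
    res <- apply(rel, 2L, function(v) {
      kt <- stats::kruskal.test(v, g)
      c(kt$statistic, kt$parameter, kt$p.value)
    })
    out <- data.frame(taxon = colnames(rel), statistic = res[1, ],
                      df = res[2, ], p = res[3, ], q = bh_adjust(res[3, ]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$q, out$p, out$taxon), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }

  ia <- ct$samples$group == group_a
  ib <- ct$samples$group == group_b
  if (sum(ia) < 2L || sum(ib) < 2L)
    stop("need at least 2 samples per compared group")
  res <- apply(rel, 2L, function(v) {
    x <- v[ia]; y <- v[ib]
    ties <- anyDuplicated(c(x, y)) > 0L
    use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
    c(p, mean(x), mean(y))
  })
  out <- data.frame(taxon = colnames(rel), p = res[1, ], q = bh_adjust(res[1, ]),
                    mean_a = res[2, ], mean_b = res[3, ],
                    direction = res[2, ] - res[3, ],
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a count table from TSV files
#'
#' The count file has taxa as rows and samples as columns (first column =
#' taxon id); sample metadata is a TSV `sample_id, group`; the taxonomy
#' TSV has `taxon_id` plus lineage rank columns (domain ... species).
#'
#' @param counts_path,metadata_path,taxonomy_path file paths.
#' @return A `count_table`.
#' @export
read_count_table <- function(counts_path, metadata_path, taxonomy_path) {
  raw <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  taxa <- raw[[1]]
  counts <- t(as.matrix(raw[, -1, drop = FALSE]))
  colnames(counts) <- taxa
  meta <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata needs columns sample_id, group")
  taxonomy <- utils::read.table(taxonomy_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  if (!("taxon_id" %in% names(taxonomy)))
    stop("taxonomy needs a taxon_id column")
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing samples present in counts")
  structure(list(counts = counts, samples = meta, taxonomy = taxonomy),
            class = "count_table")
}

#' Write a count table to TSV files
#'
#' @param ct a `count_table`.
#' @param counts_path,metadata_path,taxonomy_path output paths.
#' @export
write_count_table <- function(ct, counts_path, metadata_path, taxonomy_path) {
  stopifnot(inherits(ct, "count_table"))
  df <- data.frame(taxon_id = colnames(ct$counts), t(ct$counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ct$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ct$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}
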