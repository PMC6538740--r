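#' Simulate a herbal compound table with a planted ADME pass count
#'
#' Draws oral bioavailability (OB, percent) log-normally and drug-likeness
#' (DL) from a beta distribution, then rejection-adjusts individual rows so
#' that exactly `round(frac_pass_adme * n_compounds)` compounds satisfy the
#' screen OB > 30 and DL > 0.18. Herb labels are assigned round-robin over
#' the four herbs of the formula.
#'
#' @param spec a [sim_spec()].
#' @return A data frame with columns `compound_id`, `name`, `herb`, `ob`,
#'   `dl` (one row per compound) and attribute `planted_pass`, the ids of
#'   the compounds planted to pass the screen.
#' @export
gen_compound_table <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(sub_seed(spec, 101L))
  n <- spec$n_compounds
  n_pass <- round(spec$frac_pass_adme * n)
  herbs <- c("Radix_Puerariae", "Scutellariae_Radix", "Coptidis_Rhizoma", "Liquorice")

  ob <- rlnorm(n, meanlog = log(25), sdlog = 0.8)
  dl <- rbeta(n, 2, 5)
  pass_idx <- sample.int(n, n_pass)
  is_pass <- seq_len(n) %in% pass_idx

  # rejection-adjust: resample until each row is on its planted side
  for (i in seq_len(n)) {
    if (is_pass[i]) {
      while (!(ob[i] > 30 && dl[i] > 0.18)) {
        ob[i] <- rlnorm(1, log(45), 0.4)
        dl[i] <- rbeta(1, 4, 5)
      }
    } else if (ob[i] > 30 && dl[i] > 0.18) {
      if (runif(1) < 0.5) ob[i] <- runif(1, 2, 29.5) else dl[i] <- runif(1, 0.01, 0.175)
    }
  }

  ids <- sprintf("C%04d", seq_len(n))
  out <- data.frame(
    compound_id = ids,
    name = paste0("compound_", seq_len(n)),
    herb = herbs[((seq_len(n) - 1L) %% 4L) + 1L],
    ob = ob,
    dl = dl,
    stringsAsFactors = FALSE
  )
  attr(out, "planted_pass") <- ids[is_pass]
  out
}

#' Simulate a scale-free PPI network by preferential attachment
#'
#' Grows a connected simple undirected graph: `ppi_attach_edges` (= m) seed
#' nodes start edgeless; each of the remaining `ppi_nodes - m` nodes attaches
#' to m distinct existing nodes chosen with probability proportional to
#' degree + 1. Total edge count is therefore exactly `m * (ppi_nodes - m)`.
#' The m earliest nodes, which accumulate the highest expected degree, are
#' recorded as planted hubs.
#'
#' @param spec a [sim_spec()].
#' @return An [interaction_network] of kind `protein` with attribute
#'   `planted_hubs` (character ids of the m earliest nodes).
#' @export
gen_ppi <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(sub_seed(spec, 211L))
  n <- spec$ppi_nodes
  m <- spec$ppi_attach_edges
  ids <- sprintf("P%03d", seq_len(n))

  deg <- integer(n)
  from <- integer(m * (n - m))
  to <- integer(m * (n - m))
  k <- 0L
  for (i in (m + 1L):n) {
    tgt <- sample.int(i - 1L, m, prob = deg[seq_len(i - 1L)] + 1)
    for (j in tgt) {
      k <- k + 1L
      from[k] <- j
      to[k] <- i
      deg[j] <- deg[j] + 1L
    }
    deg[i] <- deg[i] + m
  }

  net <- interaction_network(
    nodes = data.frame(id = ids, kind = "protein", stringsAsFactors = FALSE),
    edges = data.frame(from = ids[from], to = ids[to], stringsAsFactors = FALSE)
  )
  attr(net, "planted_hubs") <- ids[seq_len(m)]
  net
}

#' Simulate a gene-set collection with planted enriched terms
#'
#' Builds `n_gene_sets` terms of 30-80 members over a 2000-gene universe and
#' emits a query list constructed so that each planted term contributes 60%
#' of its members; the remainder of the query is drawn uniformly from the
#' universe. With no planted terms the query is entirely random, giving a
#' null collection for calibration runs.
#'
#' @param spec a [sim_spec()].
#' @param universe optional character vector of member ids to draw from
#'   (defaults to `sprintf("G%04d", 1:2000)`).
#' @param query_size number of ids in the emitted query list.
#' @return A list with elements `collection` (a [gene_set_collection]),
#'   `query` (character) and `planted` (the planted term ids).
#' @export
gen_gene_sets <- function(spec, universe = sprintf("G%04d", 1:2000),
                          query_size = 150L) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(sub_seed(spec, 307L))
  ids <- sprintf("GS%02d", seq_len(spec$n_gene_sets))
  sizes <- sample(30:80, spec$n_gene_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(universe, s))
  names(sets) <- ids

  planted <- spec$planted_enriched_terms
  query <- character(0)
  for (tm in planted) {
    memb <- sets[[tm]]
    query <- c(query, sample(memb, ceiling(0.6 * length(memb))))
  }
  query <- unique(query)
  n_fill <- max(0L, query_size - length(query))
  query <- unique(c(query, sample(setdiff(universe, query), n_fill)))

  list(
    collection = gene_set_collection(
      sets,
      descriptions = setNames(paste0("simulated pathway ", seq_along(ids)), ids),
      universe = universe
    ),
    query = sort(query),
    planted = planted
  )
}

# one Dirichlet draw per row of alpha
rdirichlet_rows <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Simulate an OTU count table with planted differential taxa
#'
#' Per-sample counts are Dirichlet-multinomial: base proportions are drawn
#' log-normally and normalised, a Dirichlet draw with precision 200 adds
#' overdispersion, and 20000 reads are allocated multinomially. In the
#' treatment group the base proportions of `n_diff_taxa` planted taxa
#' (sampled among the more abundant half, so the signal is detectable at
#' realistic depth) are multiplied by `taxon_fold_change` and renormalised.
#'
#' @param spec a [sim_spec()].
#' @param reads_per_sample sequencing depth per sample.
#' @param precision Dirichlet precision (smaller = more overdispersion).
#' @return A `count_table`: list with `counts` (samples x taxa integer
#'   matrix), `samples` (`sample_id`, `group`), `taxonomy` (lineage ranks
#'   domain..species per taxon), plus attribute `planted_taxa`.
#' @export
gen_otu_table <- function(spec, reads_per_sample = 20000L, precision = 200) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(sub_seed(spec, 401L))
  nt <- spec$n_taxa
  ng <- spec$n_samples_per_group
  taxa <- sprintf("OTU%03d", seq_len(nt))

  base <- rlnorm(nt, 0, 1)
  base <- base / sum(base)
  abundant <- which(base >= median(base))
  planted <- sort(sample(abundant, min(spec$n_diff_taxa, length(abundant))))

  p_ctrl <- base
  p_trt <- base
  p_trt[planted] <- p_trt[planted] * spec$taxon_fold_change
  p_trt <- p_trt / sum(p_trt)

  groups <- rep(c("control", "treatment"), each = ng)
  counts <- matrix(0L, nrow = 2L * ng, ncol = nt)
  for (s in seq_len(2L * ng)) {
    p <- if (groups[s] == "control") p_ctrl else p_trt
    q <- rdirichlet_rows(1, precision * p)[1, ]
    counts[s, ] <- as.integer(rmultinom(1, reads_per_sample, q))
  }
  sample_ids <- sprintf("S%02d", seq_len(2L * ng))
  dimnames(counts) <- list(sample_ids, taxa)

  phylum <- paste0("p__Phylum", ((seq_len(nt) - 1L) %/% 12L) + 1L)
  genus <- paste0("g__Genus", ((seq_len(nt) - 1L) %/% 3L) + 1L)
  taxonomy <- data.frame(
    taxon_id = taxa,
    domain = "d__Bacteria",
    phylum = phylum,
    class = paste0("c__Class", ((seq_len(nt) - 1L) %/% 12L) + 1L),
    order = paste0("o__Order", ((seq_len(nt) - 1L) %/% 6L) + 1L),
    family = paste0("f__Family", ((seq_len(nt) - 1L) %/% 6L) + 1L),
    genus = genus,
    species = paste0("s__", taxa),
    stringsAsFactors = FALSE
  )

  out <- structure(
    list(counts = counts,
         samples = data.frame(sample_id = sample_ids, group = groups,
                              stringsAsFactors = FALSE),
         taxonomy = taxonomy),
    class = "count_table"
  )
  attr(out, "planted_taxa") <- taxa[planted]
  out
}

#' Simulate a metabolite intensity matrix with planted shifted features
#'
#' Feature log2 intensities are Gaussian around feature-specific baselines
#' (uniform on 10-20 log2 units, within-group SD 0.6); planted features gain
#' `metabolite_log2_shift` in the treatment group. Pooled QC injections are
#' emitted as the global mean profile plus small noise (SD 0.2), mirroring
#' the tight QC clustering expected in PCA score plots.
#'
#' @param spec a [sim_spec()].
#' @param n_qc number of pooled QC samples.
#' @return An `intensity_matrix`: list with `intensities` (samples x
#'   features, positive reals), `samples` (`sample_id`, `group`, `is_qc`),
#'   plus attribute `planted_features`.
#' @export
gen_metabolome <- function(spec, n_qc = 4L) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(sub_seed(spec, 503L))
  p <- spec$n_metabolites
  ng <- spec$n_samples_per_group
  features <- sprintf("M%04d", seq_len(p))
  baseline <- runif(p, 10, 20)
  planted <- sort(sample.int(p, spec$n_diff_metabolites))

  groups <- rep(c("control", "treatment"), each = ng)
  log2x <- matrix(rnorm(2L * ng * p, sd = 0.6), nrow = 2L * ng, ncol = p,
                  byrow = FALSE) + rep(baseline, each = 2L * ng)
  log2x[groups == "treatment", planted] <-
    log2x[groups == "treatment", planted] + spec$metabolite_log2_shift

  qc <- matrix(numeric(0), nrow = 0, ncol = p)
  if (n_qc > 0L) {
    qc_profile <- colMeans(log2x)
    qc <- matrix(rnorm(n_qc * p, sd = 0.2), nrow = n_qc, ncol = p) +
      matrix(qc_profile, nrow = n_qc, ncol = p, byrow = TRUE)
  }

  x <- rbind(log2x, qc)
  sample_ids <- c(sprintf("S%02d", seq_len(2L * ng)), sprintf("QC%02d", seq_len(n_qc)))
  dimnames(x) <- list(sample_ids, features)

  out <- structure(
    list(intensities = 2^x,
         samples = data.frame(
           sample_id = sample_ids,
           group = c(groups, rep("QC", n_qc)),
           is_qc = c(rep(FALSE, 2L * ng), rep(TRUE, n_qc)),
           stringsAsFactors = FALSE
         )),
    class = "intensity_matrix"
  )
  attr(out, "planted_features") <- features[planted]
  out
}

#' Simulate longitudinal caliper measurements of xenograft tumours
#'
#' Volumes follow exponential growth `V0 * exp(r * multiplier * day)` per
#' arm, starting from a 50 mm^3 enrolment volume, with the base rate `r`
#' calibrated so the control arm (multiplier 1) reaches 8496 mm^3 on day 32.
#' Multiplicative log-normal noise with coefficient of variation `noise_cv`
#' (mean 1) is applied per observation. Volumes are converted back to
#' caliper length/width assuming a fixed width/length ratio of 0.8 under
#' `V = 0.5 * length * width^2`.
#'
#' @param spec a [sim_spec()].
#' @param days measurement days (days since first dose).
#' @return A data frame `mouse_id, arm, day, length_mm, width_mm` with
#'   attribute `multipliers` echoing the per-arm growth-rate multipliers.
#' @export
gen_growth_data <- function(spec, days = seq(0, 32, by = 4)) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(sub_seed(spec, 601L))
  v0 <- 50
  r <- log(8496 / v0) / 32
  s2 <- log(1 + spec$noise_cv^2)
  rho <- 0.8

  rows <- list()
  for (arm in names(spec$arms)) {
    mult <- spec$arms[[arm]]
    for (mouse in seq_len(spec$n_mice_per_arm)) {
      mid <- sprintf("%s_m%02d", arm, mouse)
      mu <- v0 * exp(r * mult * days)
      noise <- exp(rnorm(length(days), mean = -s2 / 2, sd = sqrt(s2)))
      v <- mu * noise
      len <- (2 * v / rho^2)^(1 / 3)
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = mid, arm = arm, day = days,
        length_mm = len, width_mm = rho * len,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "multipliers") <- spec$arms
  out
}

#' Map screened compounds to simulated protein targets
#'
#' Assigns each ADME-passing compound 1-8 targets sampled from the PPI
#' node set with probability proportional to degree (hubs are hit more
#' often, as in curated interactomes). A small fraction of compounds is
#' left without targets, mirroring real coverage gaps.
#'
#' @param spec a [sim_spec()].
#' @param compounds output of [gen_compound_table()].
#' @param network output of [gen_ppi()].
#' @return A data frame `compound_id, target` (long format).
#' @export
gen_target_map <- function(spec, compounds, network) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(sub_seed(spec, 701L))
  passers <- compounds$compound_id[compounds$ob > 30 & compounds$dl > 0.18]
  deg <- network_degrees(network)
  rows <- list()
  for (cid in passers) {
    if (runif(1) < 0.1) next  # uncovered compound
    k <- sample(1:8, 1)
    tg <- sample(names(deg), k, prob = deg + 1)
    rows[[length(rows) + 1L]] <- data.frame(compound_id = cid, target = tg,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(compound_id = character(0),
                                       target = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
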