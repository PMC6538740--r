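#' Simulation specification for the synthetic-data generators
#'
#' Bundles every knob of the synthetic-data module into one validated object.
#' All generators draw from substreams derived deterministically from `seed`,
#' so an identical spec yields byte-identical outputs across runs.
#'
#' Defaults emulate the study design the pipeline targets: a four-herb
#' compound table with a planted ADME pass fraction, a scale-free
#' protein-protein interaction (PPI) graph grown by preferential attachment
#' with the earliest nodes as planted hubs, gene-set collections with planted
#' enriched terms, Dirichlet-multinomial OTU counts with planted fold-changed
#' taxa, log-normal metabolite intensities with planted log2 shifts, and
#' exponential tumour growth with per-arm rate multipliers calibrated so the
#' control arm reaches 8.496 cm^3 on day 32 from a 50 mm^3 enrolment volume.
#'
#' @param seed integer root seed; all generator substreams derive from it.
#' @param n_compounds number of herbal chemicals to simulate.
#' @param frac_pass_adme proportion of compounds planted to pass the ADME
#'   screen (OB > 30 and DL > 0.18); the retained count is
#'   `round(frac_pass_adme * n_compounds)`.
#' @param ppi_nodes,ppi_attach_edges size and attachment parameter of the
#'   preferential-attachment PPI graph; requires
#'   `ppi_nodes > ppi_attach_edges >= 1`. The `ppi_attach_edges` earliest
#'   nodes are the planted hubs.
#' @param n_gene_sets number of terms in the simulated gene-set collection.
#' @param planted_enriched_terms character vector of term ids (among
#'   `sprintf("GS%02d", 1:n_gene_sets)`) planted as enriched in the emitted
#'   query list; may be empty for null simulations.
#' @param n_samples_per_group samples per group for the OTU and metabolite
#'   generators (>= 2).
#' @param n_taxa,n_diff_taxa,taxon_fold_change OTU table shape: total taxa,
#'   number of planted differential taxa, and the multiplicative fold change
#'   applied to their base proportions in the treatment group.
#' @param n_metabolites,n_diff_metabolites,metabolite_log2_shift intensity
#'   matrix shape: total features, planted differential features, and the
#'   log2 shift added to them in the treatment group.
#' @param arms named numeric vector of growth-rate multipliers, one per
#'   treatment arm; must contain a `control` arm with multiplier 1.
#' @param n_mice_per_arm mice per arm in the growth-curve generator.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   measurement noise on tumour volumes (>= 0).
#'
#' @return An object of class `sim_spec` (a validated list).
#' @examples
#' spec <- sim_spec(seed = 7, n_compounds = 100, frac_pass_adme = 0.29)
#' tab <- gen_compound_table(spec)
#' sum(tab$ob > 30 & tab$dl > 0.18)  # exactly 29
#' @export
sim_spec <- function(seed = 1L,
                     n_compounds = 476L,
                     frac_pass_adme = 0.29,
                     ppi_nodes = 300L,
                     ppi_attach_edges = 5L,
                     n_gene_sets = 40L,
                     planted_enriched_terms = c("GS01", "GS02", "GS03"),
                     n_samples_per_group = 12L,
                     n_taxa = 60L,
                     n_diff_taxa = 6L,
                     taxon_fold_change = 4,
                     n_metabolites = 200L,
                     n_diff_metabolites = 10L,
                     metabolite_log2_shift = 3,
                     arms = c(control = 1,
                              gqd_low = 1.005,
                              gqd_medium = 0.988,
                              gqd_high = 0.940,
                              pd1 = 0.892,
                              gqd_low_pd1 = 0.757,
                              gqd_medium_pd1 = 0.820,
                              gqd_high_pd1 = 0.817),
                     n_mice_per_arm = 12L,
                     noise_cv = 0.3) {
  spec <- list(
    seed = as.integer(seed),
    n_compounds = as.integer(n_compounds),
    frac_pass_adme = frac_pass_adme,
    ppi_nodes = as.integer(ppi_nodes),
    ppi_attach_edges = as.integer(ppi_attach_edges),
    n_gene_sets = as.integer(n_gene_sets),
    planted_enriched_terms = as.character(planted_enriched_terms),
    n_samples_per_group = as.integer(n_samples_per_group),
    n_taxa = as.integer(n_taxa),
    n_diff_taxa = as.integer(n_diff_taxa),
    taxon_fold_change = taxon_fold_change,
    n_metabolites = as.integer(n_metabolites),
    n_diff_metabolites = as.integer(n_diff_metabolites),
    metabolite_log2_shift = metabolite_log2_shift,
    arms = arms,
    n_mice_per_arm = as.integer(n_mice_per_arm),
    noise_cv = noise_cv
  )
  validate_sim_spec(spec)
  structure(spec, class = "sim_spec")
}

validate_sim_spec <- function(spec) {
  stop_spec <- function(msg) stop("invalid simulation spec: ", msg, call. = FALSE)
  counts <- c("n_compounds", "ppi_nodes", "ppi_attach_edges", "n_gene_sets",
              "n_samples_per_group", "n_taxa", "n_diff_taxa", "n_metabolites",
              "n_diff_metabolites", "n_mice_per_arm")
  for (nm in counts) {
    v <- spec[[nm]]
    if (length(v) != 1L || is.na(v) || v < 0L) stop_spec(paste(nm, "must be a single count >= 0"))
  }
  if (spec$n_compounds < 1L) stop_spec("n_compounds must be >= 1")
  if (is.na(spec$frac_pass_adme) || spec$frac_pass_adme < 0 || spec$frac_pass_adme > 1)
    stop_spec("frac_pass_adme must lie in [0, 1]")
  if (spec$ppi_attach_edges < 1L || spec$ppi_nodes <= spec$ppi_attach_edges)
    stop_spec("need ppi_nodes > ppi_attach_edges >= 1")
  if (spec$n_samples_per_group < 2L) stop_spec("n_samples_per_group must be >= 2")
  if (spec$n_diff_taxa > spec$n_taxa) stop_spec("n_diff_taxa exceeds n_taxa")
  if (spec$n_diff_metabolites > spec$n_metabolites)
    stop_spec("n_diff_metabolites exceeds n_metabolites")
  if (!is.finite(spec$taxon_fold_change) || spec$taxon_fold_change <= 0)
    stop_spec("taxon_fold_change must be a positive real")
  if (!is.finite(spec$noise_cv) || spec$noise_cv < 0)
    stop_spec("noise_cv must be >= 0")
  if (is.null(names(spec$arms)) || any(!nzchar(names(spec$arms))) ||
      anyDuplicated(names(spec$arms)))
    stop_spec("arms must be a uniquely named numeric vector")
  if (any(!is.finite(spec$arms)) || any(spec$arms <= 0))
    stop_spec("arm growth-rate multipliers must be positive")
  all_terms <- sprintf("GS%02d", seq_len(spec$n_gene_sets))
  if (length(spec$planted_enriched_terms) &&
      !all(spec$planted_enriched_terms %in% all_terms))
    stop_spec("planted_enriched_terms must be ids among the generated terms")
  invisible(spec)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Simulation spec (seed ", x$seed, ")\n", sep = "")
  cat("  compounds: ", x$n_compounds, " (", round(100 * x$frac_pass_adme, 1),
      "% planted to pass ADME)\n", sep = "")
  cat("  PPI: ", x$ppi_nodes, " nodes, attachment ", x$ppi_attach_edges, "\n", sep = "")
  cat("  gene sets: ", x$n_gene_sets, " (planted: ",
      paste(x$planted_enriched_terms, collapse = ", "), ")\n", sep = "")
  cat("  OTU: ", x$n_taxa, " taxa, ", x$n_diff_taxa, " differential at fold ",
      x$taxon_fold_change, ", n = ", x$n_samples_per_group, "/group\n", sep = "")
  cat("  metabolites: ", x$n_metabolites, ", ", x$n_diff_metabolites,
      " shifted by ", x$metabolite_log2_shift, " log2 units\n", sep = "")
  cat("  arms: ", paste(names(x$arms), collapse = ", "),
      " (", x$n_mice_per_arm, " mice/arm, CV ", x$noise_cv, ")\n", sep = "")
  invisible(x)
}

# Deterministic substream seed per generator; keeps every derived seed
# inside 32-bit integer range.
sub_seed <- function(spec, offset) {
  as.integer((as.double(spec$seed) * 7919 + offset) %% 2147483647)
}
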