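#' Write a complete simulated fixture directory
#'
#' Generates every input the pipeline consumes from one [sim_spec()] and
#' writes them in the dialects the readers accept: compound CSV, target-map
#' TSV, PPI edge TSV, disease-target list, GMT gene sets (over the PPI
#' protein universe, with two sets planted around the simulated hubs), OTU
#' TSVs, intensity CSV and measurement CSV, plus a `ground_truth.json`
#' recording the planted signals.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulated_fixtures <- function(spec, dir) {
  stopifnot(inherits(spec, "sim_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)

  compounds <- gen_compound_table(spec)
  utils::write.csv(compounds, p("compounds.csv"), row.names = FALSE, quote = FALSE)

  ppi <- gen_ppi(spec)
  utils::write.table(ppi$edges, p("ppi_edges.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  tmap <- gen_target_map(spec, compounds, ppi)
  utils::write.table(tmap, p("target_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # disease targets: planted hubs plus a degree-weighted sample, so the
  # compound-side and disease-side networks intersect on the hub region
  set.seed(sub_seed(spec, 811L))
  deg <- network_degrees(ppi)
  hubs <- attr(ppi, "planted_hubs")
  disease <- unique(c(hubs, sample(names(deg), min(60L, length(deg)),
                                   prob = deg + 1)))
  writeLines(sort(disease), p("disease_targets.txt"))

  # protein-set GMT: 2 sets planted around the hubs' neighbourhood
  set.seed(sub_seed(spec, 823L))
  nbr <- unique(c(ppi$edges$from[ppi$edges$to %in% hubs],
                  ppi$edges$to[ppi$edges$from %in% hubs], hubs))
  sets <- c(
    lapply(1:2, function(i) unique(c(hubs, sample(nbr, min(20L, length(nbr)))))),
    lapply(3:12, function(i) sample(names(deg), 25L))
  )
  names(sets) <- sprintf("PS%02d", seq_along(sets))
  write_gmt(gene_set_collection(sets, universe = names(deg)), p("protein_sets.gmt"))

  ct <- gen_otu_table(spec)
  write_count_table(ct, p("otu_counts.tsv"), p("otu_samples.tsv"),
                    p("otu_taxonomy.tsv"))

  im <- gen_metabolome(spec)
  write_intensity_matrix(im, p("intensities.csv"))

  growth <- gen_growth_data(spec)
  utils::write.csv(growth, p("measurements.csv"), row.names = FALSE, quote = FALSE)

  truth <- list(
    planted_pass = attr(compounds, "planted_pass"),
    planted_hubs = hubs,
    planted_taxa = attr(ct, "planted_taxa"),
    planted_features = attr(im, "planted_features"),
    arm_multipliers = as.list(spec$arms)
  )
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(dir)
}

#' Pipeline configuration
#'
#' Reads a YAML configuration (or accepts a list) naming the per-stage
#' input paths and analysis options, and fills documented defaults.
#'
#' @param x path to a YAML file, or a named list.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    ob_threshold = 30, dl_threshold = 0.18, strict = TRUE,
    expand_neighbors = TRUE, use_nc = FALSE,
    ease = FALSE, q_cutoff = 0.05,
    rank = "species", rare_cutoff = 10, log_base = exp(1),
    group_a = "treatment", group_b = "control",
    n_components = 2, log_transform = TRUE,
    control_arm = "control", day = 32, volume_units = "mm3",
    tgi_convention = "ratio_of_means",
    seed = 1L
  )
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = "pipeline_config")
}

require_paths <- function(cfg, stage, keys) {
  for (k in keys) {
    path <- cfg[[k]]
    if (is.null(path) || !file.exists(path))
      stop("stage '", stage, "': missing input file for '", k, "': ",
           if (is.null(path)) "<unset>" else path, call. = FALSE)
  }
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_manifest <- function(dir, cfg, inputs, outputs, warnings = character(0)) {
  manifest <- list(
    config = unclass(cfg),
    input_md5 = as.list(setNames(tools::md5sum(inputs), basename(inputs))),
    output_md5 = as.list(setNames(tools::md5sum(outputs), basename(outputs))),
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the network-pharmacology flow
#'
#' Screens the compound table, unions the compound targets, builds the
#' compound-target bipartite network and the two PPI networks (compound
#' targets and disease targets, each with optional first-neighbour
#' expansion), intersects them, computes centralities, extracts median-
#' threshold hubs, and runs over-representation of the hub set against the
#' GMT collection. All stage outputs land in `out_dir` as TSV plus a
#' `manifest.json` with the configuration and input/output checksums (no
#' timestamps, so reruns are byte-identical) and a `summary.json` of
#' headline counts.
#'
#' @param cfg a [pipeline_config()] (or list/path coerced by it) with paths
#'   `compounds`, `target_map`, `ppi_edges`, `disease_targets`, `gene_sets`.
#' @param out_dir output directory.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_netpharm <- function(cfg, out_dir) {
  cfg <- pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warns <- character(0)
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
  })

  require_paths(cfg, "screen", "compounds")
  screen <- run_stage("screen", wcollect({
    tab <- read_compound_table(cfg$compounds)
    screen_compounds(tab, cfg$ob_threshold, cfg$dl_threshold, cfg$strict)
  }))
  utils::write.table(screen$retained, file.path(out_dir, "screened_compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  require_paths(cfg, "targets", "target_map")
  tmap <- run_stage("targets", utils::read.table(cfg$target_map, sep = "\t",
                                                 header = TRUE,
                                                 stringsAsFactors = FALSE))
  un <- run_stage("targets", union_compound_targets(screen, tmap))
  writeLines(un$targets, file.path(out_dir, "compound_targets.txt"))

  ct_net <- run_stage("bipartite", wcollect({
    keep <- tmap$compound_id %in% screen$compounds
    build_bipartite(tmap[keep, , drop = FALSE])
  }))

  require_paths(cfg, "ppi", c("ppi_edges", "disease_targets"))
  edges <- run_stage("ppi", read_edge_list(cfg$ppi_edges))
  disease <- run_stage("ppi", readLines(cfg$disease_targets))
  disease <- sort(unique(disease[nzchar(disease)]))
  cmp_ppi <- run_stage("ppi", wcollect(
    build_ppi(un$targets, edges, cfg$expand_neighbors)))
  dis_ppi <- run_stage("ppi", wcollect(
    build_ppi(disease, edges, cfg$expand_neighbors)))
  inter <- run_stage("intersect", intersect_networks(cmp_ppi, dis_ppi))
  utils::write.table(inter$edges, file.path(out_dir, "intersection_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cent <- run_stage("centrality", centralities(inter))
  write_centrality_table(cent, file.path(out_dir, "centralities.tsv"))
  hubs <- run_stage("hubs", extract_hubs(cent, use_nc = cfg$use_nc))
  writeLines(hubs$hubs, file.path(out_dir, "hubs.txt"))

  require_paths(cfg, "enrichment", "gene_sets")
  enr <- run_stage("enrichment", wcollect({
    coll <- read_gmt(cfg$gene_sets)
    ora(intersect(hubs$hubs, coll$universe), coll,
        ease = cfg$ease, q_cutoff = cfg$q_cutoff)
  }))
  write_ora(enr, file.path(out_dir, "enrichment.tsv"))

  summary <- list(
    n_compounds_retained = screen$n_retained,
    herb_counts = as.list(screen$herb_counts),
    n_targets = length(un$targets),
    covered_compounds = un$covered,
    bipartite = list(nodes = n_nodes(ct_net), edges = n_edges(ct_net)),
    compound_ppi = list(nodes = n_nodes(cmp_ppi), edges = n_edges(cmp_ppi)),
    disease_ppi = list(nodes = n_nodes(dis_ppi), edges = n_edges(dis_ppi)),
    intersection = list(nodes = n_nodes(inter), edges = n_edges(inter)),
    medians = as.list(attr(cent, "medians")),
    n_hubs = length(hubs$hubs),
    n_enriched_terms = sum(enr$enriched)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  inputs <- unlist(cfg[c("compounds", "target_map", "ppi_edges",
                         "disease_targets", "gene_sets")])
  outputs <- file.path(out_dir, c("screened_compounds.tsv", "compound_targets.txt",
                                  "intersection_edges.tsv", "centralities.tsv",
                                  "hubs.txt", "enrichment.tsv", "summary.json"))
  write_manifest(out_dir, cfg, inputs, outputs, warns)
  invisible(list(screen = screen, targets = un, network = inter,
                 centralities = cent, hubs = hubs, enrichment = enr,
                 summary = summary))
}

#' Run the microbiome + metabolome flow
#'
#' Alpha diversity and rank-sum differential abundance on the OTU table;
#' PCA, PLS-DA VIP selection on the intensity matrix (QC samples excluded
#' from the group contrast). Writes per-stage TSVs plus `summary.json`.
#'
#' @param cfg config with paths `otu_counts`, `otu_samples`, `otu_taxonomy`,
#'   `intensities` and options (`rank`, `group_a`, `group_b`,
#'   `n_components`, ...).
#' @param out_dir output directory.
#' @return Invisibly, the in-memory results.
#' @export
run_omics <- function(cfg, out_dir) {
  cfg <- pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  require_paths(cfg, "microbiome", c("otu_counts", "otu_samples", "otu_taxonomy"))
  ct <- run_stage("microbiome", read_count_table(cfg$otu_counts, cfg$otu_samples,
                                                 cfg$otu_taxonomy))
  div <- run_stage("microbiome", alpha_diversity(ct, cfg$rare_cutoff, cfg$log_base))
  utils::write.table(div, file.path(out_dir, "alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  da <- run_stage("microbiome", diff_abundance(ct, cfg$rank, cfg$group_a,
                                               cfg$group_b))
  utils::write.table(da, file.path(out_dir, "diff_abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  require_paths(cfg, "metabolome", "intensities")
  im <- run_stage("metabolome", read_intensity_matrix(cfg$intensities))
  pc <- run_stage("metabolome", pca(log(im$intensities)))
  utils::write.table(
    data.frame(sample_id = rownames(pc$scores), group = im$samples$group,
               is_qc = im$samples$is_qc, pc$scores[, 1:2, drop = FALSE]),
    file.path(out_dir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  keep <- !im$samples$is_qc &
    im$samples$group %in% c(cfg$group_a, cfg$group_b)
  sel <- run_stage("metabolome", select_differential(
    im$intensities[keep, , drop = FALSE], im$samples$group[keep],
    n_components = cfg$n_components, log_transform = cfg$log_transform))
  utils::write.table(sel$table, file.path(out_dir, "metabolite_selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sel$selected, file.path(out_dir, "selected_metabolites.txt"))

  summary <- list(
    n_samples_otu = nrow(ct$counts),
    mean_shannon = mean(div$shannon),
    n_diff_taxa_q05 = sum(da$q < 0.05),
    n_diff_taxa_q10 = sum(da$q < 0.1),
    pca_explained_pc1 = pc$explained[1],
    n_selected_metabolites = length(sel$selected)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  inputs <- unlist(cfg[c("otu_counts", "otu_samples", "otu_taxonomy", "intensities")])
  outputs <- file.path(out_dir, c("alpha_diversity.tsv", "diff_abundance.tsv",
                                  "pca_scores.tsv", "metabolite_selection.tsv",
                                  "selected_metabolites.txt", "summary.json"))
  write_manifest(out_dir, cfg, inputs, outputs)
  invisible(list(diversity = div, diff_abundance = da, pca = pc,
                 selection = sel, summary = summary))
}

#' Run the xenograft-efficacy flow
#'
#' Per-arm volume summaries, TGI against the control arm and between-arm
#' statistics at the configured day. Writes TSVs plus `summary.json` with
#' the TGI per arm.
#'
#' @param cfg config with path `measurements` and options `day`,
#'   `control_arm`, `volume_units`, `tgi_convention`.
#' @param out_dir output directory.
#' @return Invisibly, the in-memory results.
#' @export
run_efficacy <- function(cfg, out_dir) {
  cfg <- pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  require_paths(cfg, "efficacy", "measurements")
  meas <- run_stage("efficacy", read_measurements(cfg$measurements))
  summ <- run_stage("efficacy", arm_summary(meas, units = cfg$volume_units))
  utils::write.table(summ, file.path(out_dir, "arm_summaries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tg <- run_stage("efficacy", tgi_table(meas, cfg$day, cfg$control_arm,
                                        cfg$tgi_convention))
  utils::write.table(tg, file.path(out_dir, "tgi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  st <- run_stage("efficacy", compare_arms(meas, cfg$day, method = "anova_bh"))
  utils::write.table(st$pairwise, file.path(out_dir, "pairwise_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    day = cfg$day,
    tgi_percent = setNames(as.list(tg$tgi_percent), tg$arm),
    anova_p = st$anova$p
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, cfg, cfg$measurements,
                 file.path(out_dir, c("arm_summaries.tsv", "tgi.tsv",
                                      "pairwise_tests.tsv", "summary.json")))
  invisible(list(summaries = summ, tgi = tg, stats = st, summary = summary))
}
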