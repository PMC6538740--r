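test_that("spec validation rejects impossible designs", {
  expect_error(sim_spec(frac_pass_adme = 1.3), "frac_pass_adme")
  expect_error(sim_spec(frac_pass_adme = -0.1), "frac_pass_adme")
  expect_error(sim_spec(noise_cv = -0.2), "noise_cv")
  expect_error(sim_spec(taxon_fold_change = 0), "fold_change")
  expect_error(sim_spec(ppi_nodes = 5, ppi_attach_edges = 5), "ppi_nodes")
  expect_error(sim_spec(ppi_nodes = 10, ppi_attach_edges = 0), "ppi_nodes")
  expect_error(sim_spec(planted_enriched_terms = "GS99", n_gene_sets = 10),
               "planted_enriched_terms")
  expect_error(sim_spec(n_samples_per_group = 1), "n_samples_per_group")
})

test_that("compound generator plants the exact ADME pass count", {
  spec <- sim_spec(seed = 7, n_compounds = 100, frac_pass_adme = 0.29)
  tab <- gen_compound_table(spec)
  expect_equal(nrow(tab), 100)
  expect_equal(sum(tab$ob > 30 & tab$dl > 0.18), 29)
  expect_setequal(tab$compound_id[tab$ob > 30 & tab$dl > 0.18],
                  attr(tab, "planted_pass"))
  # herbs round-robin over 4 herbs
  expect_equal(length(unique(tab$herb)), 4)
  expect_true(all(table(tab$herb) == 25))

  none <- gen_compound_table(sim_spec(seed = 2, n_compounds = 40,
                                      frac_pass_adme = 0))
  expect_equal(sum(none$ob > 30 & none$dl > 0.18), 0)
  all_pass <- gen_compound_table(sim_spec(seed = 2, n_compounds = 40,
                                          frac_pass_adme = 1))
  expect_equal(sum(all_pass$ob > 30 & all_pass$dl > 0.18), 40)
})

test_that("preferential-attachment PPI has the forced edge count and planted hubs", {
  for (prm in list(c(50, 2), c(3, 2), c(120, 5))) {
    spec <- sim_spec(seed = 1, ppi_nodes = prm[1], ppi_attach_edges = prm[2])
    net <- gen_ppi(spec)
    expect_equal(n_nodes(net), prm[1])
    expect_equal(n_edges(net), prm[2] * (prm[1] - prm[2]))
    expect_length(attr(net, "planted_hubs"), prm[2])
    # connected and simple by construction
    expect_equal(sum(network_degrees(net)), 2 * n_edges(net))
  }
  spec <- sim_spec(seed = 4, ppi_nodes = 80, ppi_attach_edges = 3)
  net <- gen_ppi(spec)
  self <- intersect_networks(net, net)
  expect_identical(self$edges, net$edges)
  expect_identical(self$nodes, net$nodes)
  # planted hubs sit in the upper tail of the degree distribution
  deg <- network_degrees(net)
  expect_gt(mean(deg[attr(net, "planted_hubs")]), quantile(deg, 0.75))
})

test_that("identical spec and seed give identical outputs", {
  s1 <- sim_spec(seed = 11)
  s2 <- sim_spec(seed = 11)
  expect_identical(gen_compound_table(s1), gen_compound_table(s2))
  expect_identical(gen_ppi(s1), gen_ppi(s2))
  expect_identical(gen_gene_sets(s1), gen_gene_sets(s2))
  expect_identical(gen_otu_table(s1), gen_otu_table(s2))
  expect_identical(gen_metabolome(s1), gen_metabolome(s2))
  expect_identical(gen_growth_data(s1), gen_growth_data(s2))
  # different seed changes outputs
  expect_false(identical(gen_ppi(s1), gen_ppi(sim_spec(seed = 12))))
})

test_that("null OTU simulation is calibrated near the nominal level", {
  # no planted effect: raw Wilcoxon rejections at alpha = 0.05 should sit
  # near 5% of taxa on average
  rates <- vapply(1:20, function(s) {
    spec <- sim_spec(seed = 100 + s, n_taxa = 40, taxon_fold_change = 1,
                     n_samples_per_group = 8)
    da <- diff_abundance(gen_otu_table(spec), rank = "otu")
    mean(da$p < 0.05)
  }, numeric(1))
  expect_lt(mean(rates), 0.12)
})

test_that("growth generator reproduces arm multipliers in expectation", {
  spec <- sim_spec(seed = 5, noise_cv = 0.05, n_mice_per_arm = 10,
                   arms = c(control = 1, same = 1, strong = 0.8))
  g <- gen_growth_data(spec)
  expect_true(all(g$length_mm >= g$width_mm))
  expect_true(all(g$width_mm > 0))
  tg <- tgi_table(g, day = 32)
  # multiplier 1.0 arm: TGI near 0; noise CV 5% on 10 mice
  expect_lt(abs(tg$tgi_percent[tg$arm == "same"]), 10)
  # multiplier 0.8 arm: expected TGI = 1 - exp(r*(0.8-1)*32) ~ 64%
  r <- log(8496 / 50) / 32
  expect_lt(abs(tg$tgi_percent[tg$arm == "strong"] -
                (1 - exp(r * -0.2 * 32)) * 100), 12)
})

test_that("metabolome generator plants detectable shifts and tight QC", {
  spec <- sim_spec(seed = 9)
  im <- gen_metabolome(spec)
  expect_true(all(im$intensities > 0))
  planted <- attr(im, "planted_features")
  keep <- !im$samples$is_qc
  x <- log2(im$intensities[keep, ])
  grp <- im$samples$group[keep]
  p <- apply(x[, planted, drop = FALSE], 2, function(v)
    t.test(v[grp == "treatment"], v[grp == "control"])$p.value)
  expect_true(all(p < 0.05))
  # QC replicates vary much less than biological samples
  qc <- log2(im$intensities[im$samples$is_qc, ])
  expect_lt(mean(apply(qc, 2, sd)), mean(apply(x, 2, sd)))
})
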