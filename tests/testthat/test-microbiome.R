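test_that("abundance bookkeeping identities hold on every simulated sample", {
  ct <- gen_otu_table(sim_spec(seed = 13, n_samples_per_group = 4, n_taxa = 30))
  for (s in seq_len(nrow(ct$counts))) {
    summ <- abundance_summary(ct$counts[s, ])
    i <- as.integer(names(summ$F))
    expect_equal(sum(summ$F), summ$S_obs)
    expect_equal(sum(i * summ$F), summ$N)
    expect_equal(summ$S_rare + summ$S_abund, summ$S_obs)
  }
  expect_error(abundance_summary(c(0, 0)), "nonzero")
  expect_error(abundance_summary(c(1.5, 2)), "integers")
})

test_that("Shannon index matches closed forms and its invariances", {
  expect_equal(shannon_index(rep(3, 8)), log(8))
  expect_equal(shannon_index(c(0, 7, 0)), 0)
  expect_equal(shannon_index(c(1, 1, 2)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  expect_equal(shannon_index(rep(3, 8), base = 2), 3)
  # bounded by log richness; invariant to scaling counts
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(15, 5)
    if (all(x == 0)) next
    h <- shannon_index(x)
    expect_gte(h, 0)
    expect_lte(h, log(sum(x > 0)) + 1e-12)
    expect_equal(shannon_index(x * 7L), h)
  }
})

test_that("Chao1 matches hand-derived values in both variants", {
  expect_equal(chao1(c(1, 1, 2), bias_corrected = FALSE), 5)
  expect_equal(chao1(c(1, 1, 2)), 3.5)
  expect_equal(chao1(c(5, 7, 9)), 3)  # no singletons: S_obs
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(30, 2)
    if (sum(x > 0) < 2) next
    expect_gte(chao1(x), sum(x > 0))
    expect_gte(chao1(x, bias_corrected = FALSE), sum(x > 0))
  }
})

test_that("ACE follows the coverage formula, with degenerate fallback", {
  expect_equal(ace(c(20, 30, 40)), 3)  # no rare taxa
  expect_warning(v <- ace(c(1, 1, 12)), "Chao1")
  expect_equal(v, chao1(c(1, 1, 12)))
  # hand computation on a small sample
  x <- c(1, 1, 2, 3, 12, 15)
  s_rare <- 4; n_rare <- 7; f1 <- 2
  C <- 1 - f1 / n_rare
  fi <- c(2, 1, 1, rep(0, 7))
  g2 <- max(s_rare * sum((1:10) * (0:9) * fi) / (C * n_rare * 6) - 1, 0)
  expect_equal(ace(x), 2 + s_rare / C + (f1 / C) * g2)
})

test_that("Shannon, Chao1 and ACE agree with vegan on random samples", {
  skip_if_not_installed("vegan")
  set.seed(8)
  for (i in 1:15) {
    x <- rpois(40, 3)
    if (sum(x > 0) < 5 || !any(x == 1)) next
    expect_equal(shannon_index(x), unname(vegan::diversity(x, "shannon")))
    est <- vegan::estimateR(x)
    expect_equal(chao1(x), unname(est["S.chao1"]))
    expect_equal(ace(x), unname(est["S.ACE"]), tolerance = 1e-6)
  }
})

test_that("differential abundance recovers exact rank-sum p-values", {
  ct <- structure(list(
    counts = rbind(S1 = c(1, 9), S2 = c(2, 8), S3 = c(3, 7),
                   S4 = c(4, 6), S5 = c(5, 5), S6 = c(6, 4)),
    samples = data.frame(sample_id = paste0("S", 1:6),
                         group = rep(c("a", "b"), each = 3)),
    taxonomy = data.frame(taxon_id = c("t1", "t2"),
                          species = c("s__1", "s__2"))
  ), class = "count_table")
  colnames(ct$counts) <- c("t1", "t2")
  res <- diff_abundance(ct, rank = "species", group_a = "a", group_b = "b")
  # relative abundances of t1 are (.1,.2,.3) vs (.4,.5,.6): exact p = 0.1
  expect_equal(res$p[res$taxon == "s__1"], 0.1)
  expect_lt(res$direction[res$taxon == "s__1"], 0)
  # identical groups: exact p = 1
  ct2 <- ct
  ct2$counts <- rbind(S1 = c(1, 9), S2 = c(2, 8), S3 = c(3, 7),
                      S4 = c(1, 9), S5 = c(2, 8), S6 = c(3, 7))
  colnames(ct2$counts) <- c("t1", "t2")
  res2 <- diff_abundance(ct2, rank = "species", group_a = "a", group_b = "b")
  expect_equal(res2$p, c(1, 1))
  expect_error(diff_abundance(ct, rank = "genus"), "absent")
})

test_that("normal approximation tracks the exact test where both groups have >= 5 samples", {
  # the 0.02 agreement band holds once both groups reach 5; smaller groups
  # are served by the exact test, which diff_abundance uses by default
  set.seed(17)
  worst <- 0
  for (n1 in 5:8) for (n2 in n1:8) {
    for (rep in 1:3) {
      x <- rnorm(n1); y <- rnorm(n2)
      pa <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
      pe <- oracle_wilcox_exact_p(x, y)
      worst <- max(worst, abs(pa - pe))
    }
  }
  expect_lt(worst, 0.02)
})

test_that("planted differential taxa are recovered and nulls stay flat", {
  spec <- sim_spec(seed = 29)
  ct <- gen_otu_table(spec)
  res <- diff_abundance(ct, rank = "species")
  planted <- paste0("s__", attr(ct, "planted_taxa"))
  expect_gte(mean(res$q[match(planted, res$taxon)] < 0.1), 0.8)
  # kruskal option runs across all groups
  kr <- diff_abundance(ct, rank = "species", method = "kruskal")
  expect_true(all(c("statistic", "df", "q") %in% names(kr)))
})

test_that("count tables round-trip through the TSV writer and reader", {
  ct <- gen_otu_table(sim_spec(seed = 31, n_samples_per_group = 3, n_taxa = 12))
  d <- withr::local_tempdir()
  write_count_table(ct, file.path(d, "c.tsv"), file.path(d, "m.tsv"),
                    file.path(d, "t.tsv"))
  back <- read_count_table(file.path(d, "c.tsv"), file.path(d, "m.tsv"),
                           file.path(d, "t.tsv"))
  expect_equal(unname(back$counts), unname(ct$counts))
  expect_equal(back$samples$group, ct$samples$group)
  expect_equal(back$taxonomy$species, ct$taxonomy$species)
})
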