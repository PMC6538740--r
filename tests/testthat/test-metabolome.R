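test_that("PCA matches a covariance-eigendecomposition oracle", {
  set.seed(4)
  x <- matrix(rnorm(30 * 8), 30, 8)
  colnames(x) <- paste0("f", 1:8)
  res <- pca(x)
  z <- scale(x, center = TRUE, scale = TRUE)
  ev <- eigen(cov(z), symmetric = TRUE)$values
  expect_equal(sum(res$explained), 1)
  expect_equal(res$explained, ev / sum(ev), tolerance = 1e-10)
  # reconstruction is lossless at full rank
  recon <- res$scores %*% t(res$loadings)
  expect_equal(recon, z, ignore_attr = TRUE, tolerance = 1e-8)
  # sign convention: every component's largest-|loading| entry is positive
  for (j in seq_len(ncol(res$loadings))) {
    v <- res$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("PCA handles degenerate geometry and zero-variance features", {
  # 2D data on a line: one component explains everything
  t <- rnorm(20)
  x <- cbind(f1 = 3 * t, f2 = -2 * t)
  res <- pca(x, scale = FALSE)
  expect_equal(res$explained[1], 1)
  # duplicated samples shrink the rank
  base <- matrix(rnorm(8), 2, 4)
  y <- base[c(1, 1, 1, 2, 2, 2), ]
  expect_lt(sum(pca(y, scale = FALSE)$explained > 1e-12), nrow(y) - 1)
  z <- cbind(matrix(rnorm(40), 10, 4), const = rep(1, 10))
  expect_warning(res2 <- pca(z), "zero-variance")
  expect_equal(res2$dropped, "const")
})

test_that("NIPALS PLS-DA satisfies its algebraic structure", {
  set.seed(6)
  x <- matrix(rnorm(24 * 30), 24, 30)
  g <- rep(c("a", "b"), each = 12)
  x[g == "b", 1:5] <- x[g == "b", 1:5] + 2
  m <- plsda(x, g, n_components = 3)
  # unit-norm weights, orthogonal scores, nonnegative explained y-variance
  expect_equal(colSums(m$weights^2), rep(1, 3), ignore_attr = TRUE)
  ip <- crossprod(m$scores)
  expect_equal(ip[upper.tri(ip)], rep(0, 3), tolerance = 1e-8)
  expect_true(all(m$ssy >= 0))
  # first-component weights are proportional to X'y (closed form)
  z <- scale(x)
  y <- as.numeric(factor(g)) - mean(as.numeric(factor(g)))
  w1 <- crossprod(z, y)
  w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(as.numeric(m$weights[, 1]), as.numeric(w1), tolerance = 1e-10)
  expect_error(plsda(x, rep("a", 24)), "2 groups")
  expect_warning(plsda(x[1:4, ], rep(c("a", "b"), 2), n_components = 10),
                 "truncated")
})

test_that("VIP satisfies sum(VIP^2) = p and flags the planted block", {
  set.seed(7)
  for (ncomp in 1:3) {
    x <- matrix(rnorm(20 * 15), 20, 15)
    g <- rep(c("a", "b"), each = 10)
    m <- plsda(x, g, n_components = ncomp)
    v <- vip(m)
    expect_equal(sum(v^2), 15, tolerance = 1e-9)
  }
  # identical weights in a 1-component model give VIP = 1 everywhere
  spec <- sim_spec(seed = 41)
  im <- gen_metabolome(spec)
  keep <- !im$samples$is_qc
  m <- plsda(log(im$intensities[keep, ]), im$samples$group[keep])
  v <- sort(vip(m), decreasing = TRUE)
  planted <- attr(im, "planted_features")
  expect_gte(mean(planted %in% names(v)[seq_along(planted)]), 0.8)
})

test_that("differential selection applies the strict VIP/p conjunction", {
  spec <- sim_spec(seed = 43)
  im <- gen_metabolome(spec)
  keep <- !im$samples$is_qc
  x <- im$intensities[keep, ]
  g <- im$samples$group[keep]
  sel <- select_differential(x, g)
  planted <- attr(im, "planted_features")
  expect_true(all(planted %in% sel$selected))
  tab <- sel$table
  expect_equal(tab$selected, tab$vip > 1 & tab$p < 0.05)
  # permutation fairness: permuting features permutes the output identically
  perm <- sample(ncol(x))
  sel2 <- select_differential(x[, perm], g)
  expect_setequal(sel2$selected, sel$selected)
  expect_equal(sel2$table$vip, sel$table$vip[perm], tolerance = 1e-9)
})

test_that("Venn set logic matches brute-force membership evaluation", {
  v <- venn_specific(list(A = c("1", "2", "3"), B = c("2", "3"), C = "3"),
                     expressions = c(ab_not_c = "(A & B) & !C"))
  expect_equal(v$exclusive$A, "1")
  expect_equal(v$exclusive$B, character(0))
  expect_equal(v$common, "3")
  expect_equal(v$expressions$ab_not_c, "2")
  same <- venn_specific(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(lengths(same$exclusive), c(A = 0L, B = 0L))
  expect_error(venn_specific(list(A = "1", B = "2"),
                             expressions = c(bad = "A & Z")), "unknown set")
  expect_error(venn_specific(list(A = "1")), ">= 2")
  # random sets against brute force
  set.seed(9)
  sets <- lapply(setNames(1:4, c("w", "x", "y", "z")),
                 function(i) as.character(sample(50, 20)))
  got <- venn_specific(sets, expressions = c(e = "(w | x) & !(y & z)"))
  uni <- sort(unique(unlist(sets)))
  brute <- uni[(uni %in% sets$w | uni %in% sets$x) &
                 !(uni %in% sets$y & uni %in% sets$z)]
  expect_equal(got$expressions$e, brute)
  for (nm in names(sets)) {
    others <- unlist(sets[setdiff(names(sets), nm)])
    expect_equal(got$exclusive[[nm]], sort(setdiff(sets[[nm]], others)))
  }
})

test_that("intensity matrices round-trip through the CSV writer and reader", {
  im <- gen_metabolome(sim_spec(seed = 47, n_metabolites = 12,
                                n_samples_per_group = 3), n_qc = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_intensity_matrix(im, f)
  back <- read_intensity_matrix(f)
  expect_equal(back$samples$is_qc, im$samples$is_qc)
  expect_equal(unname(back$intensities), unname(im$intensities),
               tolerance = 1e-6)
})
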