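#' Principal component analysis with a deterministic sign convention
#'
#' Singular-value decomposition of the column-centred (and by default
#' unit-variance scaled) matrix, via `prcomp`. Zero-variance features are
#' dropped with a warning when scaling. Each component's sign is fixed so
#' the largest-magnitude loading entry is positive, making score plots
#' reproducible across platforms.
#'
#' @param x numeric matrix, samples x features.
#' @param center,scale logical preprocessing flags.
#' @return List of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components), `explained` (fractions of total
#'   variance, summing to 1), `dropped` (names of dropped features).
#' @export
pca <- function(x, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least 2 samples and 2 features")
  dropped <- character(0)
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    zero <- sds == 0 | !is.finite(sds)
    if (any(zero)) {
      warning(sum(zero), " zero-variance feature(s) dropped before scaling")
      dropped <- colnames(x)[zero]
      x <- x[, !zero, drop = FALSE]
      if (ncol(x) < 2L) stop("fewer than 2 features left after dropping")
    }
  }
  fit <- stats::prcomp(x, center = center, scale. = scale)
  flip <- apply(fit$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2L, flip, `*`)
  loadings <- sweep(fit$rotation, 2L, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 explained = fit$sdev^2 / sum(fit$sdev^2),
                 dropped = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA: ", nrow(x$scores), " samples, ", nrow(x$loadings), " features\n",
      sep = "")
  ev <- round(100 * x$explained[seq_len(min(5, length(x$explained)))], 1)
  cat("  explained (%): ", paste(ev, collapse = ", "),
      if (length(x$explained) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Two-class PLS-DA by NIPALS, with VIP scores
#'
#' Fits partial least squares on the column-centred, unit-variance data
#' with a single centred class-indicator response (the one-hot coding of a
#' two-group contrast collapses to this). Per component `a` the unit-norm
#' weight vector `w_a`, scores `t_a`, y-loading `q_a` and explained
#' response variance `SSY_a = q_a^2 * t_a' t_a` are stored. Variable
#' importance in projection is
#' `VIP_j = sqrt(p * sum_a(SSY_a * w_ja^2) / sum_a(SSY_a))`,
#' so the mean of `VIP^2` over the `p` features is exactly 1.
#' Components are truncated with a warning when the residual rank or the
#' sample/feature bounds are hit.
#'
#' @param x numeric matrix, samples x features.
#' @param groups factor or character with exactly two levels, one entry per
#'   sample (row).
#' @param n_components number of components requested.
#' @param center,scale preprocessing flags (autoscaling is the default).
#' @return Object of class `plsda`: list with `weights` (p x A), `scores`
#'   (n x A), `x_loadings`, `y_loadings` (length A), `ssy` (length A),
#'   `features`, `groups`, `levels`, `center`, `scale_`.
#' @export
plsda <- function(x, groups, n_components = 2L, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("plsda requires exactly 2 groups")
  if (length(groups) != nrow(x)) stop("one group label per sample required")
  n <- nrow(x); p <- ncol(x)
  a_max <- min(n - 1L, p)
  if (n_components > a_max) {
    warning("n_components truncated to ", a_max)
    n_components <- a_max
  }

  ctr <- if (center) colMeans(x) else rep(0, p)
  scl <- if (scale) apply(x, 2L, stats::sd) else rep(1, p)
  if (any(scl == 0)) stop("zero-variance feature(s); drop them before fitting")
  X <- sweep(sweep(x, 2L, ctr), 2L, scl, `/`)
  y <- as.numeric(groups == levels(groups)[2])
  y <- y - mean(y)

  W <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  ssy <- numeric(n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("residual response exhausted; components truncated to ", a_used)
      break
    }
    w <- w / nw
    t_ <- X %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) {
      warning("degenerate score; components truncated to ", a_used)
      break
    }
    q_a <- sum(y * t_) / tt
    p_a <- crossprod(X, t_) / tt
    X <- X - t_ %*% t(p_a)
    y <- y - as.numeric(t_) * q_a
    a_used <- a
    W[, a] <- w
    Tm[, a] <- t_
    P[, a] <- p_a
    q[a] <- q_a
    ssy[a] <- q_a^2 * tt
  }
  if (a_used == 0L) stop("no PLS component could be extracted")
  keep <- seq_len(a_used)
  structure(list(weights = W[, keep, drop = FALSE],
                 scores = Tm[, keep, drop = FALSE],
                 x_loadings = P[, keep, drop = FALSE],
                 y_loadings = q[keep],
                 ssy = ssy[keep],
                 features = colnames(x) %||% paste0("V", seq_len(p)),
                 groups = groups,
                 levels = levels(groups),
                 center = ctr, scale_ = scl),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model: ", length(x$features), " features, ",
      ncol(x$weights), " component(s)\n", sep = "")
  cat("  contrast: ", x$levels[2], " vs ", x$levels[1], "\n", sep = "")
  cat("  explained y-variance per component: ",
      paste(signif(x$ssy / sum(x$ssy), 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Variable importance in projection
#'
#' @param model a fitted [plsda()] model.
#' @return Named numeric vector of VIP scores (one per feature;
#'   `sum(vip^2) == p` holds to machine precision).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda"))
  p <- nrow(model$weights)
  num <- as.numeric(model$weights^2 %*% model$ssy)
  setNames(sqrt(p * num / sum(model$ssy)), model$features)
}

#' Differential-metabolite selection by VIP and t-test
#'
#' The metabolomics convention: a feature is differential when its PLS-DA
#' VIP strictly exceeds `vip_cutoff` (default 1.0) AND its two-sided
#' unpaired t-test p-value on log-transformed intensities is below
#' `p_cutoff` (default 0.05, unadjusted; Benjamini-Hochberg optionally via
#' `adjust = "BH"`). Nonpositive or missing intensities are imputed with
#' half the feature minimum positive value before the natural-log
#' transform; `log_transform = FALSE` tests raw intensities.
#'
#' @param x positive intensity matrix, samples x features (no QC rows).
#' @param groups two-level factor/character per sample.
#' @param vip_cutoff,p_cutoff selection thresholds (strict > for VIP,
#'   strict < for p).
#' @param n_components PLS-DA components for the VIP model.
#' @param log_transform logical.
#' @param adjust `"none"` (default) or `"BH"`; with BH the p threshold is
#'   applied to q-values.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return List with `selected` (feature names, input order) and `table`
#'   (`feature, vip, p, q, selected`).
#' @export
select_differential <- function(x, groups, vip_cutoff = 1.0, p_cutoff = 0.05,
                                n_components = 2L, log_transform = TRUE,
                                adjust = c("none", "BH"), var_equal = TRUE) {
  adjust <- match.arg(adjust)
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly 2 groups required")

  if (log_transform) {
    for (j in seq_len(ncol(x))) {
      v <- x[, j]
      bad <- !is.finite(v) | v <= 0
      if (any(bad)) {
        pos <- v[!bad]
        if (!length(pos)) stop("feature ", j, " has no positive intensities")
        v[bad] <- min(pos) / 2
        x[, j] <- v
      }
    }
    x <- log(x)
  }

  model <- plsda(x, groups, n_components = n_components)
  v <- vip(model)
  ia <- groups == levels(groups)[1]
  pvals <- apply(x, 2L, function(col)
    stats::t.test(col[ia], col[!ia], var.equal = var_equal)$p.value)
  qvals <- bh_adjust(pvals)
  crit_p <- if (adjust == "BH") qvals else pvals
  sel <- v > vip_cutoff & crit_p < p_cutoff
  feats <- model$features
  list(selected = feats[sel],
       table = data.frame(feature = feats, vip = unname(v), p = unname(pvals),
                          q = unname(qvals), selected = unname(sel),
                          stringsAsFactors = FALSE))
}

#' Exclusive, common and expression-defined subsets of named feature sets
#'
#' The Venn bookkeeping used when contrasting differential-metabolite
#' lists: for each named set its exclusive members (absent from every
#' other set), the members common to all sets, and arbitrary boolean
#' combinations given as expressions over the set names with `&`, `|`,
#' `!` and parentheses — e.g. `(gqd_pd1 & pd1) & !gqd` for "shared by the
#' two PD-1 contrasts but absent from the GQD-only contrast".
#'
#' @param sets named list (>= 2) of character vectors.
#' @param expressions optional named character vector of boolean
#'   expressions over the set names.
#' @return List with `exclusive` (named list), `common` (character) and
#'   `expressions` (named list of evaluated member vectors). Unknown set
#'   names in an expression raise an error.
#' @examples
#' venn_specific(list(A = c("1", "2", "3"), B = c("2", "3"), C = "3"),
#'               expressions = c(shared_ab_not_c = "(A & B) & !C"))
#' @export
venn_specific <- function(sets, expressions = NULL) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets)) ||
      any(!nzchar(names(sets))) || anyDuplicated(names(sets)))
    stop("sets must be a uniquely named list of length >= 2")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- lapply(sets, function(s) universe %in% s)

  exclusive <- lapply(names(sets), function(nm) {
    others <- Reduce(`|`, member[setdiff(names(sets), nm)],
                     accumulate = FALSE)
    universe[member[[nm]] & !others]
  })
  names(exclusive) <- names(sets)
  common <- universe[Reduce(`&`, member)]

  eval_expr <- function(txt) {
    expr <- tryCatch(str2lang(txt), error = function(e)
      stop("cannot parse set expression: ", txt, call. = FALSE))
    check <- function(e) {
      if (is.name(e)) {
        nm <- as.character(e)
        if (!nm %in% names(sets)) stop("unknown set name '", nm,
                                       "' in expression: ", txt, call. = FALSE)
      } else if (is.call(e)) {
        op <- as.character(e[[1]])
        if (!op %in% c("&", "|", "!", "("))
          stop("operator '", op, "' not allowed in set expressions", call. = FALSE)
        for (i in seq_along(e)[-1]) check(e[[i]])
      } else stop("invalid token in set expression: ", txt, call. = FALSE)
    }
    check(expr)
    universe[eval(expr, envir = member)]
  }
  exprs <- if (is.null(expressions)) list() else
    lapply(as.list(expressions), eval_expr)

  list(exclusive = exclusive, common = common, expressions = exprs)
}

#' Read an intensity matrix CSV
#'
#' Samples as rows with metadata columns `sample_id,group,is_qc` followed
#' by one positive-intensity column per feature.
#'
#' @param path file path.
#' @return An `intensity_matrix` (list with `intensities`, `samples`).
#' @export
read_intensity_matrix <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "group", "is_qc")
  if (!all(req %in% names(x)))
    stop("intensity file ", path, " needs columns: ", paste(req, collapse = ", "))
  meta <- x[, req]
  meta$is_qc <- as.logical(meta$is_qc)
  mat <- as.matrix(x[, setdiff(names(x), req), drop = FALSE])
  rownames(mat) <- meta$sample_id
  structure(list(intensities = mat, samples = meta), class = "intensity_matrix")
}

#' Write an intensity matrix CSV
#'
#' @param im an `intensity_matrix`.
#' @param path output path.
#' @export
write_intensity_matrix <- function(im, path) {
  stopifnot(inherits(im, "intensity_matrix"))
  df <- cbind(im$samples, as.data.frame(im$intensities, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
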