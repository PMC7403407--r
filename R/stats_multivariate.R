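# Permutation multivariate statistics implemented from first principles:
# Bray-Curtis dissimilarity, MRPP, PERMANOVA (McArdle-Anderson), Mantel
# tests, non-metric multidimensional scaling with Kruskal stress-1 and
# monotone regression, vector fitting of environmental variables, and UPGMA
# clustering. All permutation p-values use the (b + 1) / (m + 1) estimator
# and are exactly reproducible given a seed.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` between the abundance profiles of
#' every pair of samples. Values lie in `[0, 1]`: 0 for identical profiles,
#' 1 for profiles with no shared features.
#'
#' @param x abundance matrix, samples in rows (non-negative; no all-zero
#'   row).
#' @return square symmetric dissimilarity matrix with the sample rownames.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  rs <- rowSums(x)
  if (any(rs == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(x)[rs == 0], collapse = ", "))
  }
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / (rs[i] + rs[j])
    }
  }
  d
}

# weighted mean within-group distance; groups of size 1 contribute nothing
.mrpp_delta <- function(d, groups, sizes, include) {
  delta <- 0
  n_tot <- sum(sizes[include])
  for (g in which(include)) {
    idx <- which(groups == g)
    sub <- d[idx, idx]
    delta <- delta + sizes[g] / n_tot * mean(sub[lower.tri(sub)])
  }
  delta
}

#' Multi-response permutation procedure
#'
#' Tests whether samples are more similar within groups than expected by
#' chance. The observed statistic is the group-size-weighted mean
#' within-group distance `delta = sum((n_i / N) * mean within-group d)`;
#' significance comes from permuting the group labels (one-sided: small
#' delta indicates separation). The chance-corrected effect size is
#' `A = 1 - delta_obs / mean(delta_perm)`.
#'
#' @param d distance matrix (square matrix or `dist`).
#' @param groups grouping vector, one label per sample; groups of size 1 are
#'   excluded from delta with a warning.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for reproducible permutations.
#' @return list of class `perm_test`: `statistic` (delta), `A`, `p`,
#'   `n_perm`, `seed`, `method`.
#' @export
mrpp <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as_distance_matrix(d)
  groups <- as.integer(as.factor(groups))
  stopifnot(length(groups) == nrow(d))
  sizes <- tabulate(groups)
  include <- sizes >= 2L
  if (sum(include) < 2L) stop("need at least two groups with >= 2 members")
  if (any(!include & sizes > 0L)) {
    warning("group(s) of size 1 excluded from delta")
  }
  delta_obs <- .mrpp_delta(d, groups, sizes, include)
  delta_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pg <- sample(groups)
      .mrpp_delta(d, pg, sizes, include)
    }, numeric(1))
  })
  structure(list(statistic = delta_obs,
                 A = 1 - delta_obs / mean(delta_perm),
                 p = perm_p(delta_perm, delta_obs, "less"),
                 n_perm = n_perm, seed = seed, method = "MRPP"),
            class = "perm_test")
}

#' Permutational multivariate analysis of variance
#'
#' Distance-based MANOVA partitioning the total sum of squared dissimilarities
#' across ordered model terms (factors and/or continuous covariates). The
#' Gower-centered inner-product matrix `G = -1/2 J (D*D) J` is projected onto
#' nested design matrices to obtain sequential sums of squares
#' (`SS_j = tr(H_j G) - tr(H_{j-1} G)`); pseudo-F uses the residual mean
#' square, and p-values come from simultaneous row/column permutation of the
#' distance matrix (raw-sample permutation, the simplest exchangeability
#' model for a one-factor chronosequence).
#'
#' Because sums of squares are sequential, term order matters for
#' non-orthogonal designs; each term is adjusted only for those before it.
#'
#' @param d distance matrix (square matrix or `dist`).
#' @param formula right-hand-side formula over columns of `data`, e.g.
#'   `~ age_class + doc`.
#' @param data data frame of sample covariates, rows aligned with `d`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `permanova`: `terms` data frame (term, df, SS, R2,
#'   pseudo-F, p), `ss_total`, `ss_residual`, `df_residual`, `n_perm`,
#'   `seed`.
#' @export
permanova <- function(d, formula, data, n_perm = 999, seed = NULL) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  stopifnot(nrow(data) == n)
  tt <- stats::terms(formula)
  term_labels <- attr(tt, "term.labels")
  if (length(term_labels) == 0L) stop("formula has no terms")
  g <- gower_center(d)
  ss_total <- sum(diag(g))
  if (ss_total < 1e-12) stop("all samples identical (total SS is zero)")
  # nested hat matrices, intercept first
  hats <- vector("list", length(term_labels))
  x <- matrix(1, n, 1)
  df <- integer(length(term_labels))
  rank_prev <- 1L
  for (j in seq_along(term_labels)) {
    f_j <- stats::as.formula(paste("~", paste(term_labels[seq_len(j)],
                                              collapse = "+")))
    x <- stats::model.matrix(f_j, data = data)
    q <- qr(x)
    if (q$rank < ncol(x)) stop("design matrix rank deficient at term ",
                               term_labels[j])
    hats[[j]] <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    df[j] <- q$rank - rank_prev
    rank_prev <- q$rank
  }
  df_res <- n - rank_prev
  if (df_res < 1L) stop("no residual degrees of freedom")
  stat_fun <- function(gm) {
    tr <- vapply(hats, function(h) sum(h * gm), numeric(1))
    ss <- diff(c(0, tr))
    ss_res <- sum(diag(gm)) - tr[length(tr)]
    f <- (ss / df) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat_fun(g)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      p <- sample.int(n)
      stat_fun(g[p, p])$f
    }, numeric(length(term_labels)))
  })
  f_perm <- matrix(f_perm, nrow = length(term_labels))
  pvals <- vapply(seq_along(term_labels), function(j) {
    perm_p(f_perm[j, ], obs$f[j], "greater")
  }, numeric(1))
  structure(list(
    terms = data.frame(term = term_labels, df = df, ss = obs$ss,
                       r2 = obs$ss / ss_total, pseudo_f = obs$f, p = pvals,
                       row.names = NULL),
    ss_total = ss_total, ss_residual = obs$ss_res, df_residual = df_res,
    n_perm = n_perm, seed = seed), class = "permanova")
}

#' Gower-centered inner-product matrix
#'
#' `G = -1/2 J (D * D) J` with `J = I - 11'/n`, the doubly centered matrix of
#' squared dissimilarities underlying distance-based MANOVA.
#'
#' @param d square distance matrix.
#' @return square matrix `G`; `sum(diag(G))` is the total sum of squares.
#' @export
gower_center <- function(d) {
  d <- as_distance_matrix(d)
  a <- -0.5 * d^2
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

#' Mantel test between two distance matrices
#'
#' Correlates the lower triangles of two distance matrices over the same
#' samples (`r_m`); significance comes from simultaneously permuting the
#' rows and columns of the second matrix (one-sided, greater).
#'
#' @param d1,d2 distance matrices (square matrix or `dist`) over the same
#'   samples in the same order.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `perm_test`: `statistic` (r_m), `p`, `n_perm`,
#'   `seed`, `method`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  d1 <- as_distance_matrix(d1)
  d2 <- as_distance_matrix(d2)
  stopifnot(nrow(d1) == nrow(d2))
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("sample ids of the two matrices do not match")
  }
  v1 <- lower_tri(d1)
  v2 <- lower_tri(d2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("constant distances: Mantel correlation undefined")
  }
  r_obs <- stats::cor(v1, v2, method = method)
  n <- nrow(d1)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      p <- sample.int(n)
      stats::cor(v1, lower_tri(d2[p, p]), method = method)
    }, numeric(1))
  })
  structure(list(statistic = r_obs, p = perm_p(r_perm, r_obs, "greater"),
                 n_perm = n_perm, seed = seed,
                 method = paste("Mantel", method)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(x$method, "permutation test\n")
  cat("  statistic:", format(x$statistic, digits = 4))
  if (!is.null(x$A)) cat("  A:", format(x$A, digits = 4))
  cat("  p:", format(x$p, digits = 4),
      sprintf("(%d permutations)\n", x$n_perm))
  invisible(x)
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS,", x$n_perm, "permutations)\n")
  print(x$terms, digits = 4)
  cat("residual SS:", format(x$ss_residual, digits = 4),
      "on", x$df_residual, "df; total SS:",
      format(x$ss_total, digits = 4), "\n")
  invisible(x)
}

# -- non-metric multidimensional scaling ------------------------------------

#' Non-metric multidimensional scaling
#'
#' Embeds samples in `k` dimensions so that the rank order of configuration
#' distances matches the rank order of the input dissimilarities, minimizing
#' Kruskal stress-1
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`, where `dhat` is the monotone
#' (pool-adjacent-violators) regression of configuration distances on the
#' dissimilarity ranks. Ties in the dissimilarities are handled by Kruskal's
#' primary approach (tied dissimilarities impose no order constraint among
#' themselves).
#'
#' Each restart alternates monotone regression with a Guttman-transform
#' configuration update until the stress improvement drops below `tol`. The
#' first start is the metric (principal-coordinate) configuration, the rest
#' are random; the lowest-stress solution is returned, centered and rotated
#' to its principal axes.
#'
#' @param d distance matrix (square matrix or `dist`).
#' @param k embedding dimension (default 2).
#' @param restarts number of starts including the metric start (default 20).
#' @param tol stress-improvement convergence tolerance (default 1e-6).
#' @param maxit maximum iterations per start (default 500).
#' @param seed integer seed for the random starts.
#' @return list of class `nmds_ordination`: `points` (n x k coordinate
#'   matrix, centered, principal-axis orientation), `stress` (Kruskal
#'   stress-1), `converged`, `restarts`, `k`.
#' @export
nmds <- function(d, k = 2, restarts = 20, tol = 1e-6, maxit = 500,
                 seed = NULL) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 samples to embed in k dimensions")
  dv <- lower_tri(d)
  denom_rank <- order(dv)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      x0 <- if (r == 1L) {
        cm <- suppressWarnings(stats::cmdscale(d, k = k))
        if (ncol(cm) < k) cm <- cbind(cm, matrix(0, n, k - ncol(cm)))
        cm
      } else {
        matrix(stats::runif(n * k, -1, 1), n, k)
      }
      run <- .nmds_run(d, dv, x0, tol = tol, maxit = maxit)
      if (is.null(best) || run$stress < best$stress) best <- run
      if (best$stress < tol) break
    }
  })
  x <- scale(best$x, center = TRUE, scale = FALSE)
  if (stats::sd(as.vector(x)) > 0) {
    x <- x %*% svd(x)$v  # rigid rotation to principal axes
  }
  rownames(x) <- rownames(d)
  colnames(x) <- paste0("NMDS", seq_len(k))
  structure(list(points = x, stress = best$stress,
                 converged = best$converged, restarts = restarts, k = k),
            class = "nmds_ordination")
}

# single NMDS run: isotonic regression + Guttman transform majorization
.nmds_run <- function(d, dv, x, tol, maxit) {
  n <- nrow(d)
  stress_prev <- Inf
  converged <- FALSE
  best_x <- x
  best_stress <- Inf
  for (it in seq_len(maxit)) {
    dm <- as.matrix(stats::dist(x))
    dl <- lower_tri(dm)
    # primary tie approach: within tied d-blocks order by current config
    # distance, so ties impose no constraint
    ord <- order(dv, dl)
    dhat <- numeric(length(dl))
    dhat[ord] <- pava(dl[ord])
    ssq <- sum(dl^2)
    if (ssq == 0) break
    stress <- sqrt(sum((dl - dhat)^2) / ssq)
    if (stress < best_stress) {
      best_stress <- stress
      best_x <- x
    }
    if (stress_prev - stress < tol) {
      converged <- stress_prev - stress >= 0 || stress < tol
      break
    }
    stress_prev <- stress
    # Guttman transform towards the disparities dhat
    dhat_m <- matrix(0, n, n)
    dhat_m[lower.tri(dhat_m)] <- dhat
    dhat_m <- dhat_m + t(dhat_m)
    ratio <- ifelse(dm > 0, dhat_m / dm, 0)
    b <- -ratio
    diag(b) <- rowSums(ratio)
    x <- b %*% x / n
  }
  list(x = best_x, stress = best_stress, converged = converged)
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$points), "samples in", x$k,
      "dimensions\n")
  cat("  stress-1:", format(x$stress, digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Vector fitting of environmental variables onto an ordination
#'
#' Regresses each variable on the ordination coordinates; the squared
#' multiple correlation `r2` measures how well the variable aligns with the
#' configuration and the regression direction (scaled to unit length) gives
#' the arrow. Significance comes from permuting the variable's values.
#' Constant variables are skipped with a warning.
#'
#' @param ord an `nmds_ordination` (or any list with a `points` matrix), or
#'   a coordinate matrix.
#' @param variables data frame (or named list) of numeric sample variables
#'   aligned with the ordinated samples.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return data frame with one row per fitted variable: `variable`, one
#'   loading column per axis, `r2`, `p`.
#' @export
envfit_vectors <- function(ord, variables, n_perm = 999, seed = NULL) {
  x <- if (is.matrix(ord)) ord else ord$points
  variables <- as.data.frame(variables)
  stopifnot(nrow(variables) == nrow(x))
  xc <- scale(x, center = TRUE, scale = FALSE)
  q <- qr(xc)
  rows <- list()
  with_seed(seed, {
    for (v in names(variables)) {
      y <- variables[[v]]
      if (!is.numeric(y)) { warning("variable ", v, " not numeric; skipped"); next }
      if (stats::sd(y) == 0) { warning("variable ", v, " constant; skipped"); next }
      yc <- y - mean(y)
      tss <- sum(yc^2)
      r2_of <- function(yy) {
        fit <- qr.fitted(q, yy)
        sum(fit^2) / sum(yy^2)
      }
      r2 <- r2_of(yc)
      coef <- qr.coef(q, yc)
      coef[is.na(coef)] <- 0
      arrow <- coef / sqrt(sum(coef^2))
      r2_perm <- vapply(seq_len(n_perm), function(b) {
        yp <- sample(yc)
        r2_of(yp - mean(yp))
      }, numeric(1))
      row <- data.frame(variable = v, t(arrow), r2 = r2,
                        p = perm_p(r2_perm, r2, "greater"))
      names(row)[2:(1 + ncol(x))] <- colnames(x)
      rows[[v]] <- row
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# -- UPGMA ------------------------------------------------------------------

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomeration: repeatedly merges the closest pair of
#' clusters, placing the merge node at half the pair's distance, and updates
#' distances to other clusters by the cluster-size-weighted average
#' (`d(new, l) = (n_i d(i, l) + n_j d(j, l)) / (n_i + n_j)`). The result is
#' an ultrametric rooted tree (all leaves equidistant from the root when the
#' input is ultrametric-compatible; cophenetic distances are always
#' ultrametric). Ties are broken deterministically by the lexicographically
#' smallest pair of cluster labels.
#'
#' @param d distance matrix (square matrix or `dist`) with sample names.
#' @return list of class `upgma_tree`: `newick` (rooted Newick string with
#'   branch lengths), `height` (root height), `cophenetic` (ultrametric
#'   distance matrix implied by the tree), `merges` (data frame of merge
#'   steps).
#' @export
upgma <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two samples")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  active <- data.frame(label = labs, size = 1L, height = 0,
                       newick = labs, stringsAsFactors = FALSE)
  dm <- d
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  members <- lapply(seq_len(n), identity)
  merges <- list()
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(active) > 1L) {
    m <- nrow(active)
    dmin <- min(dm[lower.tri(dm)])
    # candidate pairs at the minimum; lexicographic smallest label pair wins
    cand <- which(dm <= dmin + 1e-12 & lower.tri(dm), arr.ind = TRUE)
    pair_lab <- t(apply(cand, 1, function(ij) {
      sort(c(active$label[ij[1]], active$label[ij[2]]))
    }))
    pick <- order(pair_lab[, 1], pair_lab[, 2])[1]
    i <- min(cand[pick, ]); j <- max(cand[pick, ])
    h <- dm[j, i] / 2
    ni <- active$size[i]; nj <- active$size[j]
    nwk <- paste0("(", active$newick[i], ":", fmt(h - active$height[i]),
                  ",", active$newick[j], ":", fmt(h - active$height[j]), ")")
    coph[members[[i]], members[[j]]] <- 2 * h
    coph[members[[j]], members[[i]]] <- 2 * h
    merges[[length(merges) + 1L]] <- data.frame(
      left = active$label[i], right = active$label[j], height = h)
    # weighted-average distance update
    keep <- setdiff(seq_len(m), c(i, j))
    if (length(keep) > 0L) {
      dnew <- (ni * dm[i, keep] + nj * dm[j, keep]) / (ni + nj)
      dm <- dm[keep, keep, drop = FALSE]
      dm <- rbind(cbind(dm, dnew), c(dnew, 0))
    } else {
      dm <- matrix(0, 1, 1)
    }
    new_label <- paste0("(", min(active$label[i], active$label[j]), ")")
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    active <- rbind(active[keep, , drop = FALSE],
                    data.frame(label = new_label, size = ni + nj, height = h,
                               newick = nwk, stringsAsFactors = FALSE))
  }
  structure(list(newick = paste0(active$newick[1], ";"),
                 height = active$height[1], cophenetic = coph,
                 merges = do.call(rbind, merges)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree, root height", format(x$height, digits = 4), "\n")
  cat(" ", x$newick, "\n")
  invisible(x)
}
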