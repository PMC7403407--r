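# Table-1-style group comparisons: per-analyte routing through a
# Shapiro-Wilk normality gate to either ANOVA + Tukey HSD or
# Kruskal-Wallis + pairwise Welch tests, summarized as compact letter
# displays. Standard fits go through base R (shapiro.test, aov, ptukey,
# kruskal.test, t.test); the letter-display algorithm is implemented here.

#' Tukey honestly-significant-difference pairwise p-values
#'
#' Pairwise comparisons of group means using the studentized-range
#' distribution after a one-way fit, as in `TukeyHSD(aov(...))`.
#'
#' @param values numeric response vector.
#' @param groups grouping factor (>= 2 groups, >= 2 observations each).
#' @return symmetric matrix of adjusted pairwise p-values (groups x groups,
#'   diagonal `NA`). If all values are identical (zero variance anywhere),
#'   every p is 1 (identical data cannot show differences).
#' @export
tukey_hsd <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  .check_groups(values, groups)
  k <- nlevels(groups)
  ng <- tabulate(groups)
  means <- tapply(values, groups, mean)
  df_err <- length(values) - k
  mse <- sum((values - means[groups])^2) / df_err
  p <- matrix(NA_real_, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (mse == 0) {
        pij <- if (means[i] == means[j]) 1 else 0
      } else {
        se <- sqrt(mse / 2 * (1 / ng[i] + 1 / ng[j]))
        q <- abs(means[i] - means[j]) / se
        pij <- stats::ptukey(q, k, df_err, lower.tail = FALSE)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  p
}

#' One-way ANOVA F test
#'
#' @inheritParams tukey_hsd
#' @return list with `statistic` (F), `p`, `df` (numerator, denominator).
#'   Zero-variance degenerate data (all values equal) yield `F = 0, p = 1`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  .check_groups(values, groups)
  if (stats::var(values) == 0) {
    return(list(statistic = 0, p = 1,
                df = c(nlevels(groups) - 1L, length(values) - nlevels(groups))))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  list(statistic = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = tab$Df)
}

#' Kruskal-Wallis rank-sum test
#'
#' Thin wrapper over [stats::kruskal.test()] (rank sums with tie
#' correction), with the degenerate all-equal case mapped to `H = 0, p = 1`.
#'
#' @inheritParams tukey_hsd
#' @return list with `statistic` (H), `p`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  .check_groups(values, groups)
  if (stats::var(values) == 0) {
    return(list(statistic = 0, p = 1, df = nlevels(groups) - 1L))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Pairwise Welch t tests with multiplicity adjustment
#'
#' Welch (unequal-variance) t tests for every pair of groups, with p-values
#' adjusted by [stats::p.adjust()] (Holm by default: uniformly valid with no
#' independence assumption).
#'
#' @inheritParams tukey_hsd
#' @param adjust adjustment method (default `"holm"`).
#' @return symmetric matrix of adjusted pairwise p-values.
#' @export
pairwise_welch <- function(values, groups, adjust = "holm") {
  groups <- droplevels(as.factor(groups))
  .check_groups(values, groups)
  lv <- levels(groups)
  k <- length(lv)
  pairs <- utils::combn(k, 2)
  raw <- apply(pairs, 2, function(ij) {
    x <- values[groups == lv[ij[1]]]
    y <- values[groups == lv[ij[2]]]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    stats::t.test(x, y, var.equal = FALSE)$p.value
  })
  adj <- stats::p.adjust(raw, method = adjust)
  p <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  for (j in seq_len(ncol(pairs))) {
    p[pairs[1, j], pairs[2, j]] <- p[pairs[2, j], pairs[1, j]] <- adj[j]
  }
  p
}

.check_groups <- function(values, groups) {
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(tabulate(groups) < 2L)) stop("need >= 2 observations per group")
  invisible(NULL)
}

#' Compact letter display
#'
#' Assigns letters to groups from a symmetric matrix of pairwise p-values by
#' the insert-and-absorb algorithm, so that two groups share at least one
#' letter if and only if their pairwise p-value is `>= alpha`.
#'
#' @param p symmetric matrix of (adjusted) pairwise p-values with group
#'   names as dimnames.
#' @param alpha significance threshold (default 0.05).
#' @return named character vector of letter strings (e.g. `"a"`, `"ab"`),
#'   one per group, in the order of the matrix rows.
#' @export
compact_letter_display <- function(p, alpha = 0.05) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  k <- nrow(p)
  lv <- rownames(p)
  if (is.null(lv)) lv <- as.character(seq_len(k))
  # letter sets: list of logical membership vectors; start with all together
  sets <- list(rep(TRUE, k))
  pairs <- utils::combn(k, 2)
  for (jj in seq_len(ncol(pairs))) {
    i <- pairs[1, jj]; j <- pairs[2, jj]
    if (is.na(p[i, j]) || p[i, j] >= alpha) next
    # significant pair: split every set containing both
    new_sets <- list()
    for (s in sets) {
      if (s[i] && s[j]) {
        s1 <- s; s1[j] <- FALSE
        s2 <- s; s2[i] <- FALSE
        new_sets <- c(new_sets, list(s1), list(s2))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop any set contained in (or duplicating) another kept set
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) {
      for (b in seq_along(new_sets)) {
        if (a == b || !keep[a] || !keep[b]) next
        subset_ab <- all(!new_sets[[a]] | new_sets[[b]])
        if (subset_ab &&
            (!identical(new_sets[[a]], new_sets[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  letters_out <- rep("", k)
  for (si in seq_along(sets)) {
    lab <- if (si <= 26) letters[si] else paste0(letters[(si - 1) %/% 26],
                                                 letters[(si - 1) %% 26 + 1])
    letters_out[sets[[si]]] <- paste0(letters_out[sets[[si]]], lab)
  }
  names(letters_out) <- lv
  letters_out
}

#' Compare one analyte across age classes
#'
#' The full Table-1-style routing for a single response: a Shapiro-Wilk
#' normality test on the one-way ANOVA residuals decides the path (at
#' `gate_alpha`): normal residuals go to ANOVA with Tukey HSD pairwise
#' comparisons; non-normal to Kruskal-Wallis with pairwise Welch tests
#' (Holm-adjusted). Pairwise p-values are summarized as a compact letter
#' display; groups not sharing a letter differ at `alpha`.
#'
#' @inheritParams tukey_hsd
#' @param alpha pairwise significance threshold for the letters (default
#'   0.05).
#' @param gate_alpha Shapiro-Wilk threshold for routing (default 0.05).
#' @param adjust adjustment for the nonparametric pairwise path.
#' @return list with `path` (`"parametric"` or `"nonparametric"`),
#'   `shapiro_p`, `statistic`, `p` (global test), `pairwise` (matrix),
#'   `letters` (named vector), `means`, `sds` (per group).
#' @export
group_compare <- function(values, groups, alpha = 0.05, gate_alpha = 0.05,
                          adjust = "holm") {
  groups <- droplevels(as.factor(groups))
  .check_groups(values, groups)
  means <- tapply(values, groups, mean)
  resid <- values - means[groups]
  shapiro_p <- if (stats::var(resid) == 0) {
    1  # constant residuals: nothing to reject, take the parametric path
  } else {
    stats::shapiro.test(resid)$p.value
  }
  if (shapiro_p >= gate_alpha) {
    path <- "parametric"
    glob <- one_way_anova(values, groups)
    pw <- tukey_hsd(values, groups)
  } else {
    path <- "nonparametric"
    glob <- kruskal_wallis(values, groups)
    pw <- pairwise_welch(values, groups, adjust = adjust)
  }
  list(path = path, shapiro_p = shapiro_p,
       statistic = glob$statistic, p = glob$p, pairwise = pw,
       letters = compact_letter_display(pw, alpha = alpha),
       means = means, sds = tapply(values, groups, stats::sd))
}

#' Compare all analytes of a chemistry table across age classes
#'
#' Applies [group_compare()] to every analyte of a long-format chemistry
#' table. Analytes with missing values are skipped with a warning.
#'
#' @param chem chemistry table: columns `sample_id`, `age_class`, `analyte`,
#'   `value` (and optionally `unit`).
#' @param alpha pairwise significance threshold (default 0.05).
#' @param gate_alpha Shapiro-Wilk routing threshold.
#' @return data frame with one row per analyte x group: `analyte`,
#'   `age_class`, `mean`, `sd`, `letter`, plus per-analyte `path` and
#'   global `p`. The full per-analyte results are attached as attribute
#'   `"details"` (a named list).
#' @export
compare_analytes <- function(chem, alpha = 0.05, gate_alpha = 0.05) {
  stopifnot(is.data.frame(chem),
            all(c("sample_id", "age_class", "analyte", "value") %in%
                  names(chem)))
  analytes <- unique(chem$analyte)
  rows <- list()
  details <- list()
  for (an in analytes) {
    sub <- chem[chem$analyte == an, , drop = FALSE]
    if (any(is.na(sub$value))) {
      warning("analyte ", an, " has missing values; skipped")
      next
    }
    res <- group_compare(sub$value, sub$age_class, alpha = alpha,
                         gate_alpha = gate_alpha)
    details[[an]] <- res
    rows[[an]] <- data.frame(
      analyte = an, age_class = names(res$letters),
      mean = as.numeric(res$means[names(res$letters)]),
      sd = as.numeric(res$sds[names(res$letters)]),
      letter = unname(res$letters), path = res$path, p = res$p,
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}
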