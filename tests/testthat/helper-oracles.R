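# Independent brute-force oracles used across the test files. These stay
# deliberately naive: full lattice scans, direct set enumeration, exhaustive
# permutation enumeration.

# Exhaustive CHNOS lattice scan: every formula in the element bounds whose
# mass falls within tolerance and which passes the plausibility filters.
# Builds the full (c, h, n, o, s) grid once and caches it.
oracle_lattice_env <- new.env()

oracle_full_grid <- function(params) {
  key <- paste(unlist(params$bounds), collapse = "_")
  if (!is.null(oracle_lattice_env[[key]])) return(oracle_lattice_env[[key]])
  b <- params$bounds
  g <- expand.grid(c = b$c[1]:b$c[2], h = b$h[1]:b$h[2], n = b$n[1]:b$n[2],
                   o = b$o[1]:b$o[2], s = b$s[1]:b$s[2],
                   KEEP.OUT.ATTRS = FALSE)
  g$mass <- g$c * 12 + g$h * 1.00782503 + g$n * 14.00307401 +
    g$o * 15.99491462 + g$s * 31.97207117
  oracle_lattice_env[[key]] <- g
  g
}

oracle_enumerate <- function(neutral_mass, params) {
  g <- oracle_full_grid(params)
  err <- (g$mass - neutral_mass) / neutral_mass * 1e6
  d <- 1 + g$c - g$h / 2 + g$n / 2
  keep <- abs(err) <= params$tolerance_ppm &
    g$h / g$c >= params$hc_range[1] & g$h / g$c <= params$hc_range[2] &
    g$o / g$c <= params$oc_max &
    d >= 0 & d <= params$dbe_max & abs(d - round(d)) < 1e-9
  out <- g[keep, c("c", "h", "n", "o", "s"), drop = FALSE]
  out[order(out$c, out$h, out$n, out$o, out$s), , drop = FALSE]
}

# canonical sorted key set for comparing candidate lists
candidate_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$c, df$h, df$n, df$o, df$s, sep = "_"))
}

# Direct chemodiversity enumeration: per-formula membership counting.
oracle_partition <- function(mat, age_class) {
  classes <- unique(as.character(age_class))
  formulas <- colnames(mat)
  present <- sapply(classes, function(cl) {
    sub <- mat[age_class == cl, , drop = FALSE]
    apply(sub > 0, 2, any)
  })
  detected <- rowSums(present) > 0
  present <- present[detected, , drop = FALSE]
  n_in <- rowSums(present)
  list(
    unique = sapply(classes, function(cl) sum(present[, cl] & n_in == 1)),
    shared_all = sum(n_in == length(classes)),
    total = sum(detected)
  )
}

# All permutations of 1..n (n small), one per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}

# Exhaustive Mantel p-value over all n! simultaneous permutations.
oracle_mantel_p <- function(d1, d2, method = "pearson") {
  v1 <- d1[lower.tri(d1)]
  r_obs <- stats::cor(v1, d2[lower.tri(d2)], method = method)
  perms <- all_permutations(nrow(d1))
  r_all <- apply(perms, 1, function(p) {
    stats::cor(v1, d2[p, p][lower.tri(d1)], method = method)
  })
  mean(r_all >= r_obs - 1e-12)
}

# Exhaustive MRPP p-value over all label orderings.
oracle_mrpp_p <- function(d, groups) {
  groups <- as.integer(as.factor(groups))
  delta_of <- function(g) {
    s <- 0
    for (k in unique(g)) {
      idx <- which(g == k)
      if (length(idx) < 2) next
      sub <- d[idx, idx]
      s <- s + length(idx) / length(g) * mean(sub[lower.tri(sub)])
    }
    s
  }
  d_obs <- delta_of(groups)
  perms <- all_permutations(length(groups))
  d_all <- apply(perms, 1, function(p) delta_of(groups[p]))
  mean(d_all <= d_obs + 1e-12)
}

# Direct one-way PERMANOVA SS decomposition from pairwise distances
# (within/between group-sum identity).
oracle_oneway_ss <- function(d, groups) {
  n <- nrow(d)
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- 0
  for (k in unique(groups)) {
    idx <- which(groups == k)
    sub <- d[idx, idx]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  list(total = ss_total, within = ss_within,
       between = ss_total - ss_within)
}

# a small, fast simulation design reused across pipeline tests
small_design <- function(seed = 1L, richness_by_class = c(150, 120, 90),
                         pool_size = 600, noise_peak_rate = 10, ...) {
  simulation_design(
    richness_by_class = richness_by_class, pool_size = pool_size,
    noise_peak_rate = noise_peak_rate, library_size = 2e4, n_families = 60,
    n_ko = 80, seed = seed, ...)
}
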