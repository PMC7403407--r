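# Seeded generators for every input the chronosequence analysis consumes:
# CHNOS formula pools, sample-by-formula intensity matrices, peak lists,
# KO/CAZyme count tables and chemistry tables. The defaults emulate the
# structure of a three-age permafrost chronosequence: declining formula
# richness and mean NOSC with age, rising SCFA and DOC concentrations, and
# count-table composition coupled to the DOM matrix. Truth records are
# always returned alongside the data so planted parameters can be recovered
# in tests.

# Table-1-analog chemistry targets: per-class means and standard deviations
# (three age classes, oldest last). Concentrations in mg/L, DOC in mg C/L,
# delta-13C in per mil (not truncated at zero).
.default_chemistry <- function() {
  m <- rbind(
    ice_content = c(39.72, 121.05, 51.75),
    chloride    = c(649.32, 95.79, 237.02),
    sulfate     = c(97.12, 56.10, 165.48),
    ammonium    = c(528.49, 556.50, 1815.74),
    nitrate     = c(0.63, 1.37, 0.48),
    nitrite     = c(0.25, 0.61, 0.26),
    d13C_DOC    = c(-26.2, -26.9, -27.8),
    DOC         = c(74.70, 124.50, 181.13),
    acetate     = c(0.91, 7.68, 40.45),
    butyrate    = c(0.00, 3.04, 30.15),
    formate     = c(0.38, 0.19, 0.34),
    propionate  = c(6.00, 0.74, 4.78),
    isovalerate = c(1.27, 1.10, 7.31),
    glutarate   = c(0.03, 0.01, 0.03),
    malate      = c(0.16, 0.18, 0.26)
  )
  s <- rbind(
    ice_content = c(10.25, 14.09, 5.24),
    chloride    = c(169.22, 7.82, 56.24),
    sulfate     = c(70.48, 8.65, 74.65),
    ammonium    = c(54.25, 40.96, 136.01),
    nitrate     = c(0.09, 1.17, 0.08),
    nitrite     = c(0.14, 0.10, 0.02),
    d13C_DOC    = c(0.3, 0.2, 0.1),
    DOC         = c(20.10, 25.87, 37.15),
    acetate     = c(0.10, 0.82, 6.89),
    butyrate    = c(0.00, 0.57, 6.49),
    formate     = c(0.04, 0.01, 0.04),
    propionate  = c(1.59, 0.06, 0.85),
    isovalerate = c(0.36, 0.32, 1.56),
    glutarate   = c(0.01, 0.00, 0.01),
    malate      = c(0.03, 0.04, 0.02)
  )
  units <- c(ice_content = "% dry wt", chloride = "mg/L", sulfate = "mg/L",
             ammonium = "mg/L", nitrate = "mg/L", nitrite = "mg/L",
             d13C_DOC = "per mil", DOC = "mg C/L", acetate = "mg/L",
             butyrate = "mg/L", formate = "mg/L", propionate = "mg/L",
             isovalerate = "mg/L", glutarate = "mg/L", malate = "mg/L")
  truncate <- !(rownames(m) %in% "d13C_DOC")
  list(means = m, sds = s, units = units, truncate_at_zero = truncate)
}

#' Simulation design for a synthetic chronosequence
#'
#' Bundles and validates every knob of the synthetic-data generators. The
#' defaults describe a three-age-class chronosequence with four replicates
#' per class, formula pools spanning 150-800 Da over mixed van Krevelen
#' compound classes, declining formula richness and mean NOSC with age, and
#' chemistry targets that mirror a permafrost filtrate characterization
#' table (rising SCFA and DOC concentrations with age).
#'
#' @param n_age_classes number of age classes (default 3).
#' @param class_labels labels, youngest first (default `"19ka"`, `"27ka"`,
#'   `"33ka"`).
#' @param replicates_per_class replicate cores per class (default 4).
#' @param richness_by_class target number of formulas detected per class
#'   (default declining: 400, 330, 260).
#' @param shared_fraction proportion of the smallest class richness present
#'   in all classes (default 0.6).
#' @param nosc_shift_by_class additive shift of each class's mean NOSC
#'   relative to the pool mean (default 0, -0.1, -0.25: declining with age).
#' @param mass_range neutral-mass interval in Da (default 150-800).
#' @param class_mixture named proportions over compound classes for the
#'   formula pool (must sum to 1).
#' @param pool_size number of formulas in the master pool (default 1200).
#' @param mass_error_sd_ppm Gaussian m/z error of true peaks, ppm (default
#'   0.1).
#' @param noise_peak_rate expected unassignable noise peaks per spectrum
#'   (default 20).
#' @param dropout_prob probability that a class-member formula is detected
#'   in any one replicate (default 0.9).
#' @param library_size reads per sample for count tables (default 1e5).
#' @param n_families number of CAZyme-like families (default 120).
#' @param n_ko number of KO-like features, markers excluded (default 150).
#' @param effect_families_fraction proportion of families with a planted age
#'   effect (default 0.1).
#' @param effect_size multiplicative abundance shift of affected families at
#'   the oldest class (default 10).
#' @param cazyme_trend_by_class per-class multiplier on the total CAZyme
#'   read yield (default 1, 0.85, 0.7: CAZyme gene content per genome
#'   declines with age while the single-copy markers stay constant, so
#'   marker-normalized CAZyme abundance declines).
#' @param marker_mean_count expected reads for each single-copy marker gene
#'   (default 200).
#' @param dom_coupling mixing weight between a global composition and the
#'   sample's DOM-derived composition for count tables (default 0.5).
#' @param chemistry list with `means`, `sds` (analyte x class matrices),
#'   `units` (named vector) and `truncate_at_zero` (logical vector); default
#'   mirrors the bundled permafrost chemistry targets.
#' @param seed default integer seed used by the generators when no explicit
#'   seed is passed.
#' @return validated list of class `simulation_design`.
#' @export
simulation_design <- function(n_age_classes = 3,
                              class_labels = c("19ka", "27ka", "33ka"),
                              replicates_per_class = 4,
                              richness_by_class = c(400, 330, 260),
                              shared_fraction = 0.6,
                              nosc_shift_by_class = c(0, -0.1, -0.25),
                              mass_range = c(150, 800),
                              class_mixture = c(
                                "lignin" = 0.45, "tannin" = 0.12,
                                "aminosugar-carbohydrate" = 0.08,
                                "protein" = 0.10, "lipid" = 0.08,
                                "unsaturated-hydrocarbon" = 0.07,
                                "condensed-aromatic" = 0.10),
                              pool_size = 1200,
                              mass_error_sd_ppm = 0.1,
                              noise_peak_rate = 20,
                              dropout_prob = 0.9,
                              library_size = 1e5,
                              n_families = 120,
                              n_ko = 150,
                              effect_families_fraction = 0.1,
                              effect_size = 10,
                              cazyme_trend_by_class = c(1, 0.85, 0.7),
                              marker_mean_count = 200,
                              dom_coupling = 0.5,
                              chemistry = .default_chemistry(),
                              seed = 1L) {
  d <- list(n_age_classes = as.integer(n_age_classes),
            class_labels = as.character(class_labels),
            replicates_per_class = as.integer(replicates_per_class),
            richness_by_class = as.integer(richness_by_class),
            shared_fraction = shared_fraction,
            nosc_shift_by_class = nosc_shift_by_class,
            mass_range = mass_range, class_mixture = class_mixture,
            pool_size = as.integer(pool_size),
            mass_error_sd_ppm = mass_error_sd_ppm,
            noise_peak_rate = noise_peak_rate,
            dropout_prob = dropout_prob,
            library_size = as.integer(library_size),
            n_families = as.integer(n_families), n_ko = as.integer(n_ko),
            effect_families_fraction = effect_families_fraction,
            effect_size = effect_size,
            cazyme_trend_by_class = cazyme_trend_by_class,
            marker_mean_count = marker_mean_count,
            dom_coupling = dom_coupling, chemistry = chemistry,
            seed = as.integer(seed))
  validate_design(d)
}

#' @rdname simulation_design
#' @param design a design list to validate.
#' @export
validate_design <- function(design) {
  d <- design
  k <- d$n_age_classes
  if (k < 2L) stop("need at least two age classes")
  if (length(d$class_labels) != k) stop("class_labels length != n_age_classes")
  if (d$replicates_per_class < 1L) stop("replicates_per_class must be >= 1")
  if (length(d$richness_by_class) != k || any(d$richness_by_class < 1L)) {
    stop("richness_by_class must hold one positive count per class")
  }
  for (p in c("shared_fraction", "dropout_prob", "effect_families_fraction",
              "dom_coupling")) {
    if (d[[p]] < 0 || d[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (length(d$nosc_shift_by_class) != k) {
    stop("nosc_shift_by_class must hold one shift per class")
  }
  if (length(d$mass_range) != 2L || d$mass_range[1] <= 0 ||
      d$mass_range[1] >= d$mass_range[2]) {
    stop("mass_range must be a positive increasing interval")
  }
  if (abs(sum(d$class_mixture) - 1) > 1e-8 || any(d$class_mixture < 0)) {
    stop("class_mixture proportions must be non-negative and sum to 1")
  }
  if (is.null(names(d$class_mixture))) stop("class_mixture must be named")
  if (d$pool_size < max(d$richness_by_class)) {
    stop("pool_size must be at least the largest class richness")
  }
  if (d$mass_error_sd_ppm < 0 || d$noise_peak_rate < 0) {
    stop("mass_error_sd_ppm and noise_peak_rate must be non-negative")
  }
  if (d$library_size < 1L) stop("library_size must be positive")
  if (d$n_families < 1L || d$n_ko < 1L) stop("feature counts must be positive")
  if (d$effect_size <= 0) stop("effect_size must be positive")
  if (length(d$cazyme_trend_by_class) != k || any(d$cazyme_trend_by_class <= 0)) {
    stop("cazyme_trend_by_class must hold one positive multiplier per class")
  }
  ch <- d$chemistry
  if (!all(dim(ch$means) == dim(ch$sds)) || ncol(ch$means) != k) {
    stop("chemistry means/sds must be analyte x class matrices")
  }
  if (any(ch$sds < 0)) stop("chemistry sds must be non-negative")
  structure(d, class = "simulation_design")
}

# -- formula lattice --------------------------------------------------------

.lattice_cache <- new.env(parent = emptyenv())

#' Enumerate the chemically plausible CHNOS formula lattice
#'
#' All formulas inside a mass window that satisfy the assignment-module
#' plausibility filters (H:C in 0.3-2.25, O:C <= 1.2, integer DBE in 0-25)
#' over a compact element range typical of dissolved organic matter (N <= 2,
#' S <= 1). Used as the sampling frame for synthetic formula pools; results
#' are memoized per mass range.
#'
#' @param mass_range Da interval.
#' @return data frame with columns `c`, `h`, `n`, `o`, `s`, `formula`,
#'   `mass`, `nosc`, `class`.
#' @export
formula_lattice <- function(mass_range = c(150, 800)) {
  key <- paste0(mass_range, collapse = "_")
  if (!is.null(.lattice_cache[[key]])) return(.lattice_cache[[key]])
  base <- expand.grid(c = 4:60, n = 0:2, o = 0:30, s = 0:1,
                      KEEP.OUT.ATTRS = FALSE)
  base <- base[base$o <= 1.2 * base$c, , drop = FALSE]
  # DBE in [0, 25]: 2c + n - 48 <= h <= 2 + 2c + n
  h_lo <- pmax(1, ceiling(0.3 * base$c), 2L * base$c + base$n - 48L)
  h_hi <- pmin(122, floor(2.25 * base$c), 2L + 2L * base$c + base$n)
  # parity: DBE integer requires h = n (mod 2)
  h_lo <- h_lo + as.integer((h_lo %% 2L) != (base$n %% 2L))
  cnt <- pmax(0L, (h_hi - h_lo) %/% 2L + 1L)
  keep <- cnt > 0L
  base <- base[keep, , drop = FALSE]
  h_lo <- h_lo[keep]; cnt <- cnt[keep]
  idx <- rep(seq_len(nrow(base)), cnt)
  f <- data.frame(c = base$c[idx],
                  h = h_lo[idx] + 2L * (sequence(cnt) - 1L),
                  n = base$n[idx], o = base$o[idx], s = base$s[idx])
  f$mass <- formula_mass(f)
  f <- f[f$mass >= mass_range[1] & f$mass <= mass_range[2], , drop = FALSE]
  f$formula <- format_formula(f)
  f <- f[!duplicated(f$formula), , drop = FALSE]
  f$nosc <- nosc(f)
  f$class <- classify_formula(f)
  rownames(f) <- NULL
  .lattice_cache[[key]] <- f
  f
}

#' Simulate a formula pool with planted compound-class mixture
#'
#' Samples `pool_size` formulas from the plausible-formula lattice, class by
#' class according to `class_mixture`. Every pool formula passes the
#' assignment plausibility filters by construction and carries its true
#' class label.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed (default: the design's seed).
#' @return data frame: columns `c`, `h`, `n`, `o`, `s`, `formula`, `mass`,
#'   `nosc`, `class`.
#' @export
simulate_formula_pool <- function(design, seed = design$seed) {
  design <- validate_design(design)
  lat <- formula_lattice(design$mass_range)
  mix <- design$class_mixture
  counts <- round(mix * design$pool_size)
  with_seed(seed, {
    parts <- lapply(names(mix), function(cl) {
      want <- counts[[cl]]
      if (want == 0L) return(NULL)
      avail <- which(lat$class == cl)
      if (length(avail) == 0L) {
        stop("class_mixture demands class '", cl,
             "' but no feasible formula of that class exists in mass range ",
             design$mass_range[1], "-", design$mass_range[2], " Da")
      }
      lat[sample(avail, want, replace = length(avail) < want), , drop = FALSE]
    })
    pool <- do.call(rbind, parts)
    pool <- pool[!duplicated(pool$formula), , drop = FALSE]
    rownames(pool) <- NULL
    pool
  })
}

#' Simulate a sample-by-formula intensity matrix
#'
#' Builds the per-class formula membership sets (a common core of size
#' `shared_fraction * min(richness)` plus class-specific extras drawn so the
#' class mean NOSC lands near the pool mean plus the planted per-class
#' shift), then detects each class member in each replicate with probability
#' `dropout_prob` and assigns log-normal intensities.
#'
#' @param pool formula pool from [simulate_formula_pool()].
#' @param design a [simulation_design()].
#' @param seed integer seed (default: design seed + 1).
#' @return list: `matrix` (samples x formulas intensities), `metadata`
#'   (sample_id, age_class, replicate), `class_sets` (true per-class
#'   membership, named by class label), `core` (the all-classes core set).
#' @export
simulate_dom_matrix <- function(pool, design, seed = design$seed + 1L) {
  design <- validate_design(design)
  k <- design$n_age_classes
  rich <- design$richness_by_class
  if (max(rich) > nrow(pool)) {
    stop("requested richness (", max(rich), ") exceeds pool size (",
         nrow(pool), ")")
  }
  with_seed(seed, {
    core_size <- round(design$shared_fraction * min(rich))
    core_idx <- sample(nrow(pool), core_size)
    base_mean <- mean(pool$nosc)
    class_sets <- vector("list", k)
    for (cl in seq_len(k)) {
      extras_n <- rich[cl] - core_size
      if (extras_n > 0L) {
        avail <- setdiff(seq_len(nrow(pool)), core_idx)
        shift <- design$nosc_shift_by_class[cl]
        target <- base_mean + shift * rich[cl] / extras_n
        w <- stats::dnorm(pool$nosc[avail], mean = target, sd = 0.3) + 1e-12
        extras <- sample(avail, extras_n, prob = w)
      } else {
        extras <- integer(0)
      }
      class_sets[[cl]] <- sort(c(core_idx, extras))
    }
    names(class_sets) <- design$class_labels
    all_idx <- sort(unique(unlist(class_sets)))
    formulas <- pool$formula[all_idx]
    n_samp <- k * design$replicates_per_class
    mat <- matrix(0, n_samp, length(all_idx))
    meta <- data.frame(sample_id = character(n_samp),
                       age_class = character(n_samp),
                       replicate = integer(n_samp))
    row <- 0L
    for (cl in seq_len(k)) {
      members <- match(class_sets[[cl]], all_idx)
      for (r in seq_len(design$replicates_per_class)) {
        row <- row + 1L
        det <- members[stats::runif(length(members)) < design$dropout_prob]
        mat[row, det] <- stats::rlnorm(length(det), meanlog = 0, sdlog = 1)
        meta$sample_id[row] <- paste0(design$class_labels[cl], "_r", r)
        meta$age_class[row] <- design$class_labels[cl]
        meta$replicate[row] <- r
      }
    }
    rownames(mat) <- meta$sample_id
    colnames(mat) <- formulas
    list(matrix = mat, metadata = meta,
         class_sets = lapply(class_sets, function(i) pool$formula[i]),
         core = pool$formula[sort(core_idx)])
  })
}

#' Simulate per-sample peak lists from a formula matrix
#'
#' Inverts formula assignment: every detected formula becomes a singly
#' charged deprotonated ion whose m/z is perturbed by Gaussian error of
#' standard deviation `mass_error_sd_ppm`; Poisson-distributed noise peaks
#' are drawn uniformly over the m/z range. Every peak is flagged in the
#' returned truth table.
#'
#' @param dom result of [simulate_dom_matrix()] (or a bare formula matrix).
#' @param design a [simulation_design()].
#' @param seed integer seed (default: design seed + 2).
#' @return named list (one element per sample), each a list with `peaks`
#'   (data frame `mz`, `intensity`, `sn`, sorted by m/z) and `truth` (data
#'   frame `mz`, `formula` (`NA` for noise), `is_noise`).
#' @export
simulate_peaklists <- function(dom, design, seed = design$seed + 2L) {
  design <- validate_design(design)
  mat <- if (is.list(dom) && !is.null(dom$matrix)) dom$matrix else dom
  check_formula_matrix(mat)
  masses <- formula_mass(colnames(mat))
  mz_true_all <- neutral_to_mz(masses)
  mz_lo <- neutral_to_mz(design$mass_range[1])
  mz_hi <- neutral_to_mz(design$mass_range[2])
  with_seed(seed, {
    out <- lapply(seq_len(nrow(mat)), function(i) {
      det <- which(mat[i, ] > 0)
      mz <- mz_true_all[det] *
        (1 + stats::rnorm(length(det)) * design$mass_error_sd_ppm * 1e-6)
      n_noise <- stats::rpois(1, design$noise_peak_rate)
      noise_mz <- stats::runif(n_noise, mz_lo, mz_hi)
      peaks <- data.frame(
        mz = c(mz, noise_mz),
        intensity = c(mat[i, det],
                      stats::rlnorm(n_noise, meanlog = -1, sdlog = 0.5)),
        sn = 6 + stats::rexp(length(det) + n_noise, rate = 1 / 40))
      truth <- data.frame(
        mz = peaks$mz,
        formula = c(colnames(mat)[det], rep(NA_character_, n_noise)),
        is_noise = c(rep(FALSE, length(det)), rep(TRUE, n_noise)))
      ord <- order(peaks$mz)
      list(peaks = peaks[ord, , drop = FALSE],
           truth = truth[ord, , drop = FALSE])
    })
    names(out) <- rownames(mat)
    out
  })
}

#' Simulate KO-like and CAZyme-like count tables
#'
#' Draws multinomial read counts from per-sample composition vectors: the KO
#' table at `library_size` reads per sample, the CAZyme table at
#' `library_size` scaled by the planted per-class yield trend
#' (`cazyme_trend_by_class`). Single-copy marker genes (K02874,
#' K02950, K02992, K02519) are included in the KO table with near-constant
#' expected relative abundance. A planted fraction of CAZyme families is
#' shifted multiplicatively along the age order (reaching `effect_size` at
#' the oldest class). When a DOM matrix is supplied, each sample's
#' composition is a convex mixture (weight `dom_coupling`) of the class
#' composition and a composition derived from that sample's DOM profile
#' through a fixed random loading matrix, so that the Bray-Curtis structure
#' of the count tables covaries with the DOM matrix by construction.
#'
#' @param design a [simulation_design()].
#' @param dom optional result of [simulate_dom_matrix()] for DOM coupling
#'   (also supplies sample ids and age classes).
#' @param seed integer seed (default: design seed + 3).
#' @return list: `ko` and `cazyme` count matrices (features x samples),
#'   `metadata`, `truth` (list with `effect_families`, `markers`,
#'   `effect_multipliers`).
#' @export
simulate_count_tables <- function(design, dom = NULL,
                                  seed = design$seed + 3L) {
  design <- validate_design(design)
  k <- design$n_age_classes
  markers <- c("K02874", "K02950", "K02992", "K02519")
  if (!is.null(dom)) {
    meta <- dom$metadata
  } else {
    meta <- expand.grid(replicate = seq_len(design$replicates_per_class),
                        age_class = design$class_labels,
                        KEEP.OUT.ATTRS = FALSE)
    meta$sample_id <- paste0(meta$age_class, "_r", meta$replicate)
    meta <- meta[, c("sample_id", "age_class", "replicate")]
  }
  n_samp <- nrow(meta)
  class_idx <- match(meta$age_class, design$class_labels)
  if (design$library_size < design$n_families) {
    warning("library_size below the number of families; tables will be sparse")
  }
  with_seed(seed, {
    make_table <- function(features, n_eff, marker_ids = character(0),
                           lib_by_sample) {
      n_feat <- length(features)
      base_w <- stats::rlnorm(n_feat, meanlog = 0, sdlog = 1.2)
      names(base_w) <- features
      eff_ids <- character(0)
      mult <- matrix(1, n_feat, k, dimnames = list(features, NULL))
      if (n_eff > 0L) {
        cand <- setdiff(features, marker_ids)
        eff_ids <- sample(cand, n_eff)
        grade <- design$effect_size^((seq_len(k) - 1) / (k - 1))
        mult[eff_ids, ] <- matrix(grade, n_eff, k, byrow = TRUE)
      }
      dom_comp <- NULL
      if (!is.null(dom)) {
        # fixed loading matrix couples DOM composition to feature space
        load <- matrix(stats::rlnorm(ncol(dom$matrix) * n_feat, 0, 1),
                       ncol(dom$matrix), n_feat)
        rel <- dom$matrix / rowSums(dom$matrix)
        dom_comp <- rel %*% load          # samples x features
        dom_comp <- dom_comp / rowSums(dom_comp)
      }
      counts <- matrix(0L, n_feat, n_samp,
                       dimnames = list(features, meta$sample_id))
      marker_frac <- design$marker_mean_count / design$library_size
      for (s in seq_len(n_samp)) {
        cl <- class_idx[s]
        w <- base_w * mult[, cl]
        p <- w / sum(w)
        if (!is.null(dom_comp)) {
          p <- (1 - design$dom_coupling) * p +
            design$dom_coupling * dom_comp[s, ]
        }
        if (length(marker_ids) > 0L) {
          p[marker_ids] <- 0
          p <- p / sum(p) * (1 - length(marker_ids) * marker_frac)
          p[marker_ids] <- marker_frac
        }
        counts[, s] <- stats::rmultinom(1, lib_by_sample[s], p)
      }
      list(counts = counts, effect = eff_ids, mult = mult)
    }
    ko_feats <- c(markers, sprintf("K%05d", 10000 + seq_len(design$n_ko)))
    ko <- make_table(ko_feats, n_eff = 0L, marker_ids = markers,
                     lib_by_sample = rep(design$library_size, n_samp))
    caz_feats <- sprintf("GH%d", seq_len(design$n_families))
    n_eff <- round(design$effect_families_fraction * design$n_families)
    # planted decline of total CAZyme yield relative to the (constant)
    # single-copy markers of the KO table
    caz_lib <- round(design$library_size *
                       design$cazyme_trend_by_class[class_idx])
    caz <- make_table(caz_feats, n_eff = n_eff, lib_by_sample = caz_lib)
    list(ko = ko$counts, cazyme = caz$counts, metadata = meta,
         truth = list(effect_families = caz$effect, markers = markers,
                      effect_multipliers = caz$mult,
                      cazyme_library = caz_lib))
  })
}

#' Simulate a Table-1-style chemistry table
#'
#' Draws per-sample analyte values from per-class Gaussians (truncated at
#' zero for concentrations), using the design's chemistry targets.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed (default: design seed + 4).
#' @return long-format data frame: `sample_id`, `age_class`, `replicate`,
#'   `analyte`, `value`, `unit`.
#' @export
simulate_chemistry_table <- function(design, seed = design$seed + 4L) {
  design <- validate_design(design)
  ch <- design$chemistry
  k <- design$n_age_classes
  reps <- design$replicates_per_class
  if (!any(rownames(ch$means) == "DOC")) {
    stop("chemistry targets must include DOC")
  }
  with_seed(seed, {
    rows <- list()
    for (cl in seq_len(k)) {
      for (r in seq_len(reps)) {
        sid <- paste0(design$class_labels[cl], "_r", r)
        v <- stats::rnorm(nrow(ch$means), ch$means[, cl], ch$sds[, cl])
        tr <- ch$truncate_at_zero
        v[tr] <- pmax(v[tr], 0)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, age_class = design$class_labels[cl],
          replicate = r, analyte = rownames(ch$means), value = v,
          unit = unname(ch$units[rownames(ch$means)]))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
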