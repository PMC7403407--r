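#' Nominal oxidation state of carbon
#'
#' Computes NOSC from elemental stoichiometry:
#' \deqn{NOSC = 4 - \frac{4c + h - 3n - 2o - 2s}{c}}
#' where `c`, `h`, `n`, `o`, `s` are atom counts per formula. More reduced
#' carbon compounds have lower (more negative) NOSC; more oxidized compounds
#' score higher. NOSC is an indirect measure of the thermodynamic
#' favorability of a substrate for microbial respiration.
#'
#' @param f formula table (see [molecular_formula()]) or character vector of
#'   Hill-notation strings.
#' @return numeric vector of NOSC values (dimensionless).
#' @examples
#' nosc(c("C6H12O6", "CH2O2"))  # 0 (carbohydrate), +2 (formic acid)
#' @export
nosc <- function(f) {
  f <- as_formula_table(f)
  if (any(f$c < 1L)) stop("NOSC requires at least one carbon atom")
  4 - (4 * f$c + f$h - 3 * f$n - 2 * f$o - 2 * f$s) / f$c
}

#' Elemental ratios for van Krevelen analysis
#'
#' @param f formula table or character vector of formula strings.
#' @return data frame with columns `hc` (H:C) and `oc` (O:C) molar ratios.
#' @export
element_ratios <- function(f) {
  f <- as_formula_table(f)
  if (any(f$c < 1L)) stop("element ratios require at least one carbon atom")
  data.frame(hc = f$h / f$c, oc = f$o / f$c)
}

#' Double-bond equivalents
#'
#' Rings plus pi-bonds implied by a CHNOS formula: `1 + c - h/2 + n/2`.
#'
#' @param f formula table or character vector of formula strings.
#' @return numeric vector.
#' @export
dbe <- function(f) {
  f <- as_formula_table(f)
  1 + f$c - f$h / 2 + f$n / 2
}

#' Modified aromaticity index
#'
#' AImod = (1 + c - 0.5 o - s - 0.5 h) / (c - 0.5 o - s - n), with the
#' convention that a non-positive denominator or a negative value yields 0.
#' High values indicate condensed aromatic structures; AImod >= 0.67 is the
#' conventional condensed-aromatic threshold.
#'
#' @param f formula table or character vector of formula strings.
#' @return numeric vector in `[0, Inf)` (0 for non-aromatic formulas).
#' @export
aimod <- function(f) {
  f <- as_formula_table(f)
  num <- 1 + f$c - 0.5 * f$o - f$s - 0.5 * f$h
  den <- f$c - 0.5 * f$o - f$s - f$n
  out <- ifelse(den > 0, num / den, 0)
  pmax(out, 0)
}

#' Default van Krevelen compound-class boundaries
#'
#' An ordered rule table mapping a formula's H:C, O:C, AImod and nitrogen
#' content to one of seven biochemical compound classes. Rules are evaluated
#' in priority order and the first match wins; formulas matching no rule fall
#' to `"unclassified"`. The default boundaries follow standard van Krevelen
#' conventions for dissolved organic matter:
#'
#' 1. condensed-aromatic: AImod >= 0.67
#' 2. tannin: O:C > 0.67, H:C < 1.5
#' 3. aminosugar-carbohydrate: O:C > 0.67, H:C >= 1.5
#' 4. lipid: H:C >= 1.5, O:C <= 0.2, no nitrogen
#' 5. protein: H:C >= 1.5, 0.2 < O:C <= 0.67, nitrogen present
#' 6. unsaturated-hydrocarbon: O:C <= 0.1, 0.7 <= H:C < 1.5
#' 7. lignin: 0.1 < O:C <= 0.67, 0.7 <= H:C < 1.5
#'
#' @return a data frame with one row per rule and columns `class`,
#'   `hc_min`, `hc_max` (half-open: `hc_min <= hc < hc_max` unless
#'   `hc_min_closed`/`hc_max_closed` say otherwise), `oc_min`, `oc_max`,
#'   `aimod_min`, `n_min`, `n_max`. `NA` means unconstrained. Pass a
#'   modified copy to [classify_formula()] to override boundaries.
#' @export
default_class_boundaries <- function() {
  rule <- function(class, hc_min = NA, hc_max = NA, hc_max_closed = FALSE,
                   oc_min = NA, oc_max = NA, oc_min_open = FALSE,
                   aimod_min = NA, n_min = NA, n_max = NA) {
    data.frame(class = class, hc_min = hc_min, hc_max = hc_max,
               hc_max_closed = hc_max_closed, oc_min = oc_min,
               oc_max = oc_max, oc_min_open = oc_min_open,
               aimod_min = aimod_min, n_min = n_min, n_max = n_max)
  }
  rbind(
    rule("condensed-aromatic", aimod_min = 0.67),
    rule("tannin", hc_max = 1.5, oc_min = 0.67, oc_min_open = TRUE),
    rule("aminosugar-carbohydrate", hc_min = 1.5, oc_min = 0.67,
         oc_min_open = TRUE),
    rule("lipid", hc_min = 1.5, oc_max = 0.2, n_max = 0),
    rule("protein", hc_min = 1.5, oc_min = 0.2, oc_min_open = TRUE,
         oc_max = 0.67, n_min = 1),
    rule("unsaturated-hydrocarbon", hc_min = 0.7, hc_max = 1.5,
         oc_max = 0.1),
    rule("lignin", hc_min = 0.7, hc_max = 1.5, oc_min = 0.1,
         oc_min_open = TRUE, oc_max = 0.67)
  )
}

#' Classify formulas into van Krevelen compound classes
#'
#' Evaluates the boundary rules in priority order (first match wins) and is
#' total: formulas matching no rule are labelled `"unclassified"`.
#'
#' @param f formula table or character vector of formula strings.
#' @param table boundary rule table, by default
#'   [default_class_boundaries()].
#' @return character vector of class labels, one per formula.
#' @export
classify_formula <- function(f, table = default_class_boundaries()) {
  f <- as_formula_table(f)
  r <- element_ratios(f)
  ai <- aimod(f)
  out <- rep("unclassified", nrow(f))
  unmatched <- rep(TRUE, nrow(f))
  for (k in seq_len(nrow(table))) {
    rl <- table[k, ]
    hit <- unmatched
    if (!is.na(rl$aimod_min)) hit <- hit & ai >= rl$aimod_min
    if (!is.na(rl$hc_min)) hit <- hit & r$hc >= rl$hc_min
    if (!is.na(rl$hc_max)) {
      hit <- hit & if (isTRUE(rl$hc_max_closed)) r$hc <= rl$hc_max else r$hc < rl$hc_max
    }
    if (!is.na(rl$oc_min)) {
      hit <- hit & if (isTRUE(rl$oc_min_open)) r$oc > rl$oc_min else r$oc >= rl$oc_min
    }
    if (!is.na(rl$oc_max)) hit <- hit & r$oc <= rl$oc_max
    if (!is.na(rl$n_min)) hit <- hit & f$n >= rl$n_min
    if (!is.na(rl$n_max)) hit <- hit & f$n <= rl$n_max
    out[hit] <- rl$class
    unmatched <- unmatched & !hit
  }
  out
}

#' Per-formula chemistry metrics table
#'
#' Convenience wrapper computing mass, elemental ratios, DBE, AImod, NOSC
#' and compound class for a set of formulas.
#'
#' @param f formula table or character vector of formula strings.
#' @param table boundary rule table for classification.
#' @return data frame with columns `formula`, `mass`, `hc`, `oc`, `dbe`,
#'   `aimod`, `nosc`, `class`.
#' @export
formula_metrics <- function(f, table = default_class_boundaries()) {
  f <- as_formula_table(f)
  r <- element_ratios(f)
  data.frame(formula = format_formula(f), mass = formula_mass(f),
             hc = r$hc, oc = r$oc, dbe = dbe(f), aimod = aimod(f),
             nosc = nosc(f), class = classify_formula(f, table))
}

# -- formula matrix (samples x formulas) -----------------------------------

# A formula matrix is a plain numeric matrix: rows = samples (rownames =
# sample ids), columns = formulas (colnames = Hill strings), entries =
# intensities with 0 meaning "not detected". Age-class labels travel in a
# separate metadata data frame (sample_id, age_class, replicate), vegan
# style.

check_formula_matrix <- function(mat) {
  if (!is.matrix(mat) || is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("formula matrix must be a numeric matrix with sample rownames ",
         "and formula colnames")
  }
  if (any(mat < 0)) stop("intensities must be non-negative")
  if (anyDuplicated(colnames(mat))) stop("duplicate formula columns")
  invisible(mat)
}

#' Per-sample mean NOSC
#'
#' The NOSC of the individual compounds detected in a sample (intensity
#' greater than zero) are averaged to give the NOSC of the dissolved organic
#' carbon in that sample. The average is unweighted (presence-based) by
#' default; set `weighted = TRUE` for an intensity-weighted variant.
#'
#' @param mat formula matrix (samples x formulas; see package overview).
#' @param weighted if `TRUE`, weight each formula's NOSC by its intensity.
#' @return named numeric vector, one mean NOSC per sample.
#' @export
sample_mean_nosc <- function(mat, weighted = FALSE) {
  check_formula_matrix(mat)
  vals <- nosc(colnames(mat))
  out <- vapply(seq_len(nrow(mat)), function(i) {
    det <- mat[i, ] > 0
    if (!any(det)) stop("sample ", rownames(mat)[i], " has no detections")
    if (weighted) {
      sum(vals[det] * mat[i, det]) / sum(mat[i, det])
    } else {
      mean(vals[det])
    }
  }, numeric(1))
  names(out) <- rownames(mat)
  out
}

#' Chemodiversity partition across age classes
#'
#' A formula is counted as present in an age class when it is detected in
#' any replicate of that class. Unique formulas are present in exactly one
#' class; shared formulas in two or more. The partition cells (per-class
#' unique counts, pairwise-only shared counts, the all-classes core and the
#' total) are computed by exact set algebra and always sum to the total
#' number of distinct detected formulas.
#'
#' @param mat formula matrix (samples x formulas).
#' @param age_class factor or character vector of class labels, one per
#'   sample row (at least two distinct classes).
#' @return an object of class `chemodiversity_partition`: a list with
#'   `unique` (named per-class counts), `shared` (named counts per class
#'   combination, names like `"19ka&27ka"`), `shared_all` (count present in
#'   every class), `total` (distinct formulas detected anywhere) and
#'   `class_sets` (the per-class presence sets).
#' @export
chemodiversity_partition <- function(mat, age_class) {
  check_formula_matrix(mat)
  age_class <- as.character(age_class)
  stopifnot(length(age_class) == nrow(mat))
  classes <- unique(age_class)
  if (length(classes) < 2L) stop("need at least two age classes")
  sets <- lapply(classes, function(cl) {
    sub <- mat[age_class == cl, , drop = FALSE]
    colnames(sub)[colSums(sub > 0) > 0]
  })
  names(sets) <- classes
  all_formulas <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_formulas %in% s,
                       logical(length(all_formulas)))
  if (length(all_formulas) == 1L) membership <- matrix(membership, nrow = 1L)
  n_in <- rowSums(membership)
  uniq <- vapply(seq_along(classes), function(j) {
    sum(membership[, j] & n_in == 1L)
  }, numeric(1))
  names(uniq) <- classes
  combos <- character(0)
  shared <- numeric(0)
  if (length(classes) >= 2L) {
    for (m in 2:length(classes)) {
      cmb <- utils::combn(seq_along(classes), m)
      for (j in seq_len(ncol(cmb))) {
        idx <- cmb[, j]
        cnt <- sum(rowSums(membership[, idx, drop = FALSE]) == m & n_in == m)
        combos <- c(combos, paste(classes[idx], collapse = "&"))
        shared <- c(shared, cnt)
      }
    }
  }
  names(shared) <- combos
  structure(list(unique = uniq, shared = shared,
                 shared_all = sum(n_in == length(classes)),
                 total = length(all_formulas), class_sets = sets),
            class = "chemodiversity_partition")
}

#' @export
print.chemodiversity_partition <- function(x, ...) {
  cat("Chemodiversity partition over", length(x$unique), "age classes\n")
  cat("  total distinct formulas:", x$total, "\n")
  cat("  unique per class:",
      paste(names(x$unique), x$unique, sep = "=", collapse = ", "), "\n")
  cat("  shared:",
      paste(names(x$shared), x$shared, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample compound-class relative abundance
#'
#' Proportion of detected formulas in each compound class, per sample
#' (counts of detections, not intensity-weighted). Rows sum to 1.
#'
#' @param mat formula matrix.
#' @param table boundary rule table for classification.
#' @return matrix samples x classes of proportions.
#' @export
class_relative_abundance <- function(mat, table = default_class_boundaries()) {
  check_formula_matrix(mat)
  cls <- classify_formula(colnames(mat), table)
  levels <- unique(c(table$class, "unclassified"))
  out <- t(apply(mat > 0, 1, function(det) {
    if (!any(det)) stop("sample with no detections")
    tab <- table(factor(cls[det], levels = levels))
    as.numeric(tab) / sum(det)
  }))
  colnames(out) <- levels
  rownames(out) <- rownames(mat)
  out
}

# -- SCFA / DOC chemistry ---------------------------------------------------

#' Short-chain fatty acid definitions
#'
#' The SCFA analytes tracked by the chronosequence analysis, with their
#' molecular formulas (used to derive carbon counts and molar masses for
#' unit conversion in [scfa_carbon_fraction()]).
#'
#' @return data frame with columns `analyte`, `formula`, `carbons`,
#'   `molar_mass` (g/mol).
#' @export
scfa_definitions <- function() {
  def <- data.frame(
    analyte = c("acetate", "butyrate", "formate", "propionate",
                "isovalerate", "glutarate", "malate"),
    formula = c("C2H4O2", "C4H8O2", "CH2O2", "C3H6O2",
                "C5H10O2", "C5H8O4", "C4H6O5")
  )
  f <- parse_formula(def$formula)
  def$carbons <- f$c
  # average (not monoisotopic) molar masses are the right constant for
  # converting bulk concentrations; CHNOS standard atomic weights
  aw <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
  def$molar_mass <- f$c * aw[["C"]] + f$h * aw[["H"]] + f$n * aw[["N"]] +
    f$o * aw[["O"]] + f$s * aw[["S"]]
  def
}

# molar carbon concentration (mmol C / L) from a value + unit + formula info
.to_mmol_c_per_l <- function(value, unit, carbons, molar_mass) {
  switch(unit,
         "mmol/L" = value * carbons,
         "umol/L" = value * carbons / 1000,
         "mol/L" = value * carbons * 1000,
         "mg/L" = value / molar_mass * carbons,
         "mmol C/L" = value,
         "umol C/L" = value / 1000,
         "mg C/L" = value / 12.011,
         stop("unit '", unit, "' is not convertible to molar carbon; ",
              "supported: mmol/L, umol/L, mol/L, mg/L (with formula), ",
              "mmol C/L, umol C/L, mg C/L"))
}

#' SCFA share of dissolved organic carbon
#'
#' Fraction (percent) of a sample's DOC carbon attributable to measured
#' short-chain fatty acids, on a molar-carbon basis:
#' `100 * sum(SCFA molar concentration x carbons per molecule) / DOC molar
#' carbon`. Units must be given explicitly per analyte; the function never
#' guesses units.
#'
#' @param chem chemistry table in long format: columns `sample_id`,
#'   `analyte`, `value`, `unit`. Must contain a `DOC` row per sample in a
#'   carbon-molar-convertible unit (`mg C/L`, `mmol C/L`, `umol C/L`).
#' @param scfa SCFA definition table, by default [scfa_definitions()];
#'   analytes present in `chem` but not in this table are ignored.
#' @return named numeric vector: percent of DOC carbon in SCFAs, per sample.
#' @examples
#' chem <- data.frame(sample_id = "s1",
#'                    analyte = c("acetate", "DOC"),
#'                    value = c(5, 100),
#'                    unit = c("mmol/L", "mmol C/L"))
#' scfa_carbon_fraction(chem)  # 10%
#' @export
scfa_carbon_fraction <- function(chem, scfa = scfa_definitions()) {
  stopifnot(is.data.frame(chem),
            all(c("sample_id", "analyte", "value", "unit") %in% names(chem)))
  if (any(is.na(chem$unit) | !nzchar(chem$unit))) {
    stop("every chemistry row needs an explicit unit")
  }
  samples <- unique(chem$sample_id)
  out <- vapply(samples, function(sid) {
    sub <- chem[chem$sample_id == sid, , drop = FALSE]
    doc <- sub[sub$analyte == "DOC", , drop = FALSE]
    if (nrow(doc) != 1L) stop("sample ", sid, ": need exactly one DOC row")
    if (!doc$unit %in% c("mg C/L", "mmol C/L", "umol C/L")) {
      stop("sample ", sid, ": DOC unit '", doc$unit,
           "' is not carbon-molar-convertible (use mg C/L, mmol C/L, umol C/L)")
    }
    doc_c <- .to_mmol_c_per_l(doc$value, doc$unit, NA, NA)
    rows <- sub[sub$analyte %in% scfa$analyte, , drop = FALSE]
    if (nrow(rows) == 0L) return(0)
    idx <- match(rows$analyte, scfa$analyte)
    scfa_c <- sum(mapply(.to_mmol_c_per_l, rows$value, rows$unit,
                         scfa$carbons[idx], scfa$molar_mass[idx]))
    100 * scfa_c / doc_c
  }, numeric(1))
  names(out) <- samples
  out
}
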