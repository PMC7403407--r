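#' Parameters for molecular-formula assignment
#'
#' Bundles the mass tolerance, signal-to-noise threshold, element bounds and
#' chemical-plausibility filters used by [enumerate_candidates()] and
#' [assign_peaklist()]. Defaults follow common practice for natural dissolved
#' organic matter assigned from negative-mode FT-ICR MS spectra and are fully
#' configurable.
#'
#' @param tolerance_ppm maximum |mass error| in parts per million, referenced
#'   to the observed neutral mass (default 0.5).
#' @param sn_min minimum signal-to-noise ratio for a peak to be considered
#'   (default 6; peaks below are reported with status `"filtered"`).
#' @param bounds named list of `c(lower, upper)` atom-count bounds for the
#'   elements `c`, `h`, `n`, `o`, `s`.
#' @param hc_range allowed H:C molar-ratio interval.
#' @param oc_max maximum O:C molar ratio.
#' @param dbe_max maximum double-bond equivalents (default 25). A DBE cap is
#'   part of established plausibility rules for natural organic matter; it
#'   also removes the near-mass-degenerate C21H12/O13S substitution (0.14
#'   mDa), whose decoy candidates differ from the true formula by ~27 DBE
#'   and would otherwise steal a few percent of high-mass assignments.
#' @return an object of class `assignment_params`.
#' @export
assignment_params <- function(tolerance_ppm = 0.5,
                              sn_min = 6,
                              bounds = list(c = c(1L, 60L), h = c(1L, 122L),
                                            n = c(0L, 4L), o = c(0L, 30L),
                                            s = c(0L, 2L)),
                              hc_range = c(0.3, 2.25),
                              oc_max = 1.2,
                              dbe_max = 25) {
  stopifnot(tolerance_ppm > 0, sn_min >= 0,
            length(hc_range) == 2L, hc_range[1L] <= hc_range[2L],
            oc_max > 0, dbe_max >= 0)
  for (el in c("c", "h", "n", "o", "s")) {
    b <- bounds[[el]]
    if (is.null(b) || length(b) != 2L || b[1L] > b[2L] || any(b < 0)) {
      stop("invalid bounds for element ", el)
    }
  }
  structure(list(tolerance_ppm = tolerance_ppm, sn_min = sn_min,
                 bounds = bounds, hc_range = hc_range, oc_max = oc_max,
                 dbe_max = dbe_max),
            class = "assignment_params")
}

#' Enumerate candidate formulas for a neutral mass
#'
#' Finds every CHNOS formula inside the element bounds whose monoisotopic
#' mass lies within `tolerance_ppm` of `neutral_mass` and that passes the
#' chemical-plausibility filters: H:C within `hc_range`, O:C at most
#' `oc_max`, and integer double-bond equivalents between 0 and `dbe_max`
#' (even-electron neutral molecule).
#'
#' The search loops over the heteroatom/carbon lattice and solves for the
#' unique hydrogen count closest to the residual mass, which is exhaustive
#' because the tolerance window (sub-mDa below 1000 Da) is far narrower than
#' one hydrogen mass.
#'
#' @param neutral_mass neutral monoisotopic mass (Da), `> 0`.
#' @param params an [assignment_params()] object.
#' @return a data frame with columns `c`, `h`, `n`, `o`, `s`, `formula`
#'   (Hill string) and `error_ppm`, sorted by |error_ppm| ascending (ties:
#'   fewer heteroatoms `n + s`, then lower `n`). Zero rows if no formula
#'   fits.
#' @export
enumerate_candidates <- function(neutral_mass, params = assignment_params()) {
  stopifnot(length(neutral_mass) == 1L, neutral_mass > 0)
  b <- params$bounds
  c_hi <- min(b$c[2L], floor(neutral_mass / .atomic_mass[["C"]]))
  if (c_hi < max(b$c[1L], 1L)) return(.empty_candidates())
  grid <- expand.grid(c = max(b$c[1L], 1L):c_hi,
                      n = b$n[1L]:b$n[2L],
                      o = b$o[1L]:b$o[2L],
                      s = b$s[1L]:b$s[2L],
                      KEEP.OUT.ATTRS = FALSE)
  resid <- neutral_mass -
    grid$c * .atomic_mass[["C"]] - grid$n * .atomic_mass[["N"]] -
    grid$o * .atomic_mass[["O"]] - grid$s * .atomic_mass[["S"]]
  h <- as.integer(round(resid / .atomic_mass[["H"]]))
  ok <- h >= max(b$h[1L], 1L) & h <= b$h[2L]
  grid <- grid[ok, , drop = FALSE]
  h <- h[ok]
  if (nrow(grid) == 0L) return(.empty_candidates())
  grid$h <- h
  mass <- grid$c * .atomic_mass[["C"]] + grid$h * .atomic_mass[["H"]] +
    grid$n * .atomic_mass[["N"]] + grid$o * .atomic_mass[["O"]] +
    grid$s * .atomic_mass[["S"]]
  err_ppm <- (mass - neutral_mass) / neutral_mass * 1e6
  hc <- grid$h / grid$c
  oc <- grid$o / grid$c
  d <- 1 + grid$c - grid$h / 2 + grid$n / 2
  keep <- abs(err_ppm) <= params$tolerance_ppm &
    hc >= params$hc_range[1L] & hc <= params$hc_range[2L] &
    oc <= params$oc_max &
    d >= 0 & d <= params$dbe_max & abs(d - round(d)) < 1e-9
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L) return(.empty_candidates())
  err_ppm <- err_ppm[keep]
  ord <- order(abs(err_ppm), grid$n + grid$s, grid$n)
  grid <- grid[ord, c("c", "h", "n", "o", "s"), drop = FALSE]
  rownames(grid) <- NULL
  grid$formula <- format_formula(grid)
  grid$error_ppm <- err_ppm[ord]
  grid
}

.empty_candidates <- function() {
  data.frame(c = integer(), h = integer(), n = integer(), o = integer(),
             s = integer(), formula = character(), error_ppm = numeric())
}

#' Assign molecular formulas to a peak list
#'
#' Applies the signal-to-noise gate, converts each surviving m/z to a neutral
#' mass assuming singly charged `[M-H]-` ions, enumerates candidate formulas
#' with [enumerate_candidates()] and records the outcome per peak:
#'
#' * `"filtered"` — signal-to-noise below `sn_min`;
#' * `"unassigned"` — no candidate within tolerance;
#' * `"assigned"` — exactly one candidate;
#' * `"ambiguous_resolved"` — several candidates; the one with minimal
#'   |mass error| is chosen (ties broken by fewer heteroatoms `n + s`, then
#'   lower `n` — deterministic).
#'
#' @param peaks a data frame with columns `mz`, `intensity`, `sn` (a peak
#'   list for one sample).
#' @param params an [assignment_params()] object.
#' @param sample_id identifier copied into the result.
#' @return a data frame with one row per input peak: `sample_id`, `mz`,
#'   `intensity`, `sn`, `status`, `formula`, `c`, `h`, `n`, `o`, `s`,
#'   `error_ppm`, `n_candidates`. Formula columns are `NA` for peaks without
#'   a chosen formula.
#' @export
assign_peaklist <- function(peaks, params = assignment_params(),
                            sample_id = "sample") {
  stopifnot(is.data.frame(peaks),
            all(c("mz", "intensity", "sn") %in% names(peaks)))
  n <- nrow(peaks)
  out <- data.frame(
    sample_id = rep(sample_id, n), mz = peaks$mz,
    intensity = peaks$intensity, sn = peaks$sn,
    status = rep("unassigned", n), formula = rep(NA_character_, n),
    c = rep(NA_integer_, n), h = rep(NA_integer_, n), n = rep(NA_integer_, n),
    o = rep(NA_integer_, n), s = rep(NA_integer_, n),
    error_ppm = rep(NA_real_, n), n_candidates = rep(0L, n)
  )
  if (n == 0L) return(out)
  if (any(peaks$mz <= 0) || any(peaks$intensity <= 0)) {
    stop("peaks must have positive mz and intensity")
  }
  low_sn <- peaks$sn < params$sn_min
  out$status[low_sn] <- "filtered"
  for (i in which(!low_sn)) {
    cand <- enumerate_candidates(mz_to_neutral_mass(peaks$mz[[i]]), params)
    out$n_candidates[[i]] <- nrow(cand)
    if (nrow(cand) == 0L) next
    out$status[[i]] <- if (nrow(cand) == 1L) "assigned" else "ambiguous_resolved"
    out$formula[[i]] <- cand$formula[[1L]]
    out$c[[i]] <- cand$c[[1L]]; out$h[[i]] <- cand$h[[1L]]
    out$n[[i]] <- cand$n[[1L]]; out$o[[i]] <- cand$o[[1L]]
    out$s[[i]] <- cand$s[[1L]]
    out$error_ppm[[i]] <- cand$error_ppm[[1L]]
  }
  out
}

#' Read / write peak-list CSV files
#'
#' Peak lists are plain CSV with columns `mz`, `intensity`, `sn`, sorted by
#' ascending m/z.
#'
#' @param path file path.
#' @return `read_peaklist()` returns the peak data frame.
#' @export
read_peaklist <- function(path) {
  pk <- utils::read.csv(path)
  stopifnot(all(c("mz", "intensity", "sn") %in% names(pk)))
  pk[order(pk$mz), , drop = FALSE]
}

#' @rdname read_peaklist
#' @param peaks peak data frame.
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.csv(peaks[order(peaks$mz), c("mz", "intensity", "sn")],
                   path, row.names = FALSE)
  invisible(path)
}
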