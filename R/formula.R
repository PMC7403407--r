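# Monoisotopic atomic masses (Da), IUPAC values; single source of truth for
# all mass arithmetic in the package.
.atomic_mass <- c(
  C = 12.000000,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207117
)

# Proton mass (Da); charge/electron bookkeeping for singly charged
# deprotonated ions is folded into this constant.
.proton_mass <- 1.00727646

#' Construct a table of CHNOS molecular formulas
#'
#' A molecular formula is represented as one row of a data frame with integer
#' columns `c`, `h`, `n`, `o`, `s` (atom counts). All formula-level functions
#' in the package (`formula_mass()`, `nosc()`, `classify_formula()`, ...) are
#' vectorized over the rows of such a table.
#'
#' Valid formulas describe even-electron neutral molecules: `c >= 1`,
#' `h >= 1`, heteroatom counts non-negative, and the double-bond equivalents
#' `1 + c - h/2 + n/2` a non-negative integer (which forces `h` and `n` to
#' have equal parity).
#'
#' @param c,h,n,o,s integer atom counts (recycled to a common length).
#' @param validate if `TRUE` (default), stop on invalid formulas.
#' @return a data frame with columns `c`, `h`, `n`, `o`, `s`.
#' @examples
#' molecular_formula(c = 6, h = 12, o = 6)  # glucose
#' @export
molecular_formula <- function(c, h, n = 0L, o = 0L, s = 0L, validate = TRUE) {
  f <- data.frame(c = as.integer(c), h = as.integer(h), n = as.integer(n),
                  o = as.integer(o), s = as.integer(s))
  if (validate) validate_formula(f)
  f
}

#' Validate a formula table
#'
#' Checks the even-electron neutral-molecule invariants: `c >= 1`, `h >= 1`,
#' `n`, `o`, `s >= 0` and integer non-negative double-bond equivalents.
#'
#' @param f formula table (see [molecular_formula()]).
#' @return `f`, invisibly; stops with a message on the first violation.
#' @export
validate_formula <- function(f) {
  f <- as_formula_table(f)
  if (any(f$c < 1L)) stop("molecular formula must contain at least one carbon")
  if (any(f$h < 1L)) stop("molecular formula must contain at least one hydrogen")
  if (any(f$n < 0L | f$o < 0L | f$s < 0L)) {
    stop("heteroatom counts must be non-negative")
  }
  d <- dbe(f)
  if (any(d < 0 | abs(d - round(d)) > 1e-9)) {
    stop("DBE = 1 + c - h/2 + n/2 must be a non-negative integer ",
         "(even-electron neutral molecule)")
  }
  invisible(f)
}

# Coerce x to a formula table; accepts a data.frame with c/h/n/o/s columns
# or a character vector of Hill-notation strings.
as_formula_table <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  if (!is.data.frame(x) || !all(c("c", "h", "n", "o", "s") %in% names(x))) {
    stop("expected a formula table with columns c, h, n, o, s")
  }
  x
}

#' Parse Hill-notation formula strings
#'
#' Accepts strings like `"C6H12O6"` or `"CH2O2"` (an omitted count means 1;
#' zero-count elements are omitted). Only the elements C, H, N, O, S are
#' supported.
#'
#' @param x character vector of formula strings.
#' @return a formula table (data frame with columns `c`, `h`, `n`, `o`, `s`).
#' @export
parse_formula <- function(x) {
  out <- matrix(0L, nrow = length(x), ncol = 5L,
                dimnames = list(NULL, c("C", "H", "N", "O", "S")))
  for (i in seq_along(x)) {
    s <- gsub("\\s", "", x[[i]])
    m <- gregexpr("[CHNOS][0-9]*", s)
    if (m[[1L]][1L] == -1L ||
        sum(attr(m[[1L]], "match.length")) != nchar(s)) {
      stop("cannot parse formula string: ", x[[i]])
    }
    parts <- regmatches(s, m)[[1L]]
    for (p in parts) {
      el <- substr(p, 1L, 1L)
      cnt <- substr(p, 2L, nchar(p))
      out[i, el] <- out[i, el] + if (nzchar(cnt)) as.integer(cnt) else 1L
    }
  }
  data.frame(c = out[, "C"], h = out[, "H"], n = out[, "N"],
             o = out[, "O"], s = out[, "S"])
}

#' Format formulas as Hill-notation strings
#'
#' Carbon first, hydrogen second, remaining elements alphabetical; zero-count
#' elements omitted, unit counts written without the digit (`"CH2O2"`).
#'
#' @param f formula table.
#' @return character vector, one string per row.
#' @export
format_formula <- function(f) {
  f <- as_formula_table(f)
  piece <- function(sym, cnt) {
    ifelse(cnt == 0L, "", paste0(sym, ifelse(cnt == 1L, "", cnt)))
  }
  paste0(piece("C", f$c), piece("H", f$h), piece("N", f$n),
         piece("O", f$o), piece("S", f$s))
}

#' Monoisotopic neutral mass of a formula
#'
#' Sum of atom counts times monoisotopic atomic masses (C 12 exactly,
#' H 1.00782503, N 14.00307401, O 15.99491462, S 31.97207117 Da).
#'
#' @param f formula table or character vector of formula strings.
#' @return numeric vector of masses in Da.
#' @examples
#' formula_mass(molecular_formula(6, 12, o = 6))  # 180.06339
#' @export
formula_mass <- function(f) {
  f <- as_formula_table(f)
  f$c * .atomic_mass[["C"]] + f$h * .atomic_mass[["H"]] +
    f$n * .atomic_mass[["N"]] + f$o * .atomic_mass[["O"]] +
    f$s * .atomic_mass[["S"]]
}

#' Convert measured m/z to neutral mass
#'
#' Assumes singly charged deprotonated ions `[M-H]-` (direct-infusion
#' negative electrospray): neutral mass = m/z + proton mass (1.00727646 Da).
#'
#' @param mz mass-to-charge values (Da), `> 0`.
#' @param mode ionization mode; only `"negative"` is supported.
#' @return neutral masses (Da).
#' @seealso [neutral_to_mz()] for the inverse.
#' @export
mz_to_neutral_mass <- function(mz, mode = "negative") {
  if (!identical(mode, "negative")) {
    stop("unsupported ionization mode: ", mode,
         " (only negative-mode [M-H]- ions are supported)")
  }
  if (any(mz <= 0)) stop("m/z must be positive")
  mz + .proton_mass
}

#' @rdname mz_to_neutral_mass
#' @param mass neutral masses (Da).
#' @export
neutral_to_mz <- function(mass, mode = "negative") {
  if (!identical(mode, "negative")) {
    stop("unsupported ionization mode: ", mode)
  }
  mass - .proton_mass
}
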