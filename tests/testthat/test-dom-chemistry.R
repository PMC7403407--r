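test_that("NOSC closed forms match hand evaluation of the stoichiometry", {
  # carbohydrate: 4 - (24 + 12 - 12)/6 = 0
  expect_equal(nosc("C6H12O6"), 0, tolerance = 1e-9)
  # formic acid: 4 - (4 + 2 - 4)/1 = +2
  expect_equal(nosc("CH2O2"), 2, tolerance = 1e-9)
  # cysteine: 4 - (12 + 7 - 3 - 4 - 2)/3 = 2/3
  expect_equal(nosc("C3H7NO2S"), 2 / 3, tolerance = 1e-9)
  expect_error(nosc(data.frame(c = 0, h = 2, n = 0, o = 0, s = 0)),
               "carbon")
})

test_that("NOSC orders reduced below oxidized compounds", {
  # methane-like (fully reduced) vs CO2-like stoichiometries
  expect_lt(nosc("CH4"), nosc("C6H12O6"))
  expect_lt(nosc("C6H12O6"), nosc("CH2O2"))
})

test_that("element ratios are exact count ratios, invariant to scaling", {
  expect_equal(element_ratios("C6H12O6"), data.frame(hc = 2, oc = 1))
  expect_equal(element_ratios("C16H32O2"), data.frame(hc = 2, oc = 0.125))
  expect_equal(element_ratios("C2H4"), element_ratios("C4H8"))
})

test_that("DBE counts rings plus pi bonds", {
  expect_equal(dbe("C6H12O6"), 1)
  expect_equal(dbe("C6H6"), 4)   # benzene
  expect_equal(dbe("CH4"), 0)
})

test_that("AImod floors at zero and flags condensed aromatics", {
  expect_equal(aimod("C6H12O6"), 0)  # negative numerator floored
  expect_equal(aimod("C14H6O2"), 11 / 13, tolerance = 1e-9)
  # adding hydrogens lowers AImod, all else fixed
  expect_lt(aimod("C14H8O2"), aimod("C14H6O2"))
})

test_that("compound classification follows the priority rules", {
  expect_equal(classify_formula("C6H12O6"), "aminosugar-carbohydrate")
  expect_equal(classify_formula("C16H32O2"), "lipid")
  # condensed-aromatic outranks every later rule
  f <- "C14H6O2"
  expect_gte(aimod(f), 0.67)
  expect_equal(classify_formula(f), "condensed-aromatic")
  # protein-like needs nitrogen
  expect_equal(classify_formula("C10H17NO3"), "protein")
  # classification is total
  lat <- formula_lattice(c(150, 400))
  expect_true(all(nchar(classify_formula(lat[1:500, ])) > 0))
})

test_that("per-sample mean NOSC averages detected formulas, unweighted", {
  mat <- rbind(s1 = c(1, 5), s2 = c(2, 0))
  colnames(mat) <- c("C6H12O6", "CH2O2")
  expect_equal(unname(sample_mean_nosc(mat)), c(1, 0))
  # single-formula sample returns that formula's NOSC
  expect_equal(unname(sample_mean_nosc(mat)["s2"]), nosc("C6H12O6"))
  # intensity permutations leave the presence-based mean unchanged
  mat2 <- mat
  mat2["s1", ] <- rev(mat["s1", ])
  expect_equal(sample_mean_nosc(mat)["s1"], sample_mean_nosc(mat2)["s1"])
  # brute-force oracle on a random matrix
  set.seed(7)
  lat <- formula_lattice(c(150, 800))
  f <- lat$formula[sample(nrow(lat), 40)]
  m <- matrix(rbinom(5 * 40, 1, 0.6) * rexp(5 * 40), 5, 40,
              dimnames = list(paste0("x", 1:5), f))
  m[1, ] <- pmax(m[1, ], 0.1)  # guarantee detections
  vals <- nosc(f)
  for (i in 1:5) {
    det <- m[i, ] > 0
    if (!any(det)) next
    expect_equal(unname(sample_mean_nosc(m)[i]), mean(vals[det]))
  }
})

test_that("intensity-weighted mean NOSC responds to intensities", {
  mat <- rbind(s1 = c(3, 1))
  colnames(mat) <- c("C6H12O6", "CH2O2")
  expect_equal(unname(sample_mean_nosc(mat, weighted = TRUE)), 0.5)
})

test_that("chemodiversity partition matches set algebra on a hand case", {
  # class sets A = {f1, f2, f3}, B = {f2, f3}, C = {f3}
  mat <- rbind(
    a1 = c(1, 1, 1), b1 = c(0, 1, 1), c1 = c(0, 0, 1))
  colnames(mat) <- c("C6H12O6", "CH2O2", "C16H32O2")
  p <- chemodiversity_partition(mat, c("A", "B", "C"))
  expect_equal(unname(p$unique), c(1, 0, 0))
  expect_equal(p$shared_all, 1)
  expect_equal(unname(p$shared[["A&B"]]), 1)
  expect_equal(p$total, 3)
  # cells sum to the total
  expect_equal(sum(p$unique) + sum(p$shared), p$total)
})

test_that("partition cells always sum to the distinct-formula total", {
  set.seed(11)
  lat <- formula_lattice(c(150, 800))
  for (rep in 1:20) {
    nf <- sample(10:40, 1)
    f <- lat$formula[sample(nrow(lat), nf)]
    m <- matrix(rbinom(9 * nf, 1, 0.5), 9, nf,
                dimnames = list(paste0("s", 1:9), f))
    cls <- rep(c("A", "B", "C"), each = 3)
    keep <- colSums(m) > 0
    if (sum(keep) < 2) next
    m <- m[, keep, drop = FALSE]
    p <- chemodiversity_partition(m, cls)
    o <- oracle_partition(m, cls)
    expect_equal(sum(p$unique) + sum(p$shared), p$total)
    expect_equal(unname(p$unique[c("A", "B", "C")]),
                 unname(o$unique[c("A", "B", "C")]))
    expect_equal(p$shared_all, o$shared_all)
    expect_equal(p$total, o$total)
  }
})

test_that("class relative abundances are proportions summing to one", {
  mat <- rbind(s1 = c(1, 1, 1, 1))
  colnames(mat) <- c("C16H32O2", "C18H34O2", "C10H17NO3", "C12H21NO4")
  pr <- class_relative_abundance(mat)
  expect_equal(unname(pr[1, "lipid"]), 0.5)
  expect_equal(unname(pr[1, "protein"]), 0.5)
  expect_equal(sum(pr[1, ]), 1)
  # one-class sample
  mat2 <- rbind(s1 = c(1, 1))
  colnames(mat2) <- c("C16H32O2", "C18H34O2")
  expect_equal(unname(class_relative_abundance(mat2)[1, "lipid"]), 1)
})

test_that("SCFA carbon fraction follows the molar-carbon definition", {
  chem <- data.frame(sample_id = "s1", analyte = c("acetate", "DOC"),
                     value = c(5, 100), unit = c("mmol/L", "mmol C/L"))
  expect_equal(unname(scfa_carbon_fraction(chem)), 10)
  # two SCFAs: (2 + 4) / 12 = 50%
  chem2 <- data.frame(sample_id = "s1",
                      analyte = c("acetate", "butyrate", "DOC"),
                      value = c(1, 1, 12),
                      unit = c("mmol/L", "mmol/L", "mmol C/L"))
  expect_equal(unname(scfa_carbon_fraction(chem2)), 50)
  # no SCFAs measured -> 0%
  chem3 <- data.frame(sample_id = "s1", analyte = "DOC", value = 10,
                      unit = "mmol C/L")
  expect_equal(unname(scfa_carbon_fraction(chem3)), 0)
  # mg/L converts through the molar mass (acetate 60.052 g/mol, 2 C)
  chem4 <- data.frame(sample_id = "s1", analyte = c("acetate", "DOC"),
                      value = c(60.052, 24.022),
                      unit = c("mg/L", "mg C/L"))
  expect_equal(unname(scfa_carbon_fraction(chem4)), 100, tolerance = 1e-3)
})

test_that("SCFA carbon fraction refuses to guess units", {
  chem <- data.frame(sample_id = "s1", analyte = c("acetate", "DOC"),
                     value = c(5, 100), unit = c("ppm", "mmol C/L"))
  expect_error(scfa_carbon_fraction(chem), "unit")
  chem2 <- data.frame(sample_id = "s1", analyte = c("acetate", "DOC"),
                      value = c(5, 100), unit = c("mmol/L", "mg/L"))
  expect_error(scfa_carbon_fraction(chem2), "carbon-molar")
  chem3 <- data.frame(sample_id = "s1", analyte = c("acetate", "DOC"),
                      value = c(5, 100), unit = c("", "mmol C/L"))
  expect_error(scfa_carbon_fraction(chem3), "unit")
})
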