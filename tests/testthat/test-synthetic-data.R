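test_that("simulation designs validate their invariants", {
  expect_s3_class(simulation_design(), "simulation_design")
  expect_error(simulation_design(shared_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_design(mass_range = c(800, 150)), "increasing")
  expect_error(simulation_design(richness_by_class = c(100, 100)),
               "one positive count per class")
  expect_error(simulation_design(pool_size = 10), "largest class richness")
  expect_error(simulation_design(class_mixture = c(lignin = 0.5)), "sum to 1")
  ch <- simulation_design()$chemistry
  ch$sds[1, 1] <- -1
  expect_error(simulation_design(chemistry = ch), "sds")
})

test_that("generators are pure functions of design and seed", {
  des <- small_design(seed = 81)
  expect_identical(simulate_formula_pool(des), simulate_formula_pool(des))
  pool <- simulate_formula_pool(des)
  d1 <- simulate_dom_matrix(pool, des)
  d2 <- simulate_dom_matrix(pool, des)
  expect_identical(d1, d2)
  expect_identical(simulate_peaklists(d1, des), simulate_peaklists(d1, des))
  expect_identical(simulate_count_tables(des, d1),
                   simulate_count_tables(des, d1))
  expect_identical(simulate_chemistry_table(des),
                   simulate_chemistry_table(des))
  # a different seed changes the draw
  expect_false(identical(simulate_formula_pool(des, seed = 99), pool))
})

test_that("pool honors the planted class mixture", {
  des <- small_design(class_mixture = c(lipid = 1))
  pool <- simulate_formula_pool(des)
  expect_true(all(classify_formula(pool) == "lipid"))
  expect_true(all(pool$class == "lipid"))
  # unsatisfiable class in a narrow window fails, naming the class
  # (no tannin-like formula exists between 150 and 152 Da)
  des2 <- simulation_design(mass_range = c(150, 152),
                            class_mixture = c(tannin = 1),
                            richness_by_class = c(5, 5, 5), pool_size = 10)
  expect_error(simulate_formula_pool(des2), "tannin")
})

test_that("pool formulas pass the assignment plausibility filters", {
  pool <- simulate_formula_pool(small_design(seed = 82))
  expect_silent(validate_formula(pool))
  r <- element_ratios(pool)
  expect_true(all(r$hc >= 0.3 & r$hc <= 2.25))
  expect_true(all(r$oc <= 1.2))
  expect_true(all(pool$mass >= 150 & pool$mass <= 800))
  expect_gte(nrow(pool), max(small_design()$richness_by_class))
})

test_that("pool mean NOSC tracks the mixture-weighted lattice target", {
  des <- simulation_design()
  pool <- simulate_formula_pool(des)
  lat <- formula_lattice(des$mass_range)
  class_means <- tapply(lat$nosc, lat$class, mean)
  target <- sum(des$class_mixture *
                  class_means[names(des$class_mixture)])
  expect_lt(abs(mean(pool$nosc) - target), 0.2)
})

test_that("DOM matrix respects planted richness and membership", {
  des <- small_design(seed = 83)
  pool <- simulate_formula_pool(des)
  dom <- simulate_dom_matrix(pool, des)
  for (i in seq_along(des$class_labels)) {
    cl <- des$class_labels[i]
    sub <- dom$matrix[dom$metadata$age_class == cl, , drop = FALSE]
    union_size <- sum(colSums(sub > 0) > 0)
    expect_lte(union_size, des$richness_by_class[i])
    expect_gt(union_size, 0.9 * des$richness_by_class[i])
    # detections only within the true class membership
    detected <- colnames(sub)[colSums(sub > 0) > 0]
    expect_true(all(detected %in% dom$class_sets[[cl]]))
  }
  expect_true(all(dom$matrix >= 0))
  # richness larger than the pool fails
  des_bad <- small_design()
  des_bad$richness_by_class <- c(10000L, 120L, 90L)
  des_bad$pool_size <- 20000L  # design itself stays valid
  expect_error(simulate_dom_matrix(pool, des_bad), "exceeds pool size")
})

test_that("full sharing leaves no unique formulas", {
  des <- small_design(richness_by_class = c(120, 120, 120),
                      shared_fraction = 1, seed = 84)
  pool <- simulate_formula_pool(des)
  dom <- simulate_dom_matrix(pool, des)
  p <- chemodiversity_partition(dom$matrix, dom$metadata$age_class)
  expect_true(all(p$unique == 0))
  expect_equal(p$shared_all, p$total)
})

test_that("planted NOSC shifts order the class means", {
  des <- simulation_design(seed = 85)
  pool <- simulate_formula_pool(des)
  dom <- simulate_dom_matrix(pool, des)
  m <- tapply(sample_mean_nosc(dom$matrix), dom$metadata$age_class, mean)
  m <- m[des$class_labels]
  expect_true(all(diff(m) < 0))  # declining with age, as planted
})

test_that("noiseless peak lists round-trip through assignment", {
  des <- small_design(mass_error_sd_ppm = 0, noise_peak_rate = 0, seed = 86)
  pool <- simulate_formula_pool(des)
  dom <- simulate_dom_matrix(pool, des)
  pks <- simulate_peaklists(dom, des)
  sid <- names(pks)[1]
  rec <- assign_peaklist(pks[[sid]]$peaks, assignment_params(),
                         sample_id = sid)
  expect_equal(rec$formula, pks[[sid]]$truth$formula)
})

test_that("peak truth records flag noise and preserve intensities", {
  des <- small_design(seed = 87)
  pool <- simulate_formula_pool(des)
  dom <- simulate_dom_matrix(pool, des)
  pks <- simulate_peaklists(dom, des)
  one <- pks[[3]]
  expect_equal(nrow(one$peaks), nrow(one$truth))
  expect_true(any(one$truth$is_noise))
  expect_true(all(is.na(one$truth$formula[one$truth$is_noise])))
  # true-peak intensities come from the matrix
  t_rows <- !one$truth$is_noise
  sid <- names(pks)[3]
  expect_equal(sort(one$peaks$intensity[t_rows]),
               sort(unname(dom$matrix[sid, dom$matrix[sid, ] > 0])))
})

test_that("count tables satisfy the multinomial column-sum constraint", {
  des <- small_design(seed = 88)
  ct <- simulate_count_tables(des)
  expect_true(all(colSums(ct$ko) == des$library_size))
  caz_lib <- round(des$library_size *
                     des$cazyme_trend_by_class[
                       match(ct$metadata$age_class, des$class_labels)])
  expect_equal(unname(colSums(ct$cazyme)), caz_lib)
  expect_true(all(ct$truth$markers %in% rownames(ct$ko)))
  # markers near-constant in relative abundance
  rel <- relative_abundance(ct$ko)["K02874", ]
  expect_lt(stats::sd(rel) / mean(rel), 0.2)
})

test_that("planted effect families dominate the screen flags", {
  des <- simulation_design(n_families = 100, effect_families_fraction = 0.1,
                           effect_size = 10)
  ct <- simulate_count_tables(des, seed = 89)
  res <- per_family_screen(ct$cazyme, ct$metadata$age_class, alpha = 0.01)
  flagged <- res$feature[res$affected]
  expect_gte(sum(ct$truth$effect_families %in% flagged), 9)  # >= 90% power
})

test_that("DOM coupling makes count tables Mantel-positive with DOM", {
  des <- small_design(seed = 90)
  pool <- simulate_formula_pool(des)
  dom <- simulate_dom_matrix(pool, des)
  ct <- simulate_count_tables(des, dom)
  d_dom <- bray_curtis(dom$matrix / rowSums(dom$matrix))
  d_ko <- bray_curtis(t(relative_abundance(ct$ko)))
  res <- mantel_test(d_dom, d_ko, n_perm = 499, seed = 91)
  expect_gt(res$statistic, 0)
  expect_lt(res$p, 0.05)
})

test_that("chemistry table reproduces degenerate and planted patterns", {
  des <- small_design(seed = 92)
  chem <- simulate_chemistry_table(des)
  expect_true(all(c("sample_id", "age_class", "analyte", "value", "unit")
                  %in% names(chem)))
  conc <- chem$analyte != "d13C_DOC"
  expect_true(all(chem$value[conc] >= 0))
  # sd = 0 everywhere: distinct class means earn distinct letters
  ch0 <- des$chemistry
  ch0$sds[] <- 0
  des0 <- small_design(chemistry = ch0)
  chem0 <- simulate_chemistry_table(des0, seed = 93)
  acet <- chem0[chem0$analyte == "acetate", ]
  expect_equal(as.numeric(tapply(acet$value, acet$age_class, stats::sd)),
               rep(0, 3))
  cmp <- group_compare(acet$value, acet$age_class)
  expect_equal(length(unique(cmp$letters)), 3)
})

test_that("acetate letters recover across repeated seeds", {
  # means 1/8/40-ish with sd ~10% of mean: expect a/b/c nearly always
  des <- small_design()
  ok <- 0
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    chem <- simulate_chemistry_table(des, seed = 1000 + s)
    acet <- chem[chem$analyte == "acetate", ]
    cmp <- group_compare(acet$value, acet$age_class)
    l <- cmp$letters[des$class_labels]
    if (length(unique(l)) == 3) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.95)
})
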