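# End-to-end chronosequence analysis: simulate (or accept) inputs, assign
# formulas, compute DOM chemistry and chemodiversity, normalize functional
# profiles, run the univariate chemistry comparisons and the permutation
# multivariate statistics, and write figure/table-analog outputs plus a run
# manifest. All stages are deterministic given the config seed.

#' Build and validate a pipeline configuration
#'
#' @param design a [simulation_design()] describing the synthetic inputs.
#' @param assignment an [assignment_params()] object.
#' @param class_table van Krevelen boundary table
#'   (default [default_class_boundaries()]).
#' @param alpha significance level for group comparisons and letters
#'   (default 0.05).
#' @param screen_alpha per-family screen threshold (default 0.01).
#' @param n_perm permutations for all permutation tests (default 999).
#' @param seed master seed; every stochastic stage derives its stream from
#'   it (mandatory).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = simulation_design(),
                            assignment = assignment_params(),
                            class_table = default_class_boundaries(),
                            alpha = 0.05, screen_alpha = 0.01,
                            n_perm = 999, seed = design$seed) {
  cfg <- list(design = design, assignment = assignment,
              class_table = class_table, alpha = alpha,
              screen_alpha = screen_alpha, n_perm = n_perm,
              seed = as.integer(seed))
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a config list to validate.
#' @export
validate_config <- function(cfg) {
  errors <- character(0)
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    errors <- c(errors, "seed: mandatory for stochastic stages")
  }
  if (is.null(cfg$design)) {
    errors <- c(errors, "design: missing")
  } else {
    ok <- tryCatch({ validate_design(cfg$design); TRUE },
                   error = function(e) { errors <<- c(errors,
                     paste0("design: ", conditionMessage(e))); FALSE })
  }
  if (!inherits(cfg$assignment, "assignment_params")) {
    errors <- c(errors, "assignment: not an assignment_params object")
  }
  for (p in c("alpha", "screen_alpha")) {
    if (is.null(cfg[[p]]) || cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      errors <- c(errors, paste0(p, ": must lie in (0, 1)"))
    }
  }
  if (is.null(cfg$n_perm) || cfg$n_perm < 1) {
    errors <- c(errors, "n_perm: must be a positive count")
  }
  if (length(errors) > 0L) {
    stop("invalid pipeline config:\n  ", paste(errors, collapse = "\n  "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full chronosequence pipeline
#'
#' Executes the stage order simulate -> assign -> DOM metrics/classes ->
#' chemodiversity -> functional profiles -> univariate chemistry ->
#' multivariate statistics, mirroring the analysis workflow of a paired
#' FT-ICR MS / metagenome chronosequence study. If `outdir` is given, the
#' table/figure-analog outputs are written there (CSV/JSON/Newick) and a
#' manifest with content hashes is saved.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir optional output directory (created if needed).
#' @return list of class `pipeline_result` with elements `truth` (simulated
#'   inputs and truth records), `assigned` (assignment records and the
#'   observed formula matrix), `dom` (per-sample NOSC summary with letters,
#'   chemodiversity partition, class proportions), `functional` (normalized
#'   abundances, Shannon H, per-family screen), `chemistry` (per-analyte
#'   comparison table), `multivariate` (MRPP/PERMANOVA/Mantel results, NMDS
#'   ordination, fitted vectors, UPGMA tree), `trends` (per-class summary of
#'   the planted directional trends) and `manifest`.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  cfg <- validate_config(cfg)
  design <- cfg$design
  manifest <- list(stages = list(), seed = cfg$seed)
  t_stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    value <- code
    manifest$stages[[name]] <<- list(
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    value
  }

  # -- stage 1: synthetic inputs -------------------------------------------
  sim <- t_stage("simulate", {
    pool <- simulate_formula_pool(design, seed = cfg$seed)
    dom <- simulate_dom_matrix(pool, design, seed = cfg$seed + 1L)
    peaklists <- simulate_peaklists(dom, design, seed = cfg$seed + 2L)
    counts <- simulate_count_tables(design, dom, seed = cfg$seed + 3L)
    chem <- simulate_chemistry_table(design, seed = cfg$seed + 4L)
    list(pool = pool, dom = dom, peaklists = peaklists, counts = counts,
         chem = chem)
  })
  meta <- sim$dom$metadata

  # -- stage 2: formula assignment -----------------------------------------
  assigned <- t_stage("assign", {
    recs <- lapply(names(sim$peaklists), function(sid) {
      assign_peaklist(sim$peaklists[[sid]]$peaks, cfg$assignment,
                      sample_id = sid)
    })
    names(recs) <- names(sim$peaklists)
    # observed formula matrix: chosen formulas, deduplicated per sample
    # (max intensity wins)
    all_formulas <- sort(unique(unlist(lapply(recs, function(r) {
      r$formula[!is.na(r$formula)]
    }))))
    mat <- matrix(0, length(recs), length(all_formulas),
                  dimnames = list(names(recs), all_formulas))
    for (sid in names(recs)) {
      r <- recs[[sid]]
      r <- r[!is.na(r$formula), , drop = FALSE]
      if (nrow(r) == 0L) next
      agg <- tapply(r$intensity, r$formula, max)
      mat[sid, names(agg)] <- agg
    }
    list(records = recs, matrix = mat)
  })
  obs_mat <- assigned$matrix[meta$sample_id, , drop = FALSE]

  # -- stage 3: DOM chemistry ----------------------------------------------
  dom_res <- t_stage("dom_chemistry", {
    metrics <- formula_metrics(parse_formula(colnames(obs_mat)),
                               cfg$class_table)
    mean_nosc <- sample_mean_nosc(obs_mat)
    nosc_cmp <- group_compare(mean_nosc, meta$age_class, alpha = cfg$alpha)
    summary <- data.frame(sample_id = meta$sample_id,
                          age_class = meta$age_class,
                          n_formulas = rowSums(obs_mat > 0),
                          mean_nosc = mean_nosc[meta$sample_id],
                          row.names = NULL)
    partition <- chemodiversity_partition(obs_mat, meta$age_class)
    props <- class_relative_abundance(obs_mat, cfg$class_table)
    list(metrics = metrics, summary = summary, nosc_compare = nosc_cmp,
         partition = partition, class_proportions = props)
  })

  # -- stage 4: functional profiles ----------------------------------------
  func <- t_stage("functional", {
    ko <- sim$counts$ko[, meta$sample_id, drop = FALSE]
    caz <- sim$counts$cazyme[, meta$sample_id, drop = FALSE]
    caz_rel <- relative_abundance(caz)
    ko_rel <- relative_abundance(ko)
    marker <- ko["K02874", ]
    caz_marker_ratio <- colSums(caz) / marker
    shannon <- shannon_diversity(caz_rel)
    screen <- per_family_screen(caz, meta$age_class,
                                alpha = cfg$screen_alpha)
    summary <- data.frame(sample_id = meta$sample_id,
                          age_class = meta$age_class,
                          cazyme_marker_ratio =
                            caz_marker_ratio[meta$sample_id],
                          shannon_h = shannon[meta$sample_id],
                          row.names = NULL)
    list(ko_rel = ko_rel, caz_rel = caz_rel, summary = summary,
         screen = screen)
  })

  # -- stage 5: univariate chemistry ---------------------------------------
  chem_res <- t_stage("univariate", {
    compare_analytes(sim$chem, alpha = cfg$alpha)
  })

  # -- stage 6: multivariate -----------------------------------------------
  multi <- t_stage("multivariate", {
    dom_rel <- obs_mat / rowSums(obs_mat)
    d_dom <- bray_curtis(dom_rel)
    d_ko <- bray_curtis(t(func$ko_rel))
    d_caz <- bray_curtis(t(func$caz_rel))
    doc <- sim$chem[sim$chem$analyte == "DOC", ]
    covars <- data.frame(age_class = meta$age_class,
                         doc = doc$value[match(meta$sample_id,
                                               doc$sample_id)])
    res <- list(
      mrpp_dom = mrpp(d_dom, meta$age_class, cfg$n_perm,
                      seed = cfg$seed + 10L),
      mrpp_ko = mrpp(d_ko, meta$age_class, cfg$n_perm,
                     seed = cfg$seed + 11L),
      mrpp_cazyme = mrpp(d_caz, meta$age_class, cfg$n_perm,
                         seed = cfg$seed + 12L),
      permanova_ko = permanova(d_ko, ~ age_class + doc, covars,
                               cfg$n_perm, seed = cfg$seed + 13L),
      mantel_dom_ko = mantel_test(d_dom, d_ko, n_perm = cfg$n_perm,
                                  seed = cfg$seed + 14L),
      mantel_dom_cazyme = mantel_test(d_dom, d_caz, n_perm = cfg$n_perm,
                                      seed = cfg$seed + 15L))
    ord <- nmds(d_caz, k = 2, seed = cfg$seed + 16L)
    chem_wide <- stats::reshape(
      sim$chem[, c("sample_id", "analyte", "value")],
      idvar = "sample_id", timevar = "analyte", direction = "wide")
    names(chem_wide) <- sub("^value\\.", "", names(chem_wide))
    chem_wide <- chem_wide[match(meta$sample_id, chem_wide$sample_id), ]
    fits <- envfit_vectors(ord, chem_wide[, setdiff(names(chem_wide),
                                                    "sample_id")],
                           n_perm = cfg$n_perm, seed = cfg$seed + 17L)
    tree <- upgma(d_caz)
    c(res, list(nmds = ord, envfit = fits, upgma = tree,
                distances = list(dom = d_dom, ko = d_ko, cazyme = d_caz)))
  })

  # -- planted-trend summary ------------------------------------------------
  classes <- design$class_labels
  trends <- data.frame(
    age_class = classes,
    richness = vapply(classes, function(cl)
      mean(dom_res$summary$n_formulas[meta$age_class == cl]), numeric(1)),
    mean_nosc = vapply(classes, function(cl)
      mean(dom_res$summary$mean_nosc[meta$age_class == cl]), numeric(1)),
    cazyme_marker_ratio = vapply(classes, function(cl)
      mean(func$summary$cazyme_marker_ratio[meta$age_class == cl]),
      numeric(1)),
    acetate = vapply(classes, function(cl) {
      a <- sim$chem[sim$chem$analyte == "acetate" &
                      sim$chem$age_class == cl, "value"]
      mean(a) }, numeric(1)),
    row.names = NULL)
  acet <- chem_res[chem_res$analyte == "acetate", ]
  trends$acetate_letter <- acet$letter[match(classes, acet$age_class)]

  result <- structure(
    list(truth = sim, assigned = assigned, dom = dom_res,
         functional = func, chemistry = chem_res, multivariate = multi,
         trends = trends, manifest = manifest, config = cfg),
    class = "pipeline_result")
  if (!is.null(outdir)) {
    result$manifest <- write_pipeline_outputs(result, outdir)
  }
  result
}

#' Write pipeline outputs to a directory
#'
#' Emits the table/figure-analog artifacts (chemodiversity partition JSON,
#' per-sample NOSC CSV, class-proportion CSV, chemistry comparison CSV,
#' CAZyme abundance/diversity CSV, screen CSV, ordination and fitted-vector
#' CSVs, distance matrices, UPGMA Newick, multivariate test JSON) plus a
#' manifest with MD5 content hashes.
#'
#' @param result a `pipeline_result`.
#' @param outdir output directory.
#' @return the updated manifest (also written as `manifest.json`).
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    path
  }
  paths <- c(
    w("partition.json", function(p) {
      x <- result$dom$partition
      jsonlite::write_json(list(unique = as.list(x$unique),
                                shared = as.list(x$shared),
                                shared_all = x$shared_all, total = x$total),
                           p, auto_unbox = TRUE, pretty = TRUE)
    }),
    w("sample_nosc.csv", function(p)
      utils::write.csv(result$dom$summary, p, row.names = FALSE)),
    w("class_proportions.csv", function(p)
      utils::write.csv(data.frame(sample_id =
                                    rownames(result$dom$class_proportions),
                                  result$dom$class_proportions,
                                  check.names = FALSE), p,
                       row.names = FALSE)),
    w("formula_metrics.csv", function(p)
      utils::write.csv(result$dom$metrics, p, row.names = FALSE)),
    w("chemistry_comparison.csv", function(p)
      utils::write.csv(result$chemistry, p, row.names = FALSE)),
    w("cazyme_summary.csv", function(p)
      utils::write.csv(result$functional$summary, p, row.names = FALSE)),
    w("cazyme_screen.csv", function(p)
      utils::write.csv(result$functional$screen, p, row.names = FALSE)),
    w("ordination.csv", function(p)
      utils::write.csv(data.frame(sample_id =
                                    rownames(result$multivariate$nmds$points),
                                  result$multivariate$nmds$points,
                                  stress = result$multivariate$nmds$stress),
                       p, row.names = FALSE)),
    w("envfit.csv", function(p)
      utils::write.csv(result$multivariate$envfit, p, row.names = FALSE)),
    w("cazyme_upgma.nwk", function(p)
      writeLines(result$multivariate$upgma$newick, p)),
    w("multivariate_tests.json", function(p) {
      fmt_test <- function(x) list(statistic = x$statistic, A = x$A,
                                   p = x$p, n_perm = x$n_perm)
      pa <- result$multivariate$permanova_ko
      jsonlite::write_json(list(
        mrpp = lapply(result$multivariate[c("mrpp_dom", "mrpp_ko",
                                            "mrpp_cazyme")], fmt_test),
        mantel = lapply(result$multivariate[c("mantel_dom_ko",
                                              "mantel_dom_cazyme")],
                        fmt_test),
        permanova_ko = list(terms = pa$terms, ss_total = pa$ss_total,
                            df_residual = pa$df_residual)),
        p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }),
    w("trends.csv", function(p)
      utils::write.csv(result$trends, p, row.names = FALSE))
  )
  manifest <- result$manifest
  manifest$outputs <- lapply(paths, function(p) {
    list(file = basename(p), md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Chronosequence pipeline result\n")
  cat("  samples:", nrow(x$truth$dom$metadata), " formulas detected:",
      ncol(x$assigned$matrix), "\n")
  cat("  planted-trend summary:\n")
  print(x$trends, digits = 4)
  invisible(x)
}
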