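Package: cryodomics
Title: Chronosequence Analysis of Permafrost Dissolved Organic Matter and
    Metagenome Functional Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrated analysis of permafrost (or other soil)
    chronosequences that pair ultrahigh-resolution mass spectrometry of
    dissolved organic matter with shotgun-metagenome functional profiles.
    Assigns CHNOS molecular formulas to negative-mode FT-ICR MS peak lists
    under mass-tolerance and chemical-plausibility rules; computes
    per-formula and per-sample chemistry metrics (nominal oxidation state
    of carbon, elemental ratios, aromaticity, van Krevelen compound
    classes) and the unique/shared chemodiversity partition across age
    classes; normalizes KEGG-ortholog and CAZyme count tables (relative
    abundance and single-copy marker-gene normalization), computes Shannon
    diversity, and screens per-family age effects; routes per-analyte
    group comparisons through a Shapiro-Wilk normality gate to ANOVA/Tukey
    or Kruskal-Wallis/Welch paths with compact letter displays; and links
    the data layers with permutation multivariate statistics implemented
    from first principles (Bray-Curtis dissimilarity, MRPP, PERMANOVA,
    Mantel tests, non-metric multidimensional scaling with vector fitting,
    and UPGMA clustering). A seeded synthetic-data generator reproduces
    the statistical structure the analysis assumes (declining formula
    richness and carbon oxidation state with age, rising short-chain fatty
    acids, planted functional-gene effects), so that every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
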