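#' Run the full cold-tolerance screening pipeline
#'
#' Orchestrates every stage of the screen on one panel: validation,
#' per-trait variance components under both treatments, assembly of the
#' phenotypic/genotypic covariance matrices, Smith-Hazel index
#' coefficients, CTI scoring with ranking and tolerance categories, stress
#' ratios, the significance-annotated correlation matrix and PCA of trait
#' variation.
#'
#' @param panel A `trait_panel` (e.g. from [simulate_panel()] or
#'   [read_panel()]). If `NULL`, a panel is simulated from `config`.
#' @param config A [panel_config()]; required when `panel` is `NULL`, and
#'   recorded in the report metadata either way when supplied.
#' @param index_traits Traits entering the selection index, in order
#'   (default `c("LI", "qL", "FvFm")`).
#' @param a Economic weights for the index (default all ones).
#' @param coeffs Optional `index_coefficients` to use directly (e.g.
#'   published weights), bypassing estimation of P and G.
#' @param scheme,breaks Categorization scheme, see [rank_and_categorize()].
#' @param ratio_based If `TRUE` (default) correlations and PCA operate on
#'   cold/control stress ratios; if `FALSE`, on cold entry means.
#' @param k Selection intensity for genetic advance (default 2.06).
#' @inheritParams anova_one_way
#' @return An object of class `screening_report`: list with `meta`
#'   (seed, config hash, package version), `stats`, `matrices`, `coeffs`,
#'   `cti`, `ratios`, `correlation`, `pca` and `categories` (per-category
#'   genotype lists).
#' @export
#' @examples
#' report <- run_screening(config = panel_config(n_genotypes = 20, seed = 1))
#' report
run_screening <- function(panel = NULL, config = NULL,
                          index_traits = c("LI", "qL", "FvFm"),
                          a = NULL, coeffs = NULL,
                          scheme = c("equal_width", "quantile"),
                          breaks = NULL, ratio_based = TRUE, k = 2.06,
                          trials = c("average", "pool")) {
  scheme <- match.arg(scheme)
  trials <- match.arg(trials)
  if (is.null(panel)) {
    if (is.null(config)) {
      stop("supply either `panel` or `config`", call. = FALSE)
    }
    panel <- simulate_panel(config)
  } else {
    panel <- validate_panel(panel)
    if (is.null(config)) config <- attr(panel, "config", exact = TRUE)
  }

  stats_tbl <- dplyr::bind_rows(
    trait_stats(panel, "cold", k = k, trials = trials),
    trait_stats(panel, "control", k = k, trials = trials)
  )

  matrices <- build_index_matrices(panel, index_traits, "cold", trials)
  if (is.null(coeffs)) {
    coeffs <- smith_hazel_coefficients(matrices, a = a)
  } else if (!inherits(coeffs, "index_coefficients")) {
    coeffs <- index_coefficients(coeffs, traits = index_traits, a = a)
  }

  cti <- cti_table(panel, coeffs, "cold", trials, scheme = scheme,
                   breaks = breaks)
  ratios <- stress_ratios(panel, trials = trials)
  assoc_table <- if (ratio_based) ratios else entry_means(panel, "cold",
                                                          trials = trials)
  correlation <- correlation_with_stars(assoc_table)
  pca <- pca_traits(assoc_table)

  categories <- split(cti$genotype,
                      factor(cti$category, levels = CATEGORY_LEVELS))

  meta <- list(
    seed = if (!is.null(config)) config$seed else NA_integer_,
    config_hash = rlang::hash(list(
      config = config, index_traits = index_traits, a = a,
      coeffs = if (!is.null(coeffs)) coeffs$b, scheme = scheme,
      breaks = breaks, ratio_based = ratio_based, k = k, trials = trials
    )),
    n_genotypes = length(unique(panel$genotype)),
    package_version = as.character(utils::packageVersion("coldscreen"))
  )

  structure(
    list(meta = meta, panel = panel, stats = stats_tbl, matrices = matrices,
         coeffs = coeffs, cti = cti, ratios = ratios,
         correlation = correlation, pca = pca, categories = categories),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>", x$meta$n_genotypes, "genotypes",
      "(seed", x$meta$seed, ")\n\n")
  cat("Smith-Hazel coefficients over",
      paste(x$coeffs$traits, collapse = ", "), ":\n  ")
  cat(paste0("b", seq_along(x$coeffs$b), " = ",
             signif(x$coeffs$b, 4), collapse = ", "), "\n\n")
  counts <- category_counts(x$cti)
  cat("Tolerance categories:",
      paste(names(counts), counts, sep = " = ", collapse = ", "), "\n")
  top <- head(x$cti, 2)
  cat("Most tolerant (lowest CTI):",
      paste0(top$genotype, " (CTI = ", signif(top$CTI, 3), ")",
             collapse = ", "), "\n")
  bottom <- x$cti[x$cti$rank > x$meta$n_genotypes - 2, ]
  cat("Most sensitive (highest CTI):",
      paste0(bottom$genotype, " (CTI = ", signif(bottom$CTI, 3), ")",
             collapse = ", "), "\n\n")
  pc <- x$pca$component_variance_percent
  cat("PCA: PC1 explains ", round(pc[1], 1), "%, PC2 ",
      round(pc[2], 1), "% of trait variance\n", sep = "")
  invisible(x)
}

#' Write every screening artifact to a directory
#'
#' Serializes a [run_screening()] report: `stats.csv`, `cti.csv`,
#' `ratios.csv`, `corr.csv` (square correlation matrix),
#' `corr_pairs.csv` (long format with r, p, Holm-adjusted p, stars),
#' `pca_variance.csv`, `pca_loadings.csv`, `pca_scores.csv`,
#' `matrices.json`, `coefficients.json` and a human-readable `report.md`.
#' Machine-readable files carry full numeric precision; only `report.md`
#' rounds for display. Rerunning with identical inputs reproduces
#' identical files.
#'
#' @param report A `screening_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_screening <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(dir, name), progress = FALSE)
  }
  w(report$stats, "stats.csv")
  w(report$cti, "cti.csv")
  w(report$ratios, "ratios.csv")

  rmat <- tibble::as_tibble(report$correlation$r, rownames = "trait")
  w(rmat, "corr.csv")
  w(report$correlation$pairs, "corr_pairs.csv")

  pca <- report$pca
  w(tibble::tibble(
    component = paste0("PC", seq_along(pca$component_variance_percent)),
    variance_percent = pca$component_variance_percent,
    cumulative_percent = pca$cumulative_percent
  ), "pca_variance.csv")
  w(tibble::as_tibble(pca$loadings, rownames = "trait"), "pca_loadings.csv")
  w(tibble::as_tibble(pca$scores, rownames = "genotype"), "pca_scores.csv")

  jsonlite::write_json(
    list(traits = report$matrices$traits, P = report$matrices$P,
         G = report$matrices$G, r = report$matrices$r,
         kappa = report$matrices$kappa,
         singular = report$matrices$singular),
    file.path(dir, "matrices.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  jsonlite::write_json(
    list(traits = report$coeffs$traits, b = report$coeffs$b,
         a = report$coeffs$a,
         solve_residual = report$coeffs$solve_residual),
    file.path(dir, "coefficients.json"),
    auto_unbox = TRUE, digits = NA
  )

  counts <- category_counts(report$cti)
  md <- c(
    "# Cold-tolerance screening report",
    "",
    paste0("- genotypes: ", report$meta$n_genotypes),
    paste0("- seed: ", report$meta$seed),
    paste0("- config hash: ", report$meta$config_hash),
    "",
    "## Smith-Hazel index",
    "",
    paste0("CTI = ",
           paste(signif(report$coeffs$b, 4), report$coeffs$traits,
                 sep = " x ", collapse = " + "),
           "  (low CTI = tolerant)"),
    "",
    "## Tolerance categories",
    "",
    paste0("- ", names(counts), ": ", counts,
           " (", vapply(report$categories, function(g) {
             paste(head(g, 8), collapse = ", ")
           }, character(1)), ")"),
    "",
    "## PCA",
    "",
    paste0("PC1 = ",
           round(report$pca$component_variance_percent[1], 1),
           "%, PC2 = ",
           round(report$pca$component_variance_percent[2], 1),
           "% (cumulative ",
           round(report$pca$cumulative_percent[2], 1), "%)")
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
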