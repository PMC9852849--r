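#' Simulate a balanced replicated phenotype panel
#'
#' Draws a complete, balanced genotype x treatment x replicate (x trial)
#' phenotype table from the generative model described in
#' [panel_config()]:
#'
#' \deqn{y = \mu_t + \delta_t \, [cold] + u_{trial} + s_t \, (g + e)}
#'
#' where \eqn{\mu_t} is the control mean of the trait, \eqn{\delta_t} the
#' cold shift, \eqn{u_{trial}} an additive trial effect, \eqn{g} the
#' genotype's multivariate-normal effect vector (one draw per genotype from
#' `G_cov`), \eqn{e} an independent residual draw from `E_cov` per
#' replicate, and \eqn{s_t} equal to 1 under cold and `control_attenuation`
#' under control -- both the genetic signal and the dispersion around it
#' are expressed under cold and compressed under control. Values are
#' clipped to the configured bounds.
#'
#' The realized genotype effects are attached to the returned panel and can
#' be recovered with [panel_truth()] for parameter-recovery studies.
#'
#' @param config A [panel_config()] object.
#' @return A tibble of class `trait_panel` with columns `genotype`, `trial`,
#'   `replicate`, `treatment` (`"control"`/`"cold"`), `trait` and `value`;
#'   one row per observation.
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(n_genotypes = 5, seed = 7))
#' head(panel)
simulate_panel <- function(config) {
  if (!inherits(config, "panel_config")) {
    stop("`config` must be created with panel_config()", call. = FALSE)
  }
  g <- config$n_genotypes
  n_tr <- config$n_trials
  r <- config$n_replicates
  traits <- config$traits
  p <- length(traits)

  draws <- withr::with_seed(config$seed, {
    list(
      geno = MASS::mvrnorm(g, mu = rep(0, p), Sigma = config$G_cov),
      trial = matrix(stats::rnorm(n_tr * p, sd = config$trial_sd), n_tr, p),
      resid = MASS::mvrnorm(g * n_tr * r * 2L, mu = rep(0, p),
                            Sigma = config$E_cov)
    )
  })
  geno_eff <- matrix(draws$geno, nrow = g, ncol = p,
                     dimnames = list(NULL, traits))
  trial_eff <- matrix(draws$trial, nrow = n_tr, ncol = p,
                      dimnames = list(NULL, traits))
  resid <- matrix(draws$resid, ncol = p, dimnames = list(NULL, traits))

  ids <- genotype_ids(g)
  design <- expand.grid(
    replicate = seq_len(r),
    treatment = TREATMENT_LEVELS,
    trial = seq_len(n_tr),
    genotype = seq_len(g),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )

  # under control, genotype effects and residual dispersion are both
  # attenuated: cold is where varietal differences are expressed
  is_cold <- design$treatment == "cold"
  atten <- matrix(config$control_attenuation, nrow(design), p, byrow = TRUE)
  atten[is_cold, ] <- 1
  shift <- as.numeric(is_cold)

  values <- matrix(config$control_means, nrow(design), p, byrow = TRUE) +
    outer(shift, config$cold_shift) +
    trial_eff[design$trial, , drop = FALSE] +
    (geno_eff[design$genotype, , drop = FALSE] + resid) * atten

  if (config$ordinal_li && "LI" %in% traits) {
    values[, "LI"] <- pmin(pmax(round(values[, "LI"]), 1), 8)
  }
  if (!is.null(config$bounds)) {
    for (tr in names(config$bounds)) {
      b <- config$bounds[[tr]]
      values[, tr] <- pmin(pmax(values[, tr], b[1]), b[2])
    }
  }

  panel <- tibble::tibble(
    genotype = rep(ids[design$genotype], times = p),
    trial = rep(paste0("trial", design$trial), times = p),
    replicate = rep(design$replicate, times = p),
    treatment = rep(design$treatment, times = p),
    trait = rep(traits, each = nrow(design)),
    value = as.vector(values)
  )
  panel <- dplyr::arrange(panel, .data$genotype, .data$trial,
                          .data$treatment, .data$trait, .data$replicate)

  truth <- tibble::as_tibble(cbind(
    tibble::tibble(genotype = ids),
    as.data.frame(geno_eff)
  ))
  new_trait_panel(panel, truth = truth, config = config)
}

genotype_ids <- function(n) {
  sprintf("G%0*d", max(3L, nchar(n)), seq_len(n))
}

new_trait_panel <- function(df, truth = NULL, config = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "truth") <- truth
  attr(out, "config") <- config
  class(out) <- c("trait_panel", class(tibble::tibble()))
  out
}

#' Recover the realized genotype effects behind a simulated panel
#'
#' Returns the exact multivariate-normal genotype-effect draws used by
#' [simulate_panel()], keyed by genotype. This ground truth supports
#' parameter-recovery tests (e.g. comparing estimated genotypic covariances
#' against the configured `G_cov`) and selection-accuracy studies against
#' the aggregate genotypic worth.
#'
#' @param panel A `trait_panel` produced by [simulate_panel()].
#' @return A tibble with a `genotype` column and one column of genotype
#'   effects per trait (cold-response scale).
#' @export
panel_truth <- function(panel) {
  truth <- attr(panel, "truth", exact = TRUE)
  if (is.null(truth)) {
    stop("this panel carries no simulation truth; panel_truth() only ",
         "applies to panels produced by simulate_panel()", call. = FALSE)
  }
  truth
}

#' Validate the structure of a phenotype panel
#'
#' Checks the contract every downstream estimator relies on: required
#' columns, the two-level treatment coding, no duplicate observation keys,
#' and a balanced design (every genotype x trial x treatment x trait cell
#' has the same number of replicates).
#'
#' @param panel A data frame in long panel format.
#' @return The panel, invisibly, as a `trait_panel`. Errors describe the
#'   offending rows.
#' @export
validate_panel <- function(panel) {
  required <- c("genotype", "trial", "replicate", "treatment", "trait", "value")
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop("panel is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_tr <- setdiff(unique(panel$treatment), TREATMENT_LEVELS)
  if (length(bad_tr)) {
    stop("treatment must be one of ",
         paste(TREATMENT_LEVELS, collapse = "/"),
         "; found: ", paste(bad_tr, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(panel$value)) {
    stop("panel `value` column must be numeric", call. = FALSE)
  }
  keys <- paste(panel$genotype, panel$trial, panel$replicate,
                panel$treatment, panel$trait, sep = "\r")
  if (anyDuplicated(keys)) {
    dup <- panel[duplicated(keys), c("genotype", "trial", "replicate",
                                     "treatment", "trait")]
    stop("duplicate observation keys, e.g. genotype ", dup$genotype[1],
         " trial ", dup$trial[1], " replicate ", dup$replicate[1],
         " treatment ", dup$treatment[1], " trait ", dup$trait[1],
         call. = FALSE)
  }
  cells <- dplyr::count(
    panel, .data$genotype, .data$trial, .data$treatment, .data$trait
  )
  # every genotype must carry every trial x treatment x trait cell
  n_cells_expected <- length(unique(panel$genotype)) *
    length(unique(panel$trial)) * length(unique(panel$treatment)) *
    length(unique(panel$trait))
  if (nrow(cells) != n_cells_expected || length(unique(cells$n)) != 1L) {
    counts <- table(cells$genotype)
    off <- cells$genotype[which(cells$n != max(cells$n))]
    culprit <- if (nrow(cells) != n_cells_expected) {
      names(counts)[which.min(counts)]
    } else {
      off[1]
    }
    stop("panel is not balanced: genotype ", culprit,
         " has missing or uneven cells", call. = FALSE)
  }
  invisible(new_trait_panel(panel,
                            truth = attr(panel, "truth", exact = TRUE),
                            config = attr(panel, "config", exact = TRUE)))
}

#' Genotype entry means for a treatment
#'
#' Averages replicates (and, by default, trials in two stages: replicates
#' within trial first, then trial means) to one value per genotype and
#' trait under the requested treatment. Entry means are the unit on which
#' descriptive statistics, the phenotypic covariance matrix and the
#' selection index operate.
#'
#' @param panel A `trait_panel` or equivalent long data frame.
#' @param treatment `"cold"` or `"control"`.
#' @param traits Optional character vector restricting/ordering the traits.
#' @param trials `"average"` (default) averages replicates within trial and
#'   then trials; `"pool"` averages all observations together. The two
#'   agree on balanced panels.
#' @return A wide tibble: `genotype` plus one numeric column per trait.
#' @export
entry_means <- function(panel, treatment = "cold", traits = NULL,
                        trials = c("average", "pool")) {
  trials <- match.arg(trials)
  treatment <- normalize_treatment(treatment)
  sub <- panel[panel$treatment == treatment, , drop = FALSE]
  if (!is.null(traits)) {
    missing <- setdiff(traits, unique(sub$trait))
    if (length(missing)) {
      stop("trait(s) not present under ", treatment, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    sub <- sub[sub$trait %in% traits, , drop = FALSE]
  } else {
    traits <- unique(sub$trait)
  }
  if (nrow(sub) == 0L) {
    stop("no observations under treatment ", treatment, call. = FALSE)
  }
  if (trials == "average") {
    sub <- dplyr::summarise(
      dplyr::group_by(sub, .data$genotype, .data$trial, .data$trait),
      value = mean(.data$value), .groups = "drop"
    )
  }
  means <- dplyr::summarise(
    dplyr::group_by(sub, .data$genotype, .data$trait),
    value = mean(.data$value), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(means, names_from = "trait",
                             values_from = "value")
  wide[, c("genotype", traits)]
}

normalize_treatment <- function(x) {
  out <- tolower(trimws(x))
  if (!all(out %in% TREATMENT_LEVELS)) {
    stop("treatment must be one of ",
         paste(TREATMENT_LEVELS, collapse = "/"), call. = FALSE)
  }
  out
}
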