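#' Default trait preset for a soybean cold-screening trial
#'
#' Returns the trait set and calibrated generator parameters used as defaults
#' by [panel_config()]. The preset describes a seedling-stage cold screen:
#' leaf injury index (`LI`, ordinal 1--8 scale treated numerically),
#' photochemical quenching (`qL`, 0--1), maximum PSII quantum efficiency
#' (`FvFm`, 0--1), theoretical non-photochemical quenching (`NPQt`),
#' quantum yield of non-regulated dissipation (`PhiNO`), SPAD chlorophyll
#' index, leaf thickness (`LT`, mm) and leaf area (`LeafArea`, cm^2).
#'
#' Control means and cold shifts are chosen so that simulated trait ranges
#' under 22 degC control and 4 degC cold match what a diverse 100-genotype
#' soybean panel displays (e.g. cold qL spanning roughly 0.18--0.81 while
#' control qL stays near 0.98). Genotypic standard deviations are expressed
#' on the cold-response scale; the residual covariance is `G/5`, which with
#' three replications gives an entry-mean broad-sense heritability of
#' 93.75% for every trait. The genotypic correlation structure places
#' negative correlations between the injury score and the two photochemical
#' traits (`LI`--`qL` = -0.22, `LI`--`FvFm` = -0.30) and positive
#' correlations among quenching-related traits.
#'
#' @return A named list with elements `traits`, `control_means`,
#'   `cold_shift`, `G_cov`, `E_cov` and `bounds`, in the shapes
#'   [panel_config()] expects.
#' @export
#' @examples
#' p <- cold_preset()
#' p$traits
#' diag(p$G_cov) / diag(p$E_cov)   # genotypic : residual variance = 5
cold_preset <- function() {
  traits <- c("LI", "qL", "FvFm", "NPQt", "PhiNO", "SPAD", "LT", "LeafArea")

  control_means <- c(
    LI = 1.2, qL = 0.98, FvFm = 0.80, NPQt = 25,
    PhiNO = 0.18, SPAD = 31, LT = 0.28, LeafArea = 15
  )
  cold_shift <- c(
    LI = 3.6, qL = -0.48, FvFm = -0.35, NPQt = 975,
    PhiNO = 0.07, SPAD = -2, LT = -0.04, LeafArea = 0
  )

  # genotypic SDs on the cold-response scale
  sd_g <- c(
    LI = 1.3, qL = 0.125, FvFm = 0.135, NPQt = 270,
    PhiNO = 0.04, SPAD = 3.4, LT = 0.05, LeafArea = 2.2
  )

  R <- diag(8)
  dimnames(R) <- list(traits, traits)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("LI", "qL", -0.22)
  set_r("LI", "FvFm", -0.30)
  set_r("qL", "FvFm", 0.50)
  set_r("NPQt", "LI", 0.20)
  set_r("NPQt", "qL", -0.40)
  set_r("NPQt", "FvFm", -0.40)
  set_r("NPQt", "LT", 0.30)
  set_r("PhiNO", "LI", 0.15)
  set_r("PhiNO", "qL", -0.20)
  set_r("PhiNO", "FvFm", -0.20)
  set_r("PhiNO", "NPQt", 0.30)

  G_cov <- diag(sd_g) %*% R %*% diag(sd_g)
  dimnames(G_cov) <- list(traits, traits)
  # residual covariance shares the genotypic correlation structure;
  # G/E = 5 fixes entry-mean H2 at 5/(5 + 1/3) = 93.75% for r = 3
  E_cov <- G_cov / 5

  bounds <- list(
    LI = c(1, 8), qL = c(0, 1), FvFm = c(0, 1), NPQt = c(0, Inf),
    PhiNO = c(0, 1), SPAD = c(0, Inf), LT = c(0, Inf), LeafArea = c(0, Inf)
  )

  # NPQt's cold-response scale is ~40x its control scale, so its control
  # attenuation is much stronger than the default 0.2
  control_attenuation <- c(
    LI = 0.2, qL = 0.2, FvFm = 0.2, NPQt = 0.025,
    PhiNO = 0.2, SPAD = 0.2, LT = 0.2, LeafArea = 0.2
  )

  list(
    traits = traits, control_means = control_means, cold_shift = cold_shift,
    G_cov = G_cov, E_cov = E_cov, bounds = bounds,
    control_attenuation = control_attenuation
  )
}

#' Configure a synthetic replicated phenotype trial
#'
#' Builds and validates the configuration object consumed by
#' [simulate_panel()]. The generator emulates a complete randomization
#' design: `n_genotypes` genotypes grown under two treatments (22 degC
#' control, 4 degC cold) in `n_replicates` replications, optionally across
#' `n_trials` independent trial runs.
#'
#' Each genotype receives one multivariate-normal effect vector drawn from
#' `G_cov`. Cold stress is where varietal differences are expressed, so the
#' genotype effect enters at full strength under cold and is attenuated by
#' `control_attenuation` under control. Residuals are independent
#' multivariate-normal draws from `E_cov` per replicate.
#'
#' @param n_genotypes Number of genotypes (default 100).
#' @param n_trials Number of independent trial runs (default 1).
#' @param n_replicates Replications per genotype x treatment x trial; must be
#'   at least 2 so error variance is estimable (default 3).
#' @param traits Ordered character vector of trait names.
#' @param control_means Named numeric vector: per-trait mean under control,
#'   in trait units.
#' @param cold_shift Named numeric vector: signed additive treatment effect
#'   under cold.
#' @param G_cov Genotypic covariance matrix over `traits` (trait-units^2,
#'   on the cold-response scale). Must be symmetric positive semi-definite.
#' @param E_cov Residual covariance matrix over `traits`; same requirements.
#' @param trial_sd Standard deviation of additive trial main effects
#'   (default 0; effects are drawn per trial and trait).
#' @param control_attenuation Multiplier applied to genotype effects and
#'   residuals under control, either a scalar or a named per-trait vector
#'   (default 0.2, except for the stronger NPQt attenuation in
#'   [cold_preset()]). Cold stress is where varietal and replicate
#'   dispersion is expressed; control conditions show only a narrow band of
#'   variation.
#' @param bounds Optional named list of `c(lo, hi)` clipping ranges per trait.
#' @param ordinal_li If `TRUE`, leaf injury (`LI`) values are rounded to the
#'   ordinal 1--8 scale after simulation (default `FALSE`: continuous).
#' @param seed Integer RNG seed; identical configurations yield identical
#'   panels.
#'
#' @return An object of class `panel_config`.
#' @seealso [cold_preset()] for the calibrated defaults, [simulate_panel()].
#' @export
#' @examples
#' cfg <- panel_config(n_genotypes = 10, seed = 42)
#' cfg
panel_config <- function(n_genotypes = 100,
                         n_trials = 1,
                         n_replicates = 3,
                         traits = NULL,
                         control_means = NULL,
                         cold_shift = NULL,
                         G_cov = NULL,
                         E_cov = NULL,
                         trial_sd = 0,
                         control_attenuation = NULL,
                         bounds = NULL,
                         ordinal_li = FALSE,
                         seed = 1L) {
  preset <- cold_preset()
  if (is.null(traits)) {
    traits <- preset$traits
    if (is.null(control_means)) control_means <- preset$control_means
    if (is.null(cold_shift)) cold_shift <- preset$cold_shift
    if (is.null(G_cov)) G_cov <- preset$G_cov
    if (is.null(E_cov)) E_cov <- preset$E_cov
    if (is.null(bounds)) bounds <- preset$bounds
    if (is.null(control_attenuation)) {
      control_attenuation <- preset$control_attenuation
    }
  }
  if (is.null(control_attenuation)) control_attenuation <- 0.2
  traits <- as.character(traits)
  p <- length(traits)
  if (p < 1L) stop("`traits` must name at least one trait", call. = FALSE)
  if (anyDuplicated(traits)) stop("`traits` contains duplicates", call. = FALSE)

  control_means <- resolve_trait_vector(control_means, traits, "control_means")
  cold_shift <- resolve_trait_vector(cold_shift, traits, "cold_shift")
  G_cov <- resolve_cov_matrix(G_cov, traits, "G_cov")
  E_cov <- resolve_cov_matrix(E_cov, traits, "E_cov")

  if (!is.numeric(n_replicates) || n_replicates < 2) {
    stop("`n_replicates` must be at least 2 (variance components need ",
         "within-genotype replication)", call. = FALSE)
  }
  if (n_genotypes < 1) stop("`n_genotypes` must be positive", call. = FALSE)
  if (n_trials < 1) stop("`n_trials` must be positive", call. = FALSE)
  if (trial_sd < 0) stop("`trial_sd` must be non-negative", call. = FALSE)
  if (length(control_attenuation) > 1L || !is.null(names(control_attenuation))) {
    control_attenuation <- resolve_trait_vector(control_attenuation, traits,
                                                "control_attenuation")
  } else {
    control_attenuation <- setNames(rep(as.numeric(control_attenuation),
                                        length(traits)), traits)
  }
  if (any(control_attenuation < 0)) {
    stop("`control_attenuation` must be non-negative", call. = FALSE)
  }
  if (!is.null(bounds)) {
    bad <- setdiff(names(bounds), traits)
    if (length(bad)) {
      stop("`bounds` given for unknown traits: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (tr in names(bounds)) {
      b <- bounds[[tr]]
      if (length(b) != 2L || b[1] > b[2]) {
        stop("bounds for trait ", tr, " must be c(lo, hi) with lo <= hi",
             call. = FALSE)
      }
      m <- control_means[[tr]]
      if (m < b[1] || m > b[2]) {
        stop("control mean for trait ", tr, " (", m,
             ") lies outside its bounds [", b[1], ", ", b[2], "]",
             call. = FALSE)
      }
    }
  }

  structure(
    list(
      n_genotypes = as.integer(n_genotypes),
      n_trials = as.integer(n_trials),
      n_replicates = as.integer(n_replicates),
      traits = traits,
      control_means = control_means,
      cold_shift = cold_shift,
      G_cov = G_cov,
      E_cov = E_cov,
      trial_sd = trial_sd,
      control_attenuation = control_attenuation,
      bounds = bounds,
      ordinal_li = isTRUE(ordinal_li),
      seed = as.integer(seed)
    ),
    class = "panel_config"
  )
}

resolve_trait_vector <- function(x, traits, what) {
  if (is.null(x)) {
    stop("`", what, "` must be supplied when `traits` is customised",
         call. = FALSE)
  }
  if (!is.null(names(x))) {
    missing <- setdiff(traits, names(x))
    if (length(missing)) {
      stop("`", what, "` is missing traits: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- x[traits]
  } else if (length(x) == length(traits)) {
    names(x) <- traits
  } else {
    stop("`", what, "` must have one value per trait", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x)) {
    stop("`", what, "` must be numeric and complete", call. = FALSE)
  }
  x
}

resolve_cov_matrix <- function(m, traits, what) {
  p <- length(traits)
  if (is.null(m)) {
    stop("`", what, "` must be supplied when `traits` is customised",
         call. = FALSE)
  }
  if (length(m) == 1L && p == 1L) m <- matrix(as.numeric(m), 1, 1)
  m <- as.matrix(m)
  if (!all(dim(m) == p)) {
    stop("`", what, "` must be a ", p, "x", p, " matrix matching `traits`",
         call. = FALSE)
  }
  if (!is.null(rownames(m)) && all(traits %in% rownames(m))) {
    m <- m[traits, traits, drop = FALSE]
  }
  dimnames(m) <- list(traits, traits)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop("`", what, "` must be symmetric", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev))) {
    stop("`", what, "` is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  m
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config>\n")
  cat("  genotypes:", x$n_genotypes,
      " trials:", x$n_trials,
      " replicates:", x$n_replicates, "\n")
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  att <- unique(signif(x$control_attenuation, 3))
  cat("  trial_sd:", x$trial_sd,
      " control_attenuation:", paste(att, collapse = "/"),
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Read a panel configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [panel_config()]; covariance matrices are
#' given as nested lists in the same trait order as `traits`, and `bounds`
#' as a mapping from trait name to a two-element list.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A `panel_config` object.
#' @export
read_panel_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(panel_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("G_cov", "E_cov")) {
    if (!is.null(raw[[k]]) && !is.matrix(raw[[k]])) {
      raw[[k]] <- do.call(rbind, lapply(raw[[k]], unlist))
    }
  }
  if (!is.null(raw$control_means)) raw$control_means <- unlist(raw$control_means)
  if (!is.null(raw$cold_shift)) raw$cold_shift <- unlist(raw$cold_shift)
  if (!is.null(raw$bounds)) raw$bounds <- lapply(raw$bounds, unlist)
  do.call(panel_config, raw)
}
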