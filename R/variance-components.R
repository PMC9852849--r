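#' @noRd
#' Arrange one treatment's observations as a genotype x unit x trait array.
#'
#' Replication units are trials (replicates averaged within trial first)
#' when `trials = "average"` and more than one trial is present; otherwise
#' every trial x replicate observation is its own unit.
trait_unit_array <- function(panel, traits, treatment,
                             trials = c("average", "pool")) {
  trials <- match.arg(trials)
  treatment <- normalize_treatment(treatment)
  traits <- unique(traits)
  sub <- panel[panel$treatment == treatment & panel$trait %in% traits, ,
               drop = FALSE]
  missing <- setdiff(traits, unique(sub$trait))
  if (length(missing)) {
    stop("trait(s) not present under ", treatment, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_trials <- length(unique(sub$trial))
  unit <- if (trials == "average" && n_trials > 1L) {
    sub$trial
  } else {
    paste(sub$trial, sub$replicate, sep = ".")
  }
  arr <- tapply(
    sub$value,
    list(
      genotype = factor(sub$genotype),
      unit = factor(unit),
      trait = factor(sub$trait, levels = traits)
    ),
    mean
  )
  if (anyNA(arr)) {
    stop("panel is unbalanced under ", treatment,
         ": some genotype x unit x trait cells are empty", call. = FALSE)
  }
  arr
}

#' One-way random-effects ANOVA for a trait
#'
#' Partitions one treatment's observations by genotype and returns the
#' genotype mean square (MSG), error mean square (MSE), their variance
#' ratio F = MSG/MSE and the p-value from the F distribution with
#' (g - 1, g(r - 1)) degrees of freedom. Under the random-effects model
#' E\[MSG\] = r sigma2_g + sigma2_e and E\[MSE\] = sigma2_e, which is what
#' [heritability()] and [genotypic_covariance()] exploit.
#'
#' @param panel A `trait_panel` or equivalent long data frame.
#' @param trait Trait name.
#' @param treatment `"cold"` (default) or `"control"`.
#' @param trials How multiple trials enter the replication structure:
#'   `"average"` (default) averages replicates within trial and uses trial
#'   means as replicates; `"pool"` uses every trial x replicate observation.
#' @return A one-row tibble with `trait`, `treatment`, `n_genotypes`, `r`,
#'   `df1`, `df2`, `MSG`, `MSE`, `F` and `p_value`.
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(n_genotypes = 20, seed = 3))
#' anova_one_way(panel, "qL")
anova_one_way <- function(panel, trait, treatment = "cold",
                          trials = c("average", "pool")) {
  arr <- trait_unit_array(panel, trait, treatment, trials)
  m <- arr[, , 1L, drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(arr)[1])
  g <- nrow(m)
  r <- ncol(m)
  if (g < 2L) stop("need at least 2 genotypes for ANOVA", call. = FALSE)
  if (r < 2L) {
    stop("need at least 2 replication units per genotype (r = 1 leaves ",
         "the error mean square undefined)", call. = FALSE)
  }
  entry <- rowMeans(m)
  MSG <- r * var(entry)
  MSE <- mean(apply(m, 1L, var))
  if (MSE == 0 && MSG == 0) {
    warning("all observations identical for trait ", trait,
            "; F is undefined", call. = FALSE)
    Fval <- NaN
    p <- NaN
  } else {
    Fval <- MSG / MSE
    p <- pf(Fval, g - 1L, g * (r - 1L), lower.tail = FALSE)
  }
  tibble::tibble(
    trait = trait, treatment = normalize_treatment(treatment),
    n_genotypes = g, r = r, df1 = g - 1L, df2 = g * (r - 1L),
    MSG = MSG, MSE = MSE, F = Fval, p_value = p
  )
}

#' Broad-sense heritability from expected mean squares
#'
#' Computes sigma2_g = max(0, (MSG - MSE)/r) and, on the default
#' entry-mean basis, H2 = 100 sigma2_g / (sigma2_g + MSE/r) -- the fraction
#' of variance among genotype means that is genotypic. The plot basis
#' (H2 = 100 sigma2_g / (sigma2_g + MSE)) is available via `basis`.
#'
#' @param MSG Genotype mean square (vectorised).
#' @param MSE Error mean square.
#' @param r Number of replication units per genotype; must be >= 2.
#' @param basis `"entry_mean"` (default) or `"plot"`.
#' @return Heritability in percent, in \[0, 100\]. Negative genotypic
#'   variance estimates are floored at zero (with a warning), so
#'   MSG <= MSE yields 0.
#' @export
#' @examples
#' heritability(MSG = 4, MSE = 0.5, r = 2)  # 87.5
heritability <- function(MSG, MSE, r, basis = c("entry_mean", "plot")) {
  basis <- match.arg(basis)
  if (any(r < 2)) stop("`r` must be at least 2", call. = FALSE)
  if (any(MSE < 0) || any(MSG < 0)) {
    stop("mean squares must be non-negative", call. = FALSE)
  }
  s2g <- (MSG - MSE) / r
  if (any(s2g < 0)) {
    warning("negative genotypic variance estimate floored at 0",
            call. = FALSE)
    s2g <- pmax(s2g, 0)
  }
  denom <- if (basis == "entry_mean") s2g + MSE / r else s2g + MSE
  h2 <- ifelse(denom > 0, 100 * s2g / denom, 0)
  # MSE = 0 with genotypic signal: all variance is genetic
  h2[denom == 0 & s2g == 0 & MSG > 0] <- 100
  h2
}

#' Expected genetic advance under truncation selection
#'
#' GA = k (H2/100) sigma_p, the expected shift in the population mean after
#' selecting the best fraction of genotypes, where `sigma_p` is the
#' phenotypic standard deviation of entry means and `k` the standardized
#' selection differential (2.06 for the top 5%).
#'
#' @param H2_percent Broad-sense heritability in percent.
#' @param sigma_p Phenotypic standard deviation (entry-mean basis), >= 0.
#' @param k Selection intensity (default 2.06).
#' @return Genetic advance in trait units.
#' @export
genetic_advance <- function(H2_percent, sigma_p, k = 2.06) {
  if (any(k <= 0)) stop("`k` must be positive", call. = FALSE)
  if (any(sigma_p < 0)) stop("`sigma_p` must be non-negative", call. = FALSE)
  k * (H2_percent / 100) * sigma_p
}

#' Descriptive and variance-component statistics per trait
#'
#' For each trait under one treatment: descriptive statistics of genotype
#' entry means (min, max, mean, sample sd), the one-way ANOVA mean squares
#' and F test, variance components, broad-sense heritability, genetic
#' advance and coefficients of variation. The genotypic coefficient of
#' variation is CVb = 100 sigma_g / mean; the phenotypic analogue
#' (CVp = 100 sigma_p / mean) is reported alongside.
#'
#' @inheritParams anova_one_way
#' @param traits Traits to summarise (default: all traits in the panel).
#' @param k Selection intensity for genetic advance (default 2.06, top 5%).
#' @param basis Heritability basis, see [heritability()].
#' @return A tibble with one row per trait.
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(n_genotypes = 30, seed = 11))
#' trait_stats(panel, treatment = "cold")
trait_stats <- function(panel, treatment = "cold", traits = NULL,
                        k = 2.06, basis = c("entry_mean", "plot"),
                        trials = c("average", "pool")) {
  basis <- match.arg(basis)
  trials <- match.arg(trials)
  if (is.null(traits)) {
    traits <- unique(panel$trait[panel$treatment ==
                                   normalize_treatment(treatment)])
  }
  rows <- lapply(traits, function(tr) {
    a <- anova_one_way(panel, tr, treatment, trials)
    em <- entry_means(panel, treatment, tr, trials)[[tr]]
    s2g <- max(0, (a$MSG - a$MSE) / a$r)
    s2p <- s2g + a$MSE / a$r
    h2 <- heritability(a$MSG, a$MSE, a$r, basis)
    mu <- mean(em)
    dplyr::mutate(
      a,
      min = min(em), max = max(em), mean = mu, sd = sd(em),
      sigma2_g = s2g, sigma2_e = a$MSE,
      H2_percent = h2,
      GA = genetic_advance(h2, sqrt(s2p), k),
      CVb_percent = if (mu != 0) 100 * sqrt(s2g) / abs(mu) else NA_real_,
      CVp_percent = if (mu != 0) 100 * sqrt(s2p) / abs(mu) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  out[, c("trait", "treatment", "n_genotypes", "r", "min", "max", "mean",
          "sd", "MSG", "MSE", "F", "p_value", "sigma2_g", "sigma2_e",
          "H2_percent", "GA", "CVb_percent", "CVp_percent")]
}

#' Genotypic covariance between two traits
#'
#' Analysis-of-cross-products mirror of the one-way ANOVA: the genotype
#' mean cross-product MPG and error mean cross-product MPE satisfy
#' E\[MPG\] = r cov_g + cov_e and E\[MPE\] = cov_e, so
#' cov_g = (MPG - MPE)/r. With `traitY = traitX` this reduces to the
#' genotypic variance from [anova_one_way()].
#'
#' @inheritParams anova_one_way
#' @param traitX,traitY Trait names, measured on the same replicate units.
#' @return The estimated genotypic covariance (scalar), with the mean
#'   cross-products attached as attributes `MPG` and `MPE`.
#' @export
genotypic_covariance <- function(panel, traitX, traitY, treatment = "cold",
                                 trials = c("average", "pool")) {
  arr <- trait_unit_array(panel, c(traitX, traitY), treatment, trials)
  x <- arr[, , traitX]
  y <- arr[, , traitY]
  r <- ncol(x)
  if (r < 2L) stop("need at least 2 replication units", call. = FALSE)
  MPG <- r * stats::cov(rowMeans(x), rowMeans(y))
  devx <- x - rowMeans(x)
  devy <- y - rowMeans(y)
  MPE <- sum(devx * devy) / (nrow(x) * (r - 1L))
  structure((MPG - MPE) / r, MPG = MPG, MPE = MPE)
}

#' Assemble phenotypic and genotypic covariance matrices for index traits
#'
#' Builds the two matrices the Smith-Hazel index needs: `G`, the genotypic
#' variance-covariance matrix from the analysis of cross-products, and `P`,
#' the phenotypic variance-covariance matrix of genotype entry means
#' (equivalently G + E/r). Symmetry is exact by construction. The
#' condition number of `P` is recorded; an ill-conditioned `P` raises a
#' `singular` flag that [smith_hazel_coefficients()] refuses to ignore.
#'
#' @inheritParams anova_one_way
#' @param traits Index traits, in order (default `c("LI", "qL", "FvFm")`).
#' @param kappa_max Condition-number threshold above which `P` is flagged
#'   as numerically singular (default 1e8).
#' @return An object of class `index_matrices`: a list with `traits`, `P`,
#'   `G`, `r`, `n_genotypes`, `kappa`, `singular` and (when flagged)
#'   `flagged_pair` naming the most collinear trait pair.
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(seed = 5))
#' M <- build_index_matrices(panel)
#' M$G
build_index_matrices <- function(panel, traits = c("LI", "qL", "FvFm"),
                                 treatment = "cold",
                                 trials = c("average", "pool"),
                                 kappa_max = 1e8) {
  arr <- trait_unit_array(panel, traits, treatment, trials)
  g <- dim(arr)[1]
  r <- dim(arr)[2]
  p <- dim(arr)[3]
  if (r < 2L) stop("need at least 2 replication units", call. = FALSE)
  if (g < 3L) stop("need at least 3 genotypes", call. = FALSE)

  entry <- apply(arr, c(1, 3), mean)            # g x p genotype means
  MPG <- r * stats::cov(entry)
  dev <- sweep(arr, c(1, 3), entry)             # within-genotype deviations
  dev_mat <- matrix(aperm(dev, c(2, 1, 3)), nrow = g * r, ncol = p)
  MPE <- crossprod(dev_mat) / (g * (r - 1L))

  G <- (MPG - MPE) / r
  P <- MPG / r                                  # cov of entry means = G + E/r
  dimnames(G) <- dimnames(P) <- list(traits, traits)

  sv <- svd(P, nu = 0, nv = 0)$d
  kappa <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  singular <- !is.finite(kappa) || kappa > kappa_max
  flagged_pair <- NULL
  if (singular && p > 1L) {
    cors <- stats::cov2cor(P)
    diag(cors) <- 0
    idx <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    flagged_pair <- traits[sort(idx)]
  }
  structure(
    list(traits = traits, P = P, G = G, r = r, n_genotypes = g,
         kappa = kappa, singular = singular, flagged_pair = flagged_pair),
    class = "index_matrices"
  )
}

#' @export
print.index_matrices <- function(x, ...) {
  cat("<index_matrices> traits:", paste(x$traits, collapse = ", "),
      "(", x$n_genotypes, "genotypes, r =", x$r, ")\n")
  cat("P (phenotypic, entry-mean basis):\n")
  print(signif(x$P, 4))
  cat("G (genotypic):\n")
  print(signif(x$G, 4))
  if (x$singular) {
    cat("WARNING: P is numerically singular (condition number ",
        format(x$kappa, digits = 3), ")",
        if (!is.null(x$flagged_pair)) {
          paste0("; most collinear pair: ",
                 paste(x$flagged_pair, collapse = " ~ "))
        }, "\n", sep = "")
  }
  invisible(x)
}
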