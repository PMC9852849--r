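#' Cold/control stress ratios per genotype and trait
#'
#' For every genotype and trait, the ratio of the cold entry mean to the
#' control entry mean (replicates averaged within treatment first), e.g.
#' qL ratio = qL_cold / qL_control. Ratios near 1 indicate a trait
#' unaffected by cold; ratios below 1 a cold-depressed trait.
#'
#' Ratios whose control mean has absolute value at or below `epsilon` are
#' reported as missing (with a warning), never as infinities.
#'
#' @inheritParams anova_one_way
#' @param traits Optional subset/ordering of traits.
#' @param epsilon Control means with |mean| <= `epsilon` are treated as
#'   zero (default 1e-8).
#' @return A wide tibble: `genotype` plus one ratio column per trait.
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(n_genotypes = 10, seed = 2))
#' stress_ratios(panel)
stress_ratios <- function(panel, traits = NULL,
                          trials = c("average", "pool"), epsilon = 1e-8) {
  trials <- match.arg(trials)
  cold <- entry_means(panel, "cold", traits, trials)
  ctrl <- entry_means(panel, "control", traits, trials)
  if (!identical(cold$genotype, ctrl$genotype)) {
    ctrl <- ctrl[match(cold$genotype, ctrl$genotype), ]
    if (anyNA(ctrl$genotype)) {
      stop("cold and control treatments cover different genotypes",
           call. = FALSE)
    }
  }
  trait_cols <- setdiff(names(cold), "genotype")
  out <- cold
  n_dropped <- 0L
  for (tr in trait_cols) {
    denom <- ctrl[[tr]]
    bad <- abs(denom) <= epsilon
    n_dropped <- n_dropped + sum(bad)
    out[[tr]] <- ifelse(bad, NA_real_, cold[[tr]] / denom)
  }
  if (n_dropped > 0L) {
    warning(n_dropped, " ratio(s) dropped: control mean within epsilon ",
            "of zero", call. = FALSE)
  }
  out
}

#' Pearson correlation matrix with significance stars
#'
#' Pairwise-complete Pearson correlations over a genotype x trait table
#' (typically stress ratios, following the ratio convention, or entry
#' means). Two-sided p-values come from the t transform
#' t = r sqrt((n - 2)/(1 - r^2)) with n - 2 degrees of freedom, and are
#' annotated with `***` (p < 0.001), `**` (p < 0.01), `*` (p < 0.05) or
#' blank. Holm-adjusted p-values are emitted alongside in the long-format
#' table for family-wise control, but the stars mirror the conventional
#' per-pair thresholds.
#'
#' @param table A data frame with an optional `genotype` column and numeric
#'   trait columns.
#' @return An object of class `trait_correlation`: list with trait-square
#'   matrices `r`, `p`, `n` and `stars`, and a long tibble `pairs` with one
#'   row per trait pair (`r`, `r_squared`, `n`, `p`, `p_holm`, `stars`).
#'   Constant or insufficiently observed pairs yield `NA`.
#' @export
correlation_with_stars <- function(table) {
  X <- as.data.frame(table)
  if ("genotype" %in% names(X)) X$genotype <- NULL
  if (!all(vapply(X, is.numeric, logical(1)))) {
    stop("all trait columns must be numeric", call. = FALSE)
  }
  traits <- names(X)
  p_n <- length(traits)
  if (p_n < 2L) stop("need at least 2 traits", call. = FALSE)
  X <- as.matrix(X)

  r <- matrix(NA_real_, p_n, p_n, dimnames = list(traits, traits))
  pmat <- nmat <- r
  diag(r) <- 1
  diag(pmat) <- 0
  for (i in seq_len(p_n - 1L)) {
    for (j in seq(i + 1L, p_n)) {
      ok <- stats::complete.cases(X[, c(i, j)])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (n < 3L) next
      x <- X[ok, i]
      y <- X[ok, j]
      if (sd(x) == 0 || sd(y) == 0) {
        warning("constant column in pair ", traits[i], " ~ ", traits[j],
                "; correlation undefined", call. = FALSE)
        next
      }
      rij <- cor(x, y)
      r[i, j] <- r[j, i] <- rij
      pij <- if (abs(rij) >= 1) {
        0
      } else {
        tstat <- rij * sqrt((n - 2) / (1 - rij^2))
        2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
      }
      pmat[i, j] <- pmat[j, i] <- pij
    }
  }
  diag(nmat) <- vapply(seq_len(p_n),
                       function(i) sum(!is.na(X[, i])), numeric(1))

  ut <- upper.tri(r)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- tibble::tibble(
    trait_x = traits[idx[, 1]],
    trait_y = traits[idx[, 2]],
    r = r[ut],
    r_squared = r[ut]^2,
    n = as.integer(nmat[ut]),
    p = pmat[ut]
  )
  pairs$p_holm <- stats::p.adjust(pairs$p, method = "holm")
  pairs$stars <- p_stars(pairs$p)

  stars <- matrix(p_stars(pmat), p_n, p_n, dimnames = dimnames(r))
  diag(stars) <- ""
  structure(
    list(traits = traits, r = r, p = pmat, n = nmat, stars = stars,
         pairs = pairs),
    class = "trait_correlation"
  )
}

p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat("<trait_correlation> over", length(x$traits), "traits\n")
  disp <- matrix(
    paste0(formatC(x$r, digits = 2, format = "f"),
           ifelse(is.na(x$stars), "", x$stars)),
    nrow = nrow(x$r), dimnames = dimnames(x$r)
  )
  diag(disp) <- "1"
  print(disp, quote = FALSE)
  invisible(x)
}

#' Principal component analysis of trait variation
#'
#' PCA over a genotype x trait table via singular value decomposition of
#' the column-centred (and, by default, unit-scaled) matrix. Working on
#' standardized traits -- i.e. the correlation matrix -- is the default
#' because the traits span wildly different scales (NPQt in the hundreds,
#' qL in \[0, 1\]). Rows with any missing value are dropped (listwise).
#' Loading signs are fixed so each component's largest-magnitude loading is
#' positive, making results deterministic across platforms.
#'
#' @param table A data frame with an optional `genotype` column and numeric
#'   trait columns.
#' @param standardize Scale traits to unit variance (default `TRUE`).
#' @return An object of class `trait_pca`: list with
#'   `component_variance_percent`, `cumulative_percent`, `loadings`
#'   (trait x component), `scores` (genotype x component), `sdev` and
#'   `n_genotypes`.
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(seed = 9))
#' pca <- pca_traits(stress_ratios(panel))
#' pca$component_variance_percent[1:2]
pca_traits <- function(table, standardize = TRUE) {
  X <- as.data.frame(table)
  ids <- if ("genotype" %in% names(X)) as.character(X$genotype) else NULL
  if (!is.null(ids)) X$genotype <- NULL
  traits <- names(X)
  if (length(traits) < 2L) stop("need at least 2 traits", call. = FALSE)
  keep <- stats::complete.cases(X)
  X <- as.matrix(X[keep, , drop = FALSE])
  if (!is.null(ids)) ids <- ids[keep]
  if (nrow(X) < 3L) {
    stop("need at least 3 genotypes with complete trait records",
         call. = FALSE)
  }
  if (standardize && any(apply(X, 2, sd) == 0)) {
    stop("constant trait column(s) cannot be standardized: ",
         paste(traits[apply(X, 2, sd) == 0], collapse = ", "),
         call. = FALSE)
  }
  fit <- prcomp(X, center = TRUE, scale. = standardize)
  # deterministic orientation: largest-magnitude loading positive
  for (k in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[i, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  variance <- fit$sdev^2
  pct <- 100 * variance / sum(variance)
  scores <- fit$x
  if (!is.null(ids)) rownames(scores) <- ids
  structure(
    list(
      component_variance_percent = pct,
      cumulative_percent = cumsum(pct),
      loadings = fit$rotation,
      scores = scores,
      sdev = fit$sdev,
      n_genotypes = nrow(X)
    ),
    class = "trait_pca"
  )
}

#' @export
print.trait_pca <- function(x, ...) {
  k <- min(4L, length(x$component_variance_percent))
  cat("<trait_pca>", nrow(x$loadings), "traits,", x$n_genotypes,
      "genotypes\n")
  cat("variance explained (%):",
      paste0("PC", seq_len(k), " = ",
             round(x$component_variance_percent[seq_len(k)], 1),
             collapse = ", "),
      if (length(x$component_variance_percent) > k) ", ...", "\n")
  invisible(x)
}
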