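#' Smith-Hazel selection index coefficients
#'
#' Solves the Smith-Hazel system P b = G a for the index weight vector b,
#' where P and G are the phenotypic and genotypic variance-covariance
#' matrices of the index traits and a the vector of economic weights
#' (all ones by default). The system is solved directly (LU factorization),
#' not via explicit inversion, and the achieved residual
#' max |P b - G a| is recorded. The resulting linear index b'X has maximal
#' correlation with the aggregate genotypic worth a'g among all linear
#' phenotype indices.
#'
#' @param M An [build_index_matrices()] result, or a list with elements
#'   `traits`, `P` and `G`.
#' @param a Economic weights, one per trait (default all ones).
#' @param tol Maximum acceptable residual for the solve (default 1e-8).
#' @return An object of class `index_coefficients`: list with `traits`,
#'   `b`, `a` and `solve_residual`.
#' @export
#' @examples
#' M <- list(traits = c("LI", "qL", "FvFm"),
#'           P = diag(3), G = diag(c(0.967, 0.505, 0.335)))
#' smith_hazel_coefficients(M)$b
smith_hazel_coefficients <- function(M, a = NULL, tol = 1e-8) {
  P <- M$P
  G <- M$G
  traits <- M$traits
  p <- length(traits)
  if (!all(dim(P) == p) || !all(dim(G) == p)) {
    stop("P and G must be ", p, "x", p, " matrices over the index traits",
         call. = FALSE)
  }
  if (is.null(a)) a <- rep(1, p)
  if (length(a) != p) {
    stop("economic weights `a` must have one entry per trait (",
         p, " expected, ", length(a), " given)", call. = FALSE)
  }
  if (isTRUE(M$singular)) {
    stop("phenotypic matrix P is numerically singular",
         if (!is.null(M$flagged_pair)) {
           paste0(" (most collinear trait pair: ",
                  paste(M$flagged_pair, collapse = " ~ "), ")")
         },
         "; refusing to compute index coefficients", call. = FALSE)
  }
  rhs <- as.numeric(G %*% a)
  b <- tryCatch(
    as.numeric(solve(P, rhs)),
    error = function(e) {
      pair <- collinear_pair(P, traits)
      stop("phenotypic matrix P is singular",
           if (!is.null(pair)) {
             paste0(" (most collinear trait pair: ",
                    paste(pair, collapse = " ~ "), ")")
           },
           call. = FALSE)
    }
  )
  residual <- max(abs(P %*% b - rhs))
  if (residual > tol) {
    warning("solve residual ", format(residual, digits = 3),
            " exceeds tolerance ", tol, "; P is ill-conditioned",
            call. = FALSE)
  }
  index_coefficients(b, traits, a, solve_residual = residual)
}

collinear_pair <- function(P, traits) {
  if (length(traits) < 2L) return(NULL)
  d <- diag(P)
  if (any(d <= 0)) return(traits[c(which(d <= 0)[1], which(d <= 0)[1])])
  cors <- stats::cov2cor(P)
  diag(cors) <- 0
  idx <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
  traits[sort(idx)]
}

#' Construct an index-coefficient object from known weights
#'
#' Wraps an externally supplied weight vector (for example published
#' coefficients b1 = 0.967, b2 = 0.505, b3 = 0.335 over leaf injury, qL and
#' Fv/Fm) so it can be used by [compute_cti()] without re-estimating P and
#' G. Weights are used exactly as given; no rescaling is applied.
#'
#' @param b Numeric weight vector.
#' @param traits Trait names, same length and order as `b`
#'   (default `c("LI", "qL", "FvFm")` when `b` has length 3).
#' @param a Economic weights associated with `b` (default all ones).
#' @param solve_residual Residual carried over from an estimation step
#'   (0 for externally supplied weights).
#' @return An object of class `index_coefficients`.
#' @export
#' @examples
#' cf <- index_coefficients(c(0.967, 0.505, 0.335))
#' compute_cti(cf, c(LI = 1, qL = 1, FvFm = 1))  # 1.807
index_coefficients <- function(b, traits = NULL, a = NULL,
                               solve_residual = 0) {
  b <- as.numeric(b)
  if (is.null(traits)) {
    traits <- if (length(b) == 3L) c("LI", "qL", "FvFm") else
      paste0("X", seq_along(b))
  }
  if (length(traits) != length(b)) {
    stop("`traits` and `b` must have the same length", call. = FALSE)
  }
  if (is.null(a)) a <- rep(1, length(b))
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  names(b) <- traits
  structure(
    list(traits = traits, b = b, a = a, solve_residual = solve_residual),
    class = "index_coefficients"
  )
}

#' @export
print.index_coefficients <- function(x, ...) {
  cat("<index_coefficients>\n")
  print(signif(x$b, 4))
  cat("economic weights a:", paste(signif(x$a, 4), collapse = ", "),
      " solve residual:", format(x$solve_residual, digits = 3), "\n")
  invisible(x)
}

#' Score genotypes with the cold tolerance index
#'
#' CTI = b1 X1 + b2 X2 + b3 X3 (+ ...): the exact dot product of the index
#' weights with each genotype's index-trait values. No standardization or
#' re-orientation is applied unless requested: the index is used on raw
#' trait values and low CTI indicates high cold tolerance.
#'
#' @param coeffs An `index_coefficients` object.
#' @param X A numeric vector (one genotype) or a matrix/data frame with one
#'   column per index trait, named to match `coeffs$traits` (a `genotype`
#'   column is carried through if present).
#' @param standardize If `TRUE`, columns of `X` are centred and scaled
#'   before the dot product (default `FALSE`).
#' @param orient Optional named numeric vector of +-1 applied to trait
#'   columns before scoring, for users who want strictly monotone-bad
#'   indices; default leaves traits as measured.
#' @return A numeric vector of CTI scores, named by genotype when ids are
#'   available.
#' @export
compute_cti <- function(coeffs, X, standardize = FALSE, orient = NULL) {
  if (!inherits(coeffs, "index_coefficients")) {
    stop("`coeffs` must be an index_coefficients object", call. = FALSE)
  }
  traits <- coeffs$traits
  ids <- NULL
  if (is.data.frame(X)) {
    if ("genotype" %in% names(X)) {
      ids <- as.character(X$genotype)
      X <- X[, setdiff(names(X), "genotype"), drop = FALSE]
    }
    X <- as.matrix(X)
  }
  if (is.null(dim(X))) {
    X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  }
  if (!is.null(colnames(X))) {
    missing <- setdiff(traits, colnames(X))
    if (length(missing)) {
      stop("X is missing index trait(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    X <- X[, traits, drop = FALSE]
  } else if (ncol(X) != length(traits)) {
    stop("X must have one column per index trait (", length(traits),
         " expected)", call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    who <- if (!is.null(ids)) ids[bad[1]] else paste("row", bad[1])
    stop("missing or non-finite value for genotype ", who, ", trait ",
         traits[bad[2]], call. = FALSE)
  }
  if (!is.null(orient)) {
    orient <- resolve_trait_vector(orient, traits, "orient")
    X <- sweep(X, 2L, orient, `*`)
  }
  if (standardize) X <- scale(X)
  scores <- as.numeric(X %*% coeffs$b)
  if (!is.null(ids)) names(scores) <- ids
  scores
}

#' Rank genotypes by CTI and assign tolerance categories
#'
#' Sorts genotypes by ascending CTI (rank 1 = lowest CTI = most tolerant;
#' ties broken by genotype id, lexicographically) and partitions them into
#' the five tolerance categories T (tolerant), MT (moderately tolerant),
#' MS (moderately sensitive), S (sensitive) and SS (severely sensitive).
#'
#' The default scheme cuts the observed CTI range into five equal-width
#' bins. Alternatives: `"quantile"` uses the 20/40/60/80% quantiles, and
#' explicit interior `breaks` may be supplied.
#'
#' @param scores Numeric CTI scores, named by genotype (or `ids` given).
#' @param ids Genotype identifiers matching `scores`.
#' @param scheme `"equal_width"` (default) or `"quantile"`.
#' @param breaks Optional numeric vector of 4 interior breakpoints
#'   overriding `scheme`.
#' @return A tibble of class `cti_table` with columns `genotype`, `CTI`,
#'   `rank` and `category` (factor with levels T, MT, MS, S, SS), sorted by
#'   rank. If all scores are identical every genotype lands in the middle
#'   class (MS) with a warning.
#' @export
#' @examples
#' rank_and_categorize(c(a = 1, b = 2, c = 3, d = 4, e = 5))
rank_and_categorize <- function(scores, ids = names(scores),
                                scheme = c("equal_width", "quantile"),
                                breaks = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(ids)) ids <- genotype_ids(length(scores))
  if (length(ids) != length(scores)) {
    stop("`ids` must match `scores` in length", call. = FALSE)
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("CTI scores must be finite", call. = FALSE)
  }
  n <- length(scores)
  if (is.null(breaks) && n < 5L) {
    stop("need at least 5 genotypes for the five-class scheme",
         call. = FALSE)
  }

  ord <- order(scores, ids)
  rank <- integer(n)
  rank[ord] <- seq_len(n)

  rng <- range(scores)
  if (is.null(breaks) && rng[1] == rng[2]) {
    warning("all CTI scores identical; assigning every genotype to the ",
            "middle category", call. = FALSE)
    category <- factor(rep("MS", n), levels = CATEGORY_LEVELS)
  } else {
    cuts <- if (!is.null(breaks)) {
      if (length(breaks) != 4L) {
        stop("`breaks` must supply 4 interior breakpoints", call. = FALSE)
      }
      c(-Inf, sort(breaks), Inf)
    } else if (scheme == "equal_width") {
      c(-Inf, seq(rng[1], rng[2], length.out = 6L)[2:5], Inf)
    } else {
      c(-Inf, unique(quantile(scores, probs = c(0.2, 0.4, 0.6, 0.8))), Inf)
    }
    category <- cut(scores, breaks = cuts, labels = FALSE,
                    include.lowest = TRUE, right = TRUE)
    # quantile cuts may collapse when ties abound; pad labels accordingly
    labels <- CATEGORY_LEVELS[seq_len(length(cuts) - 1L)]
    category <- factor(labels[category], levels = CATEGORY_LEVELS)
  }

  out <- tibble::tibble(genotype = ids, CTI = as.numeric(scores),
                        rank = rank, category = category)
  out <- out[ord, ]
  class(out) <- c("cti_table", class(tibble::tibble()))
  out
}

#' Full cold-tolerance index table for a panel
#'
#' Convenience wrapper running the whole index stage on a panel: extracts
#' index-trait entry means under cold, scores each genotype with
#' [compute_cti()], then ranks and categorizes with
#' [rank_and_categorize()].
#'
#' @inheritParams anova_one_way
#' @param coeffs An `index_coefficients` object (estimated via
#'   [smith_hazel_coefficients()] or supplied via [index_coefficients()]).
#' @param scheme,breaks Passed to [rank_and_categorize()].
#' @return A `cti_table` tibble with the index-trait entry means (X
#'   columns), `CTI`, `rank` and `category`, sorted by rank.
#' @export
cti_table <- function(panel, coeffs, treatment = "cold",
                      trials = c("average", "pool"),
                      scheme = c("equal_width", "quantile"), breaks = NULL) {
  X <- entry_means(panel, treatment, coeffs$traits, trials)
  scores <- compute_cti(coeffs, X)
  out <- rank_and_categorize(scores, ids = X$genotype,
                             scheme = scheme, breaks = breaks)
  out <- dplyr::left_join(out, X, by = "genotype")[
    , c("genotype", coeffs$traits, "CTI", "rank", "category")]
  class(out) <- c("cti_table", class(tibble::tibble()))
  out
}

#' Count genotypes per tolerance category
#'
#' @param x A `cti_table` (or any data frame with a `category` column).
#' @return A named integer vector over the fixed category order
#'   T, MT, MS, S, SS.
#' @export
category_counts <- function(x) {
  tab <- table(factor(x$category, levels = CATEGORY_LEVELS))
  setNames(as.integer(tab), CATEGORY_LEVELS)
}
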