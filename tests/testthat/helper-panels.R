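# Build a tiny long-format panel by hand.
# `values` is a named list: genotype -> numeric vector of replicate values.
# One trait, one trial, one treatment unless overridden.
manual_panel <- function(values, trait = "y", treatment = "cold",
                         trial = "trial1") {
  rows <- lapply(names(values), function(g) {
    v <- values[[g]]
    tibble::tibble(
      genotype = g, trial = trial, replicate = seq_along(v),
      treatment = treatment, trait = trait, value = v
    )
  })
  dplyr::bind_rows(rows)
}

# Stack several manual panels (e.g. multiple traits or treatments).
stack_panels <- function(...) dplyr::bind_rows(...)

# Single-trait generator config with explicit variance components.
scalar_config <- function(seed, g = 100, r = 3, s2g = 5, s2e = 1,
                          mean = 0, shift = 0) {
  panel_config(
    n_genotypes = g, n_replicates = r, traits = "y",
    control_means = c(y = mean), cold_shift = c(y = shift),
    G_cov = matrix(s2g), E_cov = matrix(s2e), seed = seed
  )
}

# Three-trait config whose genotypic and residual correlation structure
# both encode the same trait correlations, so cold entry means (and, with
# large control means, stress ratios) carry those correlations.
ratio_recovery_config <- function(seed, g = 100) {
  traits <- c("qL", "FvFm", "LI")
  R <- matrix(c(
    1.00, 0.50, -0.22,
    0.50, 1.00, -0.30,
    -0.22, -0.30, 1.00
  ), 3, 3, dimnames = list(traits, traits))
  sd_g <- c(qL = 5, FvFm = 5, LI = 15)
  G <- diag(sd_g) %*% R %*% diag(sd_g)
  panel_config(
    n_genotypes = g, n_replicates = 3, traits = traits,
    control_means = c(qL = 100, FvFm = 100, LI = 100),
    cold_shift = c(qL = -50, FvFm = -50, LI = 50),
    G_cov = G, E_cov = G / 5, seed = seed
  )
}
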