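#' Read a phenotype panel from CSV
#'
#' Expects the long panel format: columns `genotype`, `trial`, `replicate`,
#' `treatment`, `trait`, `value` (any column order; matched by name), one
#' observation per row, decimal-point numbers, UTF-8. Treatment labels are
#' normalized to lower case (`"Cold"` is accepted as `"cold"`, with a
#' warning). The panel is validated for duplicate keys and balance before
#' being returned.
#'
#' @param path Path to a CSV file.
#' @return A `trait_panel` tibble.
#' @export
read_panel <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("genotype", "trial", "replicate", "treatment", "trait",
                "value")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("malformed panel header in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value) & !is.na(raw$value))
  if (length(bad)) {
    stop("non-numeric value at line ", bad[1] + 1L, " of ", path, ": '",
         raw$value[bad[1]], "'", call. = FALSE)
  }
  replicate <- suppressWarnings(as.integer(raw$replicate))
  if (anyNA(replicate)) {
    stop("non-integer replicate at line ",
         which(is.na(replicate))[1] + 1L, " of ", path, call. = FALSE)
  }
  treatment <- tolower(trimws(raw$treatment))
  if (!identical(treatment, raw$treatment)) {
    warning("treatment labels normalized to lower case", call. = FALSE)
  }
  bad_tr <- setdiff(unique(treatment), TREATMENT_LEVELS)
  if (length(bad_tr)) {
    stop("unknown treatment label(s) in ", path, ": ",
         paste(bad_tr, collapse = ", "), call. = FALSE)
  }
  panel <- tibble::tibble(
    genotype = raw$genotype, trial = raw$trial, replicate = replicate,
    treatment = treatment, trait = raw$trait, value = value
  )
  validate_panel(panel)
}

#' Write a phenotype panel to CSV
#'
#' Writes the long panel format read back by [read_panel()], at full
#' numeric precision (shortest round-trip representation). Simulation truth
#' is not serialized; keep it separately via [panel_truth()] if needed.
#'
#' @param panel A `trait_panel` or equivalent data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  cols <- c("genotype", "trial", "replicate", "treatment", "trait", "value")
  readr::write_csv(tibble::as_tibble(panel)[, cols], path, progress = FALSE)
  invisible(path)
}
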