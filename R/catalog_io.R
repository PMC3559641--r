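#' @title Catalog and cohort input/output
#'
#' @description
#' Readers and writers for the three tabular formats the package uses:
#' a catalog of published SNP associations (one row per reported
#' association: gene, rsID, source population and sizes, published
#' minor-allele odds ratio), a per-individual cohort table (case/control
#' status plus minor-allele dosage 0/1/2 per SNP and optional quantitative
#' skin-prick-test scores), and generic result tables. All files are
#' tab-separated UTF-8 with a header row.
#'
#' @name catalog_io
NULL

CATALOG_COLUMNS <- c("gene", "snp_id", "polymorphism", "population",
                     "or", "reference")

#' Read a catalog of published SNP associations
#'
#' The catalog is a TSV with columns `gene`, `snp_id`, `polymorphism`,
#' `population`, `or`, `reference` and the source-study sample sizes given
#' either as a single `population_size` column in the printed
#' `"cases; controls"` form (split on `";"`, whitespace tolerated) or as
#' explicit `n_cases` / `n_controls` columns.
#'
#' @param path Path to a tab-separated catalog file.
#' @return A data frame of class `snp_catalog` with one row per published
#'   association and columns `snp_id`, `gene`, `polymorphism`, `population`,
#'   `n_cases`, `n_controls`, `or`, `reference`.
#' @export
#' @examples
#' cat_path <- system.file("extdata", "published_association_catalog.tsv",
#'                         package = "snpreplicate")
#' catalog <- read_snp_catalog(cat_path)
#' nrow(catalog)  # 33 published associations
read_snp_catalog <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("catalog file not found: %s", path))
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(CATALOG_COLUMNS, names(raw))
  if (length(missing_cols)) {
    abort_validation(sprintf("catalog is missing required column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    out <- data.frame(snp_id = character(), gene = character(),
                      polymorphism = character(), population = character(),
                      n_cases = integer(), n_controls = integer(),
                      or = numeric(), reference = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("snp_catalog", class(out))
    return(out)
  }

  if ("population_size" %in% names(raw)) {
    parts <- strsplit(raw$population_size, ";")
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      abort_validation(sprintf(
        "row %d: population_size must be 'cases; controls', got '%s'",
        bad[1L], raw$population_size[bad[1L]]))
    }
    n_cases <- suppressWarnings(as.integer(trimws(vapply(parts, `[`, "", 1L))))
    n_controls <- suppressWarnings(as.integer(trimws(vapply(parts, `[`, "", 2L))))
  } else if (all(c("n_cases", "n_controls") %in% names(raw))) {
    n_cases <- suppressWarnings(as.integer(raw$n_cases))
    n_controls <- suppressWarnings(as.integer(raw$n_controls))
  } else {
    abort_validation(
      "catalog is missing required column(s): population_size (or n_cases + n_controls)")
  }

  or <- suppressWarnings(as.numeric(raw$or))
  for (i in seq_along(or)) {
    if (is.na(or[i]) || or[i] <= 0) {
      abort_validation(sprintf(
        "row %d: odds ratio must be a positive number, got '%s'", i, raw$or[i]))
    }
    if (is.na(n_cases[i]) || n_cases[i] < 1L || is.na(n_controls[i]) ||
        n_controls[i] < 1L) {
      abort_validation(sprintf(
        "row %d: source sample sizes must be positive integers", i))
    }
  }

  out <- data.frame(snp_id = raw$snp_id, gene = raw$gene,
                    polymorphism = raw$polymorphism,
                    population = raw$population,
                    n_cases = n_cases, n_controls = n_controls,
                    or = or, reference = raw$reference,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_catalog", class(out))
  out
}

#' The packaged catalog of 33 published allergic-rhinitis associations
#'
#' Returns the catalog of 33 published candidate-gene associations with
#' allergic rhinitis that the power analysis is built around: for each
#' association the gene, rsID, source population, source-study case/control
#' sizes and the published (or recalculated) minor-allele odds ratio.
#' Published ORs range from 0.16 to 7.75. Three rsIDs (rs2280089, rs2280090,
#' rs187238) appear twice, reported from two different source studies.
#'
#' @return A `snp_catalog` data frame with 33 rows; see
#'   [read_snp_catalog()] for columns.
#' @export
#' @examples
#' catalog <- packaged_catalog()
#' subset(catalog, gene == "ADAM33")
packaged_catalog <- function() {
  path <- system.file("extdata", "published_association_catalog.tsv",
                      package = "snpreplicate")
  read_snp_catalog(path)
}

#' Read a per-individual cohort table
#'
#' Cohort files are TSVs with columns `individual_id`, `status`
#' (`case`/`control`), one column per SNP holding the minor-allele dosage
#' (0, 1, 2 or NA), and optional quantitative skin-prick-test score columns
#' named `spt:<allergen>` (non-negative reals, NA allowed).
#'
#' @param path Path to a tab-separated cohort file.
#' @return A data frame of class `cohort_dataset` with attributes
#'   `snp_ids` and `allergens`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cohort file not found: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("individual_id", "status")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort_validation(sprintf("cohort is missing required column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  spt_cols <- grep("^spt:", names(raw), value = TRUE)
  snp_cols <- setdiff(names(raw), c(required, spt_cols))
  if (length(snp_cols) == 0L) {
    abort_validation("cohort has no SNP dosage columns")
  }
  bad_status <- setdiff(unique(raw$status), c("case", "control"))
  if (length(bad_status)) {
    abort_validation(sprintf("invalid status value(s): %s",
                             paste(bad_status, collapse = ", ")))
  }
  for (sc in snp_cols) {
    v <- raw[[sc]]
    if (!all(is.na(v) | v %in% c(0, 1, 2))) {
      abort_validation(sprintf(
        "column %s: dosages must be 0, 1, 2 or NA", sc))
    }
    raw[[sc]] <- as.integer(v)
  }
  for (ac in spt_cols) {
    v <- raw[[ac]]
    if (!is.numeric(v) || any(v < 0, na.rm = TRUE)) {
      abort_validation(sprintf(
        "column %s: SPT scores must be non-negative reals or NA", ac))
    }
  }
  new_cohort(raw, snp_cols, sub("^spt:", "", spt_cols))
}

new_cohort <- function(df, snp_ids, allergens) {
  structure(df, snp_ids = snp_ids, allergens = allergens,
            class = c("cohort_dataset", "data.frame"))
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("Cohort: %d cases, %d controls, %d SNP(s), %d allergen(s)\n",
              sum(x$status == "case"), sum(x$status == "control"),
              length(attr(x, "snp_ids")), length(attr(x, "allergens"))))
  invisible(x)
}

#' Numbers of cases and controls in a cohort
#' @param cohort A `cohort_dataset`.
#' @return Named integer vector with elements `n_case` and `n_control`.
#' @export
cohort_sizes <- function(cohort) {
  c(n_case = sum(cohort$status == "case"),
    n_control = sum(cohort$status == "control"))
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]; writing then re-reading reproduces the
#' dataset exactly (dosages are integers and SPT scores carry at most three
#' decimals by construction in the simulator).
#'
#' @param cohort A `cohort_dataset`.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA"),
    error = function(e) abort_io(conditionMessage(e)))
  invisible(path)
}

#' Render a numeric value for a result table
#'
#' Four significant figures; values with magnitude below 1e-4 (small
#' P-values) are rendered in scientific notation; NA renders as "NA".
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_result_number <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    if (is.na(xi)) {
      out[i] <- "NA"
    } else if (xi != 0 && abs(xi) < 1e-4) {
      out[i] <- formatC(signif(xi, 4), format = "e", digits = 3)
    } else {
      out[i] <- format(signif(xi, 4), scientific = FALSE, trim = TRUE)
    }
  }
  out
}

#' Write a result table as TSV
#'
#' Columns keep their order; numeric columns are rendered with
#' [format_result_number()] (4 significant figures, scientific notation
#' below 1e-4); missing values are rendered as "NA". An empty table yields
#' a header-only file.
#'
#' @param results A data frame of results.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- format_result_number(df[[nm]])
    }
  }
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA"),
    error = function(e) abort_io(conditionMessage(e)))
  invisible(path)
}
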