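## File formats: RFC-4180 CSV in (lipid matrix, class map, sample metadata),
## TSV out for the report tables. Readers validate aggressively and name the
## offending cells; report writers stamp a provenance comment header.

BINARY_COLS <- c("male", "smoker", "diabetes", "family_history_chd",
                 "statin", "art", "detectable_vl", "cvd_event")

#' Write a cohort to CSV files
#'
#' Writes `lipid_matrix.csv` (rows = samples, first column `sample_id`, one
#' column per species), `class_map.csv` (`species_id`, `class_name`) and
#' `metadata.csv` (sample metadata, snake_case columns), all RFC-4180.
#' Concentrations are always written on the raw scale (a `log10`-export
#' cohort is back-transformed first), so the CSV schema is unambiguous.
#'
#' @param cohort A `lipid_cohort` (or compatible list).
#' @param dir Output directory (created if needed).
#' @return Named paths of the three files, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "lipid_matrix.csv"),
             class_map = file.path(dir, "class_map.csv"),
             metadata = file.path(dir, "metadata.csv"))
  parts <- as_cohort_parts(cohort)
  readr::write_csv(parts$lipids, paths[["matrix"]])
  readr::write_csv(cohort$class_map, paths[["class_map"]])
  readr::write_csv(cohort$samples, paths[["metadata"]])
  invisible(paths)
}

#' Read and validate a lipid concentration matrix with its class map
#'
#' @param matrix_csv CSV with header: `sample_id` then one column per lipid
#'   species; values must be finite and nonnegative.
#' @param classmap_csv CSV with header `species_id,class_name` covering every
#'   species column of the matrix.
#' @return List with tibbles `lipids` and `class_map`.
#' @export
read_lipid_matrix <- function(matrix_csv, classmap_csv) {
  lipids <- readr::read_csv(matrix_csv, show_col_types = FALSE,
                            progress = FALSE)
  if (!"sample_id" %in% names(lipids)) {
    abort("lipid matrix must have a 'sample_id' first column")
  }
  dup <- lipids$sample_id[duplicated(lipids$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample_id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  sp <- setdiff(names(lipids), "sample_id")
  if (length(sp) == 0) abort("lipid matrix has no species columns")
  for (cn in sp) {
    v <- lipids[[cn]]
    if (!is.numeric(v)) abort(sprintf("species column '%s' is not numeric", cn))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(sprintf("invalid concentration (negative/NaN) at row %d, column '%s'",
                    bad[1], cn))
    }
  }
  class_map <- readr::read_csv(classmap_csv, show_col_types = FALSE,
                               progress = FALSE)
  if (!all(c("species_id", "class_name") %in% names(class_map))) {
    abort("class map must have columns 'species_id' and 'class_name'")
  }
  unmapped <- setdiff(sp, class_map$species_id)
  if (length(unmapped) > 0) {
    abort(sprintf("species without a class: %s",
                  paste(head(unmapped, 10), collapse = ", ")))
  }
  list(lipids = lipids, class_map = class_map[class_map$species_id %in% sp, ])
}

#' Read and validate sample metadata
#'
#' @param metadata_csv CSV with snake_case columns including `sample_id` and
#'   `group` (one of `HIV_CASE`, `HIV_CONTROL`, `HEALTHY`); binary columns
#'   must contain only 0/1.
#' @return A typed samples tibble.
#' @export
read_metadata <- function(metadata_csv) {
  samples <- readr::read_csv(metadata_csv, show_col_types = FALSE,
                             progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("metadata must have 'sample_id' and 'group' columns")
  }
  bad_group <- setdiff(unique(samples$group), GROUPS)
  if (length(bad_group) > 0) {
    abort(sprintf("unknown group label(s): %s (expected %s)",
                  paste(bad_group, collapse = ", "),
                  paste(GROUPS, collapse = ", ")))
  }
  for (cn in intersect(BINARY_COLS, names(samples))) {
    v <- samples[[cn]]
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad) > 0) {
      abort(sprintf("binary column '%s' has non-0/1 value at row %d",
                    cn, bad[1]))
    }
  }
  num_cols <- setdiff(names(samples), c("sample_id", "group"))
  for (cn in num_cols) {
    if (any(!is.finite(samples[[cn]]))) {
      abort(sprintf("non-finite value in column '%s'", cn))
    }
  }
  samples
}

#' Read a cohort previously written with [write_cohort()]
#'
#' Assembles the lipid matrix, class map and metadata, checking that the
#' sample sets agree.
#'
#' @param dir Directory containing `lipid_matrix.csv`, `class_map.csv`,
#'   `metadata.csv`.
#' @return A `lipid_cohort`-compatible list (`lipids`, `samples`,
#'   `class_map`).
#' @export
read_cohort <- function(dir) {
  mat <- read_lipid_matrix(file.path(dir, "lipid_matrix.csv"),
                           file.path(dir, "class_map.csv"))
  samples <- read_metadata(file.path(dir, "metadata.csv"))
  only_mat <- setdiff(mat$lipids$sample_id, samples$sample_id)
  only_meta <- setdiff(samples$sample_id, mat$lipids$sample_id)
  if (length(only_mat) > 0 || length(only_meta) > 0) {
    abort(sprintf(
      "sample sets disagree; in matrix only: %s; in metadata only: %s",
      paste(head(only_mat, 5), collapse = ", "),
      paste(head(only_meta, 5), collapse = ", ")))
  }
  samples <- samples[match(mat$lipids$sample_id, samples$sample_id), ]
  structure(list(lipids = mat$lipids, samples = samples,
                 class_map = mat$class_map),
            class = "lipid_cohort")
}

## provenance-stamped TSV writer used by the pipeline stages
write_report_tsv <- function(df, path, seed, config_hash) {
  header <- sprintf("# lipidcvd %s | seed=%s | config_hash=%s",
                    as.character(packageVersion("lipidcvd")),
                    seed, config_hash)
  writeLines(header, path)
  suppressWarnings(
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

read_report_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
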