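## End-to-end pipeline: simulate -> associate -> crossval -> risk -> report.
## Each stage reads its inputs from (and writes its artifacts to) a working
## directory, so stages can be rerun independently; randomness in each stage
## comes from a labelled sub-stream of the one global seed.

#' Configure an end-to-end pipeline run
#'
#' @param seed Global seed; each stage draws from a labelled sub-stream of it
#'   (see [substream_seed()]), so stages rerun independently yet
#'   reproducibly.
#' @param generator List of arguments for [generator_config()] (the
#'   `simulate` stage); ignored when an existing cohort directory is
#'   analysed.
#' @param analysis_scale `"log10"` or `"raw"` for the association scans.
#' @param cv List of arguments for [cv_config()].
#' @param feature_set `"species"`, `"conventional"` or `"combined"`.
#' @param sizes Candidate model sizes for the size search (default
#'   `1..max_features`).
#' @param size_repeats Repeats used during the model-size search.
#' @param equations Character vector of risk-equation YAML paths for the
#'   `risk` stage (default: none).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, generator = list(),
                            analysis_scale = c("log10", "raw"),
                            cv = list(), feature_set = "species",
                            sizes = NULL, size_repeats = 20,
                            equations = character()) {
  analysis_scale <- match.arg(analysis_scale)
  structure(list(seed = as.integer(seed), generator = generator,
                 analysis_scale = analysis_scale, cv = cv,
                 feature_set = feature_set, sizes = sizes,
                 size_repeats = size_repeats, equations = equations),
            class = "pipeline_config")
}

config_hash <- function(config) rlang::hash(config)

#' Run pipeline stages
#'
#' `run_pipeline()` executes the requested stages in order against a working
#' directory:
#' \describe{
#'   \item{simulate}{generate a synthetic cohort and write the three CSVs;}
#'   \item{associate}{cohort characteristics table plus species- and
#'     class-level association scans for the two design contrasts
#'     (HIV control vs healthy adjusted for family history of CHD, smoking
#'     and hsCRP; HIV case vs HIV control adjusted for statin treatment);}
#'   \item{crossval}{model-size search, full repeated-CV harness at the
#'     chosen size, per-trial audit table and inclusion frequencies;}
#'   \item{risk}{per-equation 10-year risks and C-statistics for the
#'     case-vs-control outcome;}
#'   \item{report}{one combined plain-text summary.}
#' }
#' All TSV artifacts carry a `# lipidcvd <version> | seed | config_hash`
#' comment header and are byte-identical under a fixed seed.
#'
#' @param out_dir Working/output directory.
#' @param config A [pipeline_config()].
#' @param stages Subset of `c("simulate", "associate", "crossval", "risk",
#'   "report")`, in order.
#' @return Invisibly, a named list of artifact paths.
#' @export
#' @examples
#' \donttest{
#' dir <- tempfile()
#' cfg <- pipeline_config(seed = 1, cv = list(repeats = 5, max_features = 5),
#'                        sizes = c(2, 4))
#' run_pipeline(dir, cfg, stages = c("simulate", "crossval"))
#' }
run_pipeline <- function(out_dir, config = pipeline_config(),
                         stages = c("simulate", "associate", "crossval",
                                    "risk", "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  paths <- list()
  log_lines <- c(sprintf("lipidcvd %s", as.character(packageVersion("lipidcvd"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", hash),
                 sprintf("stages: %s", paste(stages, collapse = ", ")))

  if ("simulate" %in% stages) {
    gen_args <- config$generator
    gen_args$seed <- substream_seed(config$seed, "simulate")
    gcfg <- do.call(generator_config, gen_args)
    cohort <- generate_cohort(gcfg)
    paths$cohort <- write_cohort(cohort, out_dir)
    log_lines <- c(log_lines,
                   sprintf("simulate: %d samples x %d species",
                           nrow(cohort$lipids), nrow(cohort$class_map)))
  }

  needs_cohort <- any(c("associate", "crossval", "risk", "report") %in% stages)
  cohort <- if (needs_cohort) read_cohort(out_dir)

  if ("associate" %in% stages) {
    tab <- cohort_table(cohort$samples)
    paths$cohort_table <- write_report_tsv(tab,
      file.path(out_dir, "cohort_table.tsv"), config$seed, hash)
    contrasts <- list(
      contrast_spec("HIV_CONTROL", "HEALTHY",
                    adjust = c("family_history_chd", "smoker", "hscrp")),
      contrast_spec("HIV_CASE", "HIV_CONTROL", adjust = "statin"))
    for (ct in contrasts) {
      for (lv in c("class", "species")) {
        scan <- suppressWarnings(
          association_scan(cohort, ct, level = lv,
                           analysis_scale = config$analysis_scale))
        fname <- sprintf("association_%s_%s.tsv", tolower(ct$label), lv)
        paths[[paste0("assoc_", ct$label, "_", lv)]] <-
          write_report_tsv(as_tibble(scan), file.path(out_dir, fname),
                           config$seed, hash)
      }
    }
  }

  if ("crossval" %in% stages) {
    cv_args <- config$cv
    cv_args$seed <- substream_seed(config$seed, "crossval")
    ccfg <- do.call(cv_config, cv_args)
    fm <- cv_features(cohort, config$feature_set)
    rep_obj <- cv_report(fm$x, fm$y, ccfg, sizes = config$sizes,
                         size_repeats = config$size_repeats)
    paths$cv_summary <- write_report_tsv(
      mutate(rep_obj$summary,
             display = ifelse(.data$metric == "auc",
                              sprintf("%.3f (%.3f, %.3f)", .data$mean,
                                      .data$ci95_low, .data$ci95_high),
                              sprintf("%.1f (%.1f, %.1f)", .data$mean,
                                      .data$ci95_low, .data$ci95_high))),
      file.path(out_dir, "cv_summary.tsv"), config$seed, hash)
    paths$auc_vs_size <- write_report_tsv(rep_obj$curve,
      file.path(out_dir, "auc_vs_size.tsv"), config$seed, hash)
    paths$inclusion <- write_report_tsv(rep_obj$inclusion,
      file.path(out_dir, "inclusion.tsv"), config$seed, hash)
    audit <- mutate(as_tibble(rep_obj$trials),
                    selected_features = purrr::map_chr(.data$selected_features,
                                                       paste, collapse = ";"))
    paths$trials <- write_report_tsv(audit,
      file.path(out_dir, "cv_trials.tsv"), config$seed, hash)
    log_lines <- c(log_lines,
                   sprintf("crossval: %d trials, n* = %d features",
                           nrow(rep_obj$trials), rep_obj$n_star))
  }

  if ("risk" %in% stages && length(config$equations) > 0) {
    hiv <- cohort$samples[cohort$samples$group %in%
                            c("HIV_CASE", "HIV_CONTROL"), , drop = FALSE]
    for (eq_path in config$equations) {
      eq <- read_risk_equation(eq_path)
      sc <- score_cohort(eq, hiv)
      out <- sc$risks
      out$equation <- eq$name
      out$c_statistic <- sc$auc
      fname <- sprintf("risk_%s.tsv", gsub("[^A-Za-z0-9]+", "_", eq$name))
      paths[[paste0("risk_", eq$name)]] <- write_report_tsv(out,
        file.path(out_dir, fname), config$seed, hash)
      log_lines <- c(log_lines,
                     sprintf("risk: %s C-statistic %.3f (n=%d)",
                             eq$name, sc$auc, sc$n_used))
    }
  }

  if ("report" %in% stages) {
    paths$report <- write_text_report(out_dir, config, hash)
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths$log <- file.path(out_dir, "run_log.txt")
  invisible(paths)
}

## plain-text roll-up of whatever stage artifacts exist in out_dir
write_text_report <- function(out_dir, config, hash) {
  path <- file.path(out_dir, "report.txt")
  lines <- c(sprintf("lipidcvd %s combined report",
                     as.character(packageVersion("lipidcvd"))),
             sprintf("seed=%d config_hash=%s", config$seed, hash), "")
  cv_path <- file.path(out_dir, "cv_summary.tsv")
  if (file.exists(cv_path)) {
    cv <- read_report_tsv(cv_path)
    lines <- c(lines, "Cross-validated performance (mean, 95% CI):",
               sprintf("  %-12s %s", cv$metric, cv$display), "")
  }
  for (lv in c("class", "species")) {
    for (f in list.files(out_dir, sprintf("^association_.*_%s\\.tsv$", lv),
                         full.names = TRUE)) {
      a <- read_report_tsv(f)
      nsig <- sum(a$p_adj < 0.05, na.rm = TRUE)
      lines <- c(lines,
                 sprintf("%s: %d/%d %s features with adjusted p < 0.05",
                         basename(f), nsig, nrow(a), lv))
    }
  }
  risk_files <- list.files(out_dir, "^risk_.*\\.tsv$", full.names = TRUE)
  for (f in risk_files) {
    r <- read_report_tsv(f)
    lines <- c(lines, sprintf("%s: C-statistic %.3f",
                              r$equation[1], r$c_statistic[1]))
  }
  writeLines(lines, path)
  path
}
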