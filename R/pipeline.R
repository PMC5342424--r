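#' End-to-end radiogenomic biomarker discovery pipeline
#'
#' Runs the full analysis on a (synthetic or user-supplied) cohort:
#' differential-expression screening between PsP and TTP, the longitudinal
#' sparse-regression stability grid, coverage-rate candidate selection, and
#' validation of the candidates on an independent cohort.
#'
#' The expression panel of the cohort is treated as an already screened
#' differential panel (as in the study design the synthetic generator
#' emulates, where a genome-wide screen precedes the regression), so the
#' regression grid runs on all genes of `Y`; the screening step is reported
#' alongside.  When `cohort` carries planted active genes, the overlap of
#' the selected candidates with the planted set is scored with a
#' hypergeometric enrichment test.
#'
#' @param cohort a `synthetic_cohort` (or any list with elements `X`, `Y`,
#'   `labels`, optionally `active_genes` and `config`).  If `NULL`, a cohort
#'   is generated from `config`.
#' @param config a [simulation_config()] used when `cohort` is `NULL` and to
#'   generate the validation cohort.
#' @param grid a [grid_spec()] for the stability runs.
#' @param coverage_P coverage rate for candidate selection (default 0.8).
#' @param screen_alpha screening threshold (default 0.005).
#' @param validate run validation on an independently generated cohort
#'   (requires `config`).
#' @param verbose print progress.
#' @return An object of class `psp_pipeline`: list with `screen`
#'   (`screen_result`), `coverage` (`coverage_table`), `candidates`,
#'   `validation` (`validation_report` or `NULL`), and, when planted truth
#'   is available, `enrichment` (list with `overlap`, `p_value`).
#' @export
run_psp_pipeline <- function(cohort = NULL, config = simulation_config(),
                             grid = grid_spec(), coverage_P = 0.8,
                             screen_alpha = 0.005, validate = TRUE,
                             verbose = FALSE) {
  if (is.null(cohort)) cohort <- generate_dataset(config)
  if (!is.null(cohort$config)) config <- cohort$config
  scr <- wilcoxon_screen(cohort$Y, cohort$labels, alpha = screen_alpha)
  if (verbose) print(scr)
  cov <- run_grid(cohort$X, cohort$Y, grid, verbose = verbose)
  candidates <- coverage_select(cov, coverage_P)
  enrichment <- NULL
  if (length(cohort$active_genes)) {
    planted <- colnames(cohort$Y)[cohort$active_genes]
    overlap <- length(intersect(candidates, planted))
    # P(overlap >= observed) drawing |candidates| genes from the panel
    p <- phyper(overlap - 1, length(planted),
                ncol(cohort$Y) - length(planted), length(candidates),
                lower.tail = FALSE)
    enrichment <- list(planted = planted, overlap = overlap, p_value = p)
  }
  val <- NULL
  if (validate && length(candidates)) {
    vc <- generate_validation_cohort(config, candidates)
    val <- validate_biomarkers(vc$Y, vc$labels, candidates)
  }
  structure(list(screen = scr, coverage = cov, candidates = candidates,
                 validation = val, enrichment = enrichment,
                 coverage_P = coverage_P, grid = grid),
            class = "psp_pipeline")
}

#' @export
print.psp_pipeline <- function(x, ...) {
  cat("Radiogenomic PsP/TTP biomarker pipeline\n")
  cat(sprintf("  screening: %d genes at p < %g\n",
              length(x$screen$retained), x$screen$alpha))
  cat(sprintf("  stability grid: %d runs; %d candidate gene(s) at P >= %g\n",
              attr(x$coverage, "n_runs"), length(x$candidates),
              x$coverage_P))
  if (length(x$candidates))
    cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  if (!is.null(x$enrichment))
    cat(sprintf("  planted-gene enrichment: %d / %d recovered, hypergeometric p = %.3g\n",
                x$enrichment$overlap, length(x$enrichment$planted),
                x$enrichment$p_value))
  if (!is.null(x$validation)) {
    up <- sum(x$validation$direction == "higher-in-PsP" &
                x$validation$significant)
    cat(sprintf("  validation: %d / %d candidates significantly higher in PsP\n",
                up, nrow(x$validation)))
  }
  invisible(x)
}
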