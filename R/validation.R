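#' Validate biomarkers on an independent cohort
#'
#' Tests each chosen biomarker gene for a PsP-versus-TTP expression
#' difference in an independent cohort with the same two-sided Wilcoxon
#' rank-sum engine as the screening step, and reports the direction of the
#' difference (by group medians) together with boxplot five-number
#' summaries per group.
#'
#' @param Y samples x genes expression matrix of the independent cohort.
#' @param labels group labels aligned with the rows of `Y` (PsP / TTP).
#' @param biomarkers gene names (matched against `colnames(Y)`) or column
#'   indices of the biomarkers to validate.
#' @param alpha significance threshold for the report (default 0.05).
#' @return An object of class `validation_report`: a data frame with one
#'   row per biomarker (`gene`, `p_value`, `direction`, `significant`,
#'   group medians and means) plus attributes `boxplot_stats` (named list
#'   of per-group five-number summaries) and `alpha`.
#' @export
validate_biomarkers <- function(Y, labels, biomarkers, alpha = 0.05) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- gene_names(ncol(Y))
  labels <- as.factor(labels)
  if (length(labels) != nrow(Y))
    stop("'labels' must have one entry per row of Y")
  lev <- levels(droplevels(labels))
  if (length(lev) != 2L) stop("exactly two groups are required")
  g1 <- if ("PsP" %in% lev) "PsP" else lev[1]
  g2 <- setdiff(lev, g1)
  i1 <- which(labels == g1); i2 <- which(labels == g2)
  if (!length(i1)) stop(sprintf("group '%s' is empty", g1))
  if (!length(i2)) stop(sprintf("group '%s' is empty", g2))
  if (is.character(biomarkers)) {
    missing <- setdiff(biomarkers, colnames(Y))
    if (length(missing))
      stop("biomarker gene(s) absent from the cohort: ",
           paste(missing, collapse = ", "))
    cols <- match(biomarkers, colnames(Y))
  } else {
    cols <- as.integer(biomarkers)
    if (any(cols < 1L | cols > ncol(Y)))
      stop("biomarker indices out of range")
  }
  if (!length(cols)) stop("no biomarkers supplied")
  rows <- lapply(cols, function(j) {
    p <- wilcoxon_p(Y[i1, j], Y[i2, j])
    m1 <- median(Y[i1, j]); m2 <- median(Y[i2, j])
    data.frame(gene = colnames(Y)[j], p_value = p,
               direction = if (m1 > m2) paste0("higher-in-", g1)
                           else if (m1 < m2) paste0("higher-in-", g2)
                           else "none",
               significant = p < alpha,
               median_psp = m1, median_ttp = m2,
               mean_psp = mean(Y[i1, j]), mean_ttp = mean(Y[i2, j]),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  bx <- lapply(cols, function(j)
    list(PsP = fivenum(Y[i1, j]), TTP = fivenum(Y[i2, j])))
  names(bx) <- colnames(Y)[cols]
  structure(rep, class = c("validation_report", "data.frame"),
            boxplot_stats = bx, alpha = alpha,
            groups = setNames(c(length(i1), length(i2)), c(g1, g2)))
}

#' @export
print.validation_report <- function(x, ...) {
  grp <- attr(x, "groups")
  cat(sprintf("Biomarker validation (%d vs %d samples, alpha = %g)\n",
              grp[1], grp[2], attr(x, "alpha")))
  print.data.frame(as.data.frame(x)[, c("gene", "p_value", "direction",
                                        "significant")], digits = 4)
  invisible(x)
}

#' Boxplot of biomarker expression by group
#'
#' A small plotting helper for a [validate_biomarkers()] report: side-by-side
#' group boxplots of each biomarker's expression.
#'
#' @param Y,labels the cohort used for validation.
#' @param biomarkers gene names or indices to plot.
#' @param ... passed to [graphics::boxplot()].
#' @return Invisibly, the boxplot statistics.
#' @export
plot_biomarker_expression <- function(Y, labels, biomarkers, ...) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- gene_names(ncol(Y))
  if (is.character(biomarkers)) cols <- match(biomarkers, colnames(Y))
  else cols <- as.integer(biomarkers)
  labels <- as.factor(labels)
  vals <- as.vector(Y[, cols, drop = FALSE])
  gene <- rep(colnames(Y)[cols], each = nrow(Y))
  grp <- rep(labels, times = length(cols))
  invisible(graphics::boxplot(vals ~ interaction(grp, gene),
                              ylab = "expression", las = 2, ...))
}
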