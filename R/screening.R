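#' Two-sided Wilcoxon rank-sum p-value
#'
#' The shared test engine of the screening and validation modules.  Uses the
#' exact null distribution of the rank-sum statistic when the smaller group
#' has at most 12 samples and the data carry no ties; otherwise the normal
#' approximation with mid-ranks, tie-corrected variance and continuity
#' correction.  No multiple-testing adjustment is applied here.
#'
#' @param x,y numeric vectors of the two groups (each of length >= 1).
#' @return The two-sided p-value in (0, 1].
#' @export
wilcoxon_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  v <- c(x, y)
  if (any(!is.finite(v))) stop("non-finite expression values")
  r <- rank(v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(v) > 0L
  if (!ties && min(n1, n2) <= 12L) {
    p <- if (U > n1 * n2 / 2)
      pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else
      pwilcox(U, n1, n2)
    return(min(2 * p, 1))
  }
  z <- U - n1 * n2 / 2
  nties <- table(r)
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(1)  # all values identical
  zc <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(2 * min(pnorm(zc), pnorm(zc, lower.tail = FALSE)), 1)
}

#' Screen differentially expressed genes between PsP and TTP
#'
#' Applies a two-sided Wilcoxon rank-sum test to every gene and flags genes
#' with `p < alpha` (raw p-values; the screening threshold is applied without
#' multiple-testing correction, with an optional Benjamini-Hochberg mode).
#'
#' @param Y samples x genes expression matrix.
#' @param labels factor or character vector of group labels aligned with the
#'   rows of `Y`; the first factor level (or `"PsP"` when present) is treated
#'   as the PsP group.
#' @param alpha screening threshold on the (possibly adjusted) p-value
#'   (default 0.005).
#' @param adjust `"none"` (default) for raw p-values or `"BH"` for
#'   Benjamini-Hochberg adjusted ones.
#' @return An object of class `screen_result`: a list with `table` (data
#'   frame of gene, p_value, direction, pass), `retained` (passing gene
#'   names sorted by p ascending), `alpha` and the group sizes.
#' @export
wilcoxon_screen <- function(Y, labels, alpha = 0.005,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- gene_names(ncol(Y))
  labels <- as.factor(labels)
  if (length(labels) != nrow(Y))
    stop("'labels' must have one entry per row of Y")
  if (nlevels(droplevels(labels)) != 2L)
    stop("exactly two groups are required")
  lev <- levels(droplevels(labels))
  g1 <- if ("PsP" %in% lev) "PsP" else lev[1]
  g2 <- setdiff(lev, g1)
  i1 <- which(labels == g1); i2 <- which(labels == g2)
  for (nm in c(g1, g2))
    if (!sum(labels == nm)) stop(sprintf("group '%s' is empty", nm))
  if (length(i1) < 2L || length(i2) < 2L)
    stop("both groups need at least 2 samples")
  p <- vapply(seq_len(ncol(Y)),
              function(j) wilcoxon_p(Y[i1, j], Y[i2, j]), numeric(1))
  med_diff <- vapply(seq_len(ncol(Y)),
                     function(j) median(Y[i1, j]) - median(Y[i2, j]),
                     numeric(1))
  p_use <- if (adjust == "BH") p.adjust(p, "BH") else p
  pass <- p_use < alpha
  tab <- data.frame(gene = colnames(Y), p_value = p,
                    p_adjusted = if (adjust == "BH") p_use else NA_real_,
                    direction = ifelse(med_diff > 0, paste0("higher-in-", g1),
                                       ifelse(med_diff < 0,
                                              paste0("higher-in-", g2),
                                              "none")),
                    pass = pass, stringsAsFactors = FALSE)
  retained <- tab$gene[pass][order(p_use[pass])]
  structure(list(table = tab, retained = retained, alpha = alpha,
                 adjust = adjust, groups = setNames(c(length(i1), length(i2)),
                                                    c(g1, g2))),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum screen (%s): %d / %d genes with p < %g (%d vs %d samples)\n",
    if (x$adjust == "none") "raw p" else "BH-adjusted p",
    length(x$retained), nrow(x$table), x$alpha,
    x$groups[1], x$groups[2]))
  if (length(x$retained))
    cat("  retained:", paste(head(x$retained, 10), collapse = ", "),
        if (length(x$retained) > 10) "..." else "", "\n")
  invisible(x)
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Clusters genes (or samples) with UPGMA (average linkage) on the
#' dissimilarity `1 - Pearson correlation`, the arrangement used for
#' expression heatmaps of screened genes.
#'
#' @param Y samples x genes expression matrix.
#' @param what `"genes"` (default) clusters the columns of `Y` across
#'   samples; `"samples"` clusters the rows across genes.
#' @return An object of class `cluster_result`: list with the `hclust`
#'   object (`tree`), `merge`, `height`, `order`, `labels` and a Newick
#'   string (`newick`).
#' @export
hierarchical_cluster <- function(Y, what = c("genes", "samples")) {
  what <- match.arg(what)
  Y <- as.matrix(Y)
  M <- if (what == "genes") Y else t(Y)
  if (is.null(colnames(M)))
    colnames(M) <- paste0(substr(what, 1, 1), seq_len(ncol(M)))
  if (ncol(M) < 2L) stop("need at least 2 items to cluster")
  v <- apply(M, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance ", what, ": ",
         paste(colnames(M)[v == 0], collapse = ", "))
  D <- 1 - cor(M)
  hc <- hclust(as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)
  structure(list(tree = hc, merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels,
                 newick = ape::write.tree(phy)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("UPGMA clustering of %d items on 1 - Pearson correlation\n",
              length(x$labels)))
  cat(sprintf("  merge heights: %.3g .. %.3g\n", min(x$height),
              max(x$height)))
  invisible(x)
}
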