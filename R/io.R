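#' Read and write cohorts as plain-text tables
#'
#' A cohort is stored as one TSV per imaging time point (`X_t1.tsv`, ...,
#' samples x features with a `sample_id` column), an expression TSV
#' (`Y.tsv`, samples x genes), a label CSV (`labels.csv` with columns
#' `sample_id,group`) and, when ground truth is present, the unfolded
#' coefficient tensor (`W_true_unfolded.tsv`) plus a JSON sidecar with the
#' generating configuration.
#'
#' @param cohort a `synthetic_cohort` (or compatible list).
#' @param dir output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   `synthetic_cohort`-shaped list (without planted metadata beyond
#'   `W_true` when stored).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- cohort$X
  T_ <- dim(X)[3]
  for (t in seq_len(T_)) {
    df <- data.frame(sample_id = rownames(X[, , t]), X[, , t],
                     check.names = FALSE)
    write.table(df, file.path(dir, sprintf("X_%s.tsv", dimnames(X)[[3]][t])),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(sample_id = rownames(cohort$Y), cohort$Y,
                         check.names = FALSE),
              file.path(dir, "Y.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(data.frame(sample_id = rownames(cohort$Y),
                       group = as.character(cohort$labels)),
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$W_true)) {
    W1 <- unfold_coefficients(cohort$W_true)
    write.table(data.frame(feature = rownames(W1), W1, check.names = FALSE),
                file.path(dir, "W_true_unfolded.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$config))
    jsonlite::write_json(unclass(cohort$config),
                         file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  xfiles <- sort(list.files(dir, pattern = "^X_.*\\.tsv$",
                            full.names = TRUE))
  if (!length(xfiles)) stop("no X_*.tsv time-point tables found in ", dir)
  mats <- lapply(xfiles, function(f) {
    df <- read.delim(f, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  })
  X <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)),
             dimnames = list(rownames(mats[[1]]), colnames(mats[[1]]),
                             sub("^X_(.*)\\.tsv$", "\\1", basename(xfiles))))
  ydf <- read.delim(file.path(dir, "Y.tsv"), check.names = FALSE)
  Y <- as.matrix(ydf[, -1, drop = FALSE])
  rownames(Y) <- ydf[[1]]
  lab <- read.csv(file.path(dir, "labels.csv"))
  labels <- factor(lab$group[match(rownames(Y), lab$sample_id)],
                   levels = c("PsP", "TTP"))
  W_true <- NULL
  wpath <- file.path(dir, "W_true_unfolded.tsv")
  if (file.exists(wpath)) {
    wdf <- read.delim(wpath, check.names = FALSE)
    W1 <- as.matrix(wdf[, -1, drop = FALSE])
    T_ <- dim(X)[3]
    W_true <- array(W1, dim = c(nrow(W1), ncol(W1) / T_, T_))
    dimnames(W_true) <- list(wdf[[1]], colnames(Y), dimnames(X)[[3]])
  }
  structure(list(X = X, Y = Y, labels = labels, W_true = W_true,
                 active_genes = integer(0), active_features = list(),
                 config = NULL),
            class = "synthetic_cohort")
}

#' Write solver outputs as plain-text tables
#'
#' Writes the fitted coefficient tensor (one TSV per time point plus the
#' unfolded matrix), the overall weight map and the objective trace.
#'
#' @param fit a [fit_longreg()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "longreg_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  W <- fit$W
  for (t in seq_len(dim(W)[3])) {
    tn <- dimnames(W)[[3]][t]
    if (is.null(tn)) tn <- paste0("t", t)
    write.table(data.frame(feature = dimnames(W)[[1]], W[, , t],
                           check.names = FALSE),
                file.path(dir, sprintf("W_%s.tsv", tn)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  W1 <- unfold_coefficients(W)
  write.table(data.frame(feature = rownames(W1), W1, check.names = FALSE),
              file.path(dir, "W_unfolded.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  wm <- overall_weights(fit)
  write.table(data.frame(time = rownames(wm$W_prime), wm$W_prime,
                         check.names = FALSE),
              file.path(dir, "weight_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(data.frame(sweep = seq_along(fit$objective) - 1L,
                       objective = fit$objective),
            file.path(dir, "objective_trace.csv"), row.names = FALSE)
  invisible(dir)
}
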