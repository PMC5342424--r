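#' Simulation configuration for synthetic radiogenomic cohorts
#'
#' Bundles all knobs of the synthetic-cohort generator.  The defaults mirror
#' the discovery-cohort geometry of the study design this package implements:
#' 17 samples (5 pseudoprogression / 12 true progression), 225 imaging
#' features observed at 4 MRI time points, and an expression panel of 119
#' genes (the panel is generated on the scale of an already screened
#' differential-expression panel, not a whole transcriptome).
#'
#' The planted association is sparse, temporally smooth and low-rank: a small
#' set of `n_active_genes` gene columns load on `coeff_rank` latent
#' components, each supported on `n_active_features_per_gene` imaging
#' features, so that the unfolded coefficient matrix has rank at most
#' `coeff_rank` and per-gene feature supports are identical across time up to
#' Gaussian jitter of the per-time loadings.
#'
#' @param n_samples number of discovery samples.
#' @param n_psp number of pseudoprogression (PsP) samples; the remaining
#'   samples are labeled TTP (true tumor progression).
#' @param n_features number of imaging features `d` per time point.
#' @param n_genes number of genes `c` in the expression panel.
#' @param n_timepoints number of longitudinal imaging time points `T`.
#' @param n_active_genes number of genes carrying a planted imaging
#'   association and group effect.
#' @param n_active_features_per_gene size of each active gene's imaging
#'   feature support.
#' @param effect_size standardized PsP-minus-TTP mean shift added to active
#'   gene columns (expression units; active columns have total standard
#'   deviation near `sqrt(0.25 + noise_sd^2)`).
#' @param temporal_jitter standard deviation of the relative perturbation of
#'   per-time-point coefficient loadings (0 forces coefficients constant in
#'   time).
#' @param coeff_rank target rank of the planted unfolded coefficient matrix.
#' @param noise_sd standard deviation of the additive expression noise.
#' @param seed integer seed; all generator functions are deterministic given
#'   the configuration.
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [small_profile()] for a fast test-scale configuration,
#'   [generate_dataset()], [generate_coefficients()].
#' @export
simulation_config <- function(n_samples = 17L, n_psp = 5L,
                              n_features = 225L, n_genes = 119L,
                              n_timepoints = 4L,
                              n_active_genes = 12L,
                              n_active_features_per_gene = 10L,
                              effect_size = 2, temporal_jitter = 0.05,
                              coeff_rank = 5L, noise_sd = 0.5,
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_psp = as.integer(n_psp),
              n_features = as.integer(n_features),
              n_genes = as.integer(n_genes),
              n_timepoints = as.integer(n_timepoints),
              n_active_genes = as.integer(n_active_genes),
              n_active_features_per_gene = as.integer(n_active_features_per_gene),
              effect_size = as.numeric(effect_size),
              temporal_jitter = as.numeric(temporal_jitter),
              coeff_rank = as.integer(coeff_rank),
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_samples", "n_psp", "n_features", "n_genes", "n_timepoints")
  for (f in counts)
    if (cfg[[f]] < 1L) stop(sprintf("'%s' must be >= 1", f))
  if (cfg$n_psp >= cfg$n_samples)
    stop("'n_psp' must be smaller than 'n_samples'")
  if (cfg$n_active_genes < 0L || cfg$n_active_genes > cfg$n_genes)
    stop(sprintf("'n_active_genes' (%d) must lie in [0, n_genes = %d]",
                 cfg$n_active_genes, cfg$n_genes))
  if (cfg$n_active_genes > 0L) {
    if (cfg$n_active_features_per_gene < 1L ||
        cfg$n_active_features_per_gene > cfg$n_features)
      stop(sprintf(
        "'n_active_features_per_gene' (%d) must lie in [1, n_features = %d]",
        cfg$n_active_features_per_gene, cfg$n_features))
    rmax <- min(cfg$n_features, cfg$n_genes * cfg$n_timepoints)
    if (cfg$coeff_rank < 1L || cfg$coeff_rank > rmax)
      stop(sprintf("'coeff_rank' (%d) must lie in [1, %d]",
                   cfg$coeff_rank, rmax))
  }
  if (cfg$temporal_jitter < 0) stop("'temporal_jitter' must be >= 0")
  if (cfg$noise_sd < 0) stop("'noise_sd' must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort configuration: %d samples (%d PsP / %d TTP)\n",
    x$n_samples, x$n_psp, x$n_samples - x$n_psp))
  cat(sprintf("  %d imaging features x %d time points, %d genes\n",
              x$n_features, x$n_timepoints, x$n_genes))
  cat(sprintf(
    "  planted: %d active genes, %d features each, rank <= %d, jitter %.3g\n",
    x$n_active_genes, x$n_active_features_per_gene, x$coeff_rank,
    x$temporal_jitter))
  cat(sprintf("  effect size %.3g, noise sd %.3g, seed %d\n",
              x$effect_size, x$noise_sd, x$seed))
  invisible(x)
}

#' Fast small-scale simulation profile
#'
#' A reduced configuration (30 samples, 20 features, 15 genes, 3 time points)
#' with the same planted structure as the default profile, intended for unit
#' tests and quick experiments where the fit is overdetermined (`n > d`).
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [simulation_config()].
#' @return A `sim_config`.
#' @export
small_profile <- function(seed = 1L, ...) {
  args <- list(n_samples = 30L, n_psp = 10L, n_features = 20L,
               n_genes = 15L, n_timepoints = 3L, n_active_genes = 4L,
               n_active_features_per_gene = 4L, coeff_rank = 2L,
               effect_size = 2, temporal_jitter = 0.05, noise_sd = 0.5,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# marginal sd of the planted imaging signal in each active gene column;
# fixed by design so that the default effect size of 2 corresponds to a
# standardized group separation near 2.8 (see the methods vignette)
.signal_sd <- 0.5

#' Generate a planted coefficient tensor
#'
#' Draws the ground-truth regression coefficients `W` (features x genes x
#' time points) used by [generate_dataset()].  Coefficients are built as a
#' factor product `U V_t`: `U` has `coeff_rank` columns, each supported on
#' `n_active_features_per_gene` features, and every active gene is assigned
#' one latent component, so the unfolded matrix `[W_1 ... W_T]` has rank at
#' most `coeff_rank` and exactly `n_active_genes` nonzero gene columns.
#' Per-time loadings are jittered with relative standard deviation
#' `temporal_jitter`; with zero jitter all time slices are identical.
#'
#' @param config a [simulation_config()].
#' @return A numeric array `d x c x T` with attributes `active_genes`
#'   (integer index set) and `active_features` (list of per-gene feature
#'   index sets).
#' @export
generate_coefficients <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  d <- config$n_features; c_ <- config$n_genes; T_ <- config$n_timepoints
  set.seed(config$seed)
  W <- array(0, dim = c(d, c_, T_),
             dimnames = list(feature_names(d), gene_names(c_),
                             time_names(T_)))
  if (config$n_active_genes == 0L) {
    attr(W, "active_genes") <- integer(0)
    attr(W, "active_features") <- list()
    return(W)
  }
  r <- min(config$coeff_rank, config$n_active_genes)
  active <- sort(sample.int(c_, config$n_active_genes))
  comp_of <- rep_len(seq_len(r), config$n_active_genes)
  U <- matrix(0, d, r)
  supports <- vector("list", r)
  for (k in seq_len(r)) {
    supports[[k]] <- sort(sample.int(d, config$n_active_features_per_gene))
    u <- runif(config$n_active_features_per_gene, 0.5, 1.5) *
      sample(c(-1, 1), config$n_active_features_per_gene, replace = TRUE)
    U[supports[[k]], k] <- u / sqrt(sum(u^2))
  }
  base_loading <- .signal_sd * sqrt(T_)
  for (t in seq_len(T_)) {
    V <- matrix(0, r, c_)
    load_t <- base_loading *
      (1 + rnorm(config$n_active_genes, sd = config$temporal_jitter))
    V[cbind(comp_of, active)] <- load_t
    W[, , t] <- U %*% V
  }
  attr(W, "active_genes") <- active
  attr(W, "active_features") <- setNames(supports[comp_of],
                                         gene_names(c_)[active])
  W
}

feature_names <- function(d) sprintf("f%03d", seq_len(d))
gene_names <- function(c_) sprintf("g%03d", seq_len(c_))
time_names <- function(T_) sprintf("t%d", seq_len(T_))
sample_names <- function(n) sprintf("s%02d", seq_len(n))

#' Generate a synthetic discovery cohort
#'
#' Draws a full synthetic radiogenomic cohort: a standardized longitudinal
#' imaging-feature tensor `X` (samples x features x time points), an
#' expression matrix `Y` (samples x genes) and PsP/TTP group labels.  The
#' expression is generated as the time average of the per-time-point linear
#' predictors plus an additive PsP group shift on active gene columns and
#' Gaussian noise:
#'
#'   `Y = (1/T) sum_t X_t W_t + effect_size * 1(PsP) on active genes + noise`
#'
#' Every feature column of `X` is standardized to zero mean and unit standard
#' deviation at every time point.  The first `n_psp` samples are the PsP
#' group.
#'
#' @param config a [simulation_config()].
#' @return An object of class `synthetic_cohort`: a list with elements `X`
#'   (n x d x T array), `Y` (n x c matrix), `labels` (factor with levels
#'   `PsP`, `TTP`), `W_true`, `active_genes`, `active_features` and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  W <- generate_coefficients(config)  # seeds the RNG stream
  n <- config$n_samples; d <- config$n_features
  c_ <- config$n_genes; T_ <- config$n_timepoints
  X <- array(rnorm(n * d * T_), dim = c(n, d, T_),
             dimnames = list(sample_names(n), feature_names(d),
                             time_names(T_)))
  for (t in seq_len(T_)) {
    Xt <- X[, , t, drop = FALSE][, , 1]
    X[, , t] <- scale(Xt)
  }
  signal <- matrix(0, n, c_)
  for (t in seq_len(T_)) signal <- signal + X[, , t] %*% W[, , t]
  signal <- signal / T_
  labels <- factor(rep(c("PsP", "TTP"), c(config$n_psp, n - config$n_psp)),
                   levels = c("PsP", "TTP"))
  Y <- signal
  active <- attr(W, "active_genes")
  if (length(active) && config$effect_size != 0)
    Y[labels == "PsP", active] <- Y[labels == "PsP", active] +
      config$effect_size
  if (config$noise_sd > 0)
    Y <- Y + matrix(rnorm(n * c_, sd = config$noise_sd), n, c_)
  dimnames(Y) <- list(sample_names(n), gene_names(c_))
  structure(list(X = X, Y = Y, labels = labels, W_true = W,
                 active_genes = active,
                 active_features = attr(W, "active_features"),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic radiogenomic cohort: %d samples (%d PsP), %d features x %d time points, %d genes\n",
    dim(x$X)[1], sum(x$labels == "PsP"), dim(x$X)[2], dim(x$X)[3],
    ncol(x$Y)))
  if (length(x$active_genes))
    cat("  planted genes:", paste(colnames(x$Y)[x$active_genes],
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Generate an independent validation cohort
#'
#' Draws a fresh cohort emulating an external validation set (default 21
#' samples, 6 PsP / 15 TTP) in which the supplied biomarker gene columns are
#' shifted upward in the PsP group by `config$effect_size` on a unit-variance
#' expression background.  The random stream is decoupled from the discovery
#' cohort by a fixed seed offset, so validation samples are independent draws.
#'
#' @param config a [simulation_config()]; supplies the gene panel, effect
#'   size and seed.
#' @param biomarkers integer indices or gene names of the biomarker columns
#'   to shift.  An empty set raises a warning and returns a null cohort with
#'   no planted shift.
#' @param n_samples,n_psp validation cohort size (defaults 21 and 6).
#' @return A `synthetic_cohort`; `W_true` is zero and `active_genes` holds
#'   the biomarker indices.
#' @export
generate_validation_cohort <- function(config, biomarkers,
                                       n_samples = 21L, n_psp = 6L) {
  stopifnot(inherits(config, "sim_config"))
  c_ <- config$n_genes
  genes <- gene_names(c_)
  if (is.character(biomarkers)) {
    missing <- setdiff(biomarkers, genes)
    if (length(missing))
      stop("unknown biomarker gene(s): ", paste(missing, collapse = ", "))
    biomarkers <- match(biomarkers, genes)
  }
  biomarkers <- as.integer(biomarkers)
  if (length(biomarkers) && (min(biomarkers) < 1L || max(biomarkers) > c_))
    stop("biomarker indices must lie in [1, n_genes]")
  if (!length(biomarkers))
    warning("empty biomarker set: returning a null validation cohort")
  n <- as.integer(n_samples); n_psp <- as.integer(n_psp)
  stopifnot(n_psp >= 1L, n_psp < n)
  set.seed(config$seed + 1000003L)
  d <- config$n_features; T_ <- config$n_timepoints
  X <- array(rnorm(n * d * T_), dim = c(n, d, T_),
             dimnames = list(sample_names(n), feature_names(d),
                             time_names(T_)))
  for (t in seq_len(T_)) X[, , t] <- scale(X[, , t, drop = FALSE][, , 1])
  labels <- factor(rep(c("PsP", "TTP"), c(n_psp, n - n_psp)),
                   levels = c("PsP", "TTP"))
  Y <- matrix(rnorm(n * c_), n, c_, dimnames = list(sample_names(n), genes))
  if (length(biomarkers) && config$effect_size != 0)
    Y[labels == "PsP", biomarkers] <- Y[labels == "PsP", biomarkers] +
      config$effect_size
  W0 <- array(0, dim = c(d, c_, T_),
              dimnames = list(feature_names(d), genes, time_names(T_)))
  structure(list(X = X, Y = Y, labels = labels, W_true = W0,
                 active_genes = biomarkers,
                 active_features = list(), config = config),
            class = "synthetic_cohort")
}
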