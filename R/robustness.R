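# ---------------------------------------------------------------------------
# Sampling-bias robustness (stratified subsample bootstrap at 60-90%) and the
# inventory-completeness audits.
# ---------------------------------------------------------------------------

#' Stratified random sample of units
#'
#' Within each stratum, floor(fraction * n_s) units (at least 1 when the
#' stratum is non-empty) are drawn without replacement.
#'
#' @param units data.frame with a \code{stratum} column (e.g. a
#'   \code{county_table}).
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed (NULL to use the current RNG state, as inside
#'   replicated procedures).
#' @return integer vector of selected row indices.
#' @export
stratified_sample <- function(units, fraction, seed = NULL) {
  if (!("stratum" %in% names(units))) stop("units must have a stratum column")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  strata <- if (is.factor(units$stratum)) levels(units$stratum)
  else unique(units$stratum)
  idx <- integer(0)
  for (st in strata) {
    rows <- which(units$stratum == st)
    if (!length(rows)) stop("empty stratum: ", st)
    m <- max(1L, floor(fraction * length(rows)))
    idx <- c(idx, if (m == length(rows)) rows
             else rows[sample.int(length(rows), m)])
  }
  sort(idx)
}

#' Sampling-bias robustness test
#'
#' For each fraction, runs \code{reps} replicates, each drawing a stratified
#' subsample (without replacement) of that fraction, fitting the Gaussian
#' GLM once and counting which coefficients reach p < alpha; the
#' per-fraction top-k by count is compared with the full-data top-k. The
#' full-data (100 percent) baseline is the step-2 procedure itself:
#' case-resampling bootstrap significance counting
#' (\code{\link{bootstrap_significance}}). A fraction of exactly 1 draws the
#' full dataset in every replicate, so with reps = 1 its top-k equals a
#' single full-data GLM's significance ranking.
#'
#' @param y_resid response.
#' @param X predictor matrix.
#' @param units data.frame with a \code{stratum} column, one row per unit.
#' @param fractions subsample fractions (default 0.6, 0.7, 0.8, 0.9).
#' @param reps replicates per fraction (default 1000).
#' @param alpha significance level (default 0.05).
#' @param k selection size (default 6).
#' @param seed integer master seed.
#' @return object of class \code{robustness_report}: fractions, counts (list
#'   of named vectors per fraction, including "1" for the baseline), top_k
#'   (list per fraction), full_top_k, consistent (flag: every fraction's
#'   top-k set equals the full-data one), reps, alpha, seed.
#' @export
robustness_test <- function(y_resid, X, units, fractions = c(0.6, 0.7, 0.8, 0.9),
                            reps = 1000, alpha = 0.05, k = 6, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y_resid), nrow(units) == length(y_resid))
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  vars <- colnames(X)
  Xd <- cbind("(Intercept)" = 1, X)

  full_report <- bootstrap_significance(y_resid, X, reps = reps,
                                        alpha = alpha, seed = seed)
  full_top <- select_top_k(full_report, k)

  counts_by_frac <- list()
  top_by_frac <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    set.seed(child_seed(seed, 100L + fi))
    counts <- stats::setNames(integer(length(vars)), vars)
    sum_abs_t <- stats::setNames(numeric(length(vars)), vars)
    redraws <- 0L; done <- 0L
    while (done < reps) {
      idx <- stratified_sample(units, f)
      fit <- ols_coef_table(Xd[idx, , drop = FALSE], y_resid[idx])
      if (is.null(fit)) {
        redraws <- redraws + 1L
        if (redraws > 10L * reps) stop("too many rank-deficient subsamples")
        next
      }
      counts <- counts + (fit$p[-1] < alpha)
      sum_abs_t <- sum_abs_t + abs(fit$t[-1])
      done <- done + 1L
    }
    rep_f <- structure(list(counts = counts, mean_abs_t = sum_abs_t / reps,
                            reps = reps, alpha = alpha, redraws = redraws,
                            seed = seed),
                       class = "selection_report")
    key <- format(f)
    counts_by_frac[[key]] <- rep_f$counts
    top_by_frac[[key]] <- as.character(select_top_k(rep_f, k))
  }
  consistent <- all(vapply(top_by_frac, function(s)
    setequal(s, as.character(full_top)), TRUE))
  structure(list(fractions = fractions, counts = counts_by_frac,
                 top_k = top_by_frac, full_top_k = as.character(full_top),
                 full_counts = full_report$counts,
                 consistent = consistent, reps = reps, alpha = alpha, k = k,
                 seed = as.integer(seed)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness test: %d reps, fractions %s\n", x$reps,
              paste(x$fractions, collapse = ", ")))
  cat("  full-data top-k:", paste(x$full_top_k, collapse = ", "), "\n")
  cat("  consistent across fractions:", x$consistent, "\n")
  invisible(x)
}

#' Compare two inventories on under-sampled units
#'
#' Restricts to units whose incompleteness score exceeds the cutoff and
#' summarizes the per-unit richness difference (ours - reference): its mean
#' and SD, and how many under-sampled units are higher / identical / lower
#' in our inventory.
#'
#' @param ours per-unit richness of this inventory (optionally named by unit
#'   id).
#' @param reference per-unit richness of the reference inventory.
#' @param incompleteness per-unit incompleteness score of the reference.
#' @param cutoff under-sampling cutoff (default 0.05).
#' @return object of class \code{completeness_report}: n_undersampled,
#'   mean_diff, sd_diff, n_higher, n_identical, n_lower, cutoff.
#' @export
compare_inventories <- function(ours, reference, incompleteness,
                                cutoff = 0.05) {
  if (!is.null(names(ours)) && !is.null(names(reference))) {
    shared <- intersect(names(ours), names(reference))
    if (!length(shared)) stop("no shared unit ids")
    ours <- ours[shared]; reference <- reference[shared]
    incompleteness <- incompleteness[shared]
  }
  stopifnot(length(ours) == length(reference),
            length(ours) == length(incompleteness))
  sel <- which(incompleteness > cutoff)
  d <- ours[sel] - reference[sel]
  structure(list(n_undersampled = length(sel),
                 mean_diff = if (length(d)) mean(d) else NA_real_,
                 sd_diff = if (length(d) > 1) stats::sd(d) else
                   if (length(d) == 1) 0 else NA_real_,
                 n_higher = sum(d > 0), n_identical = sum(d == 0),
                 n_lower = sum(d < 0), cutoff = cutoff),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("completeness audit (cutoff %g): %d under-sampled units\n",
              x$cutoff, x$n_undersampled))
  cat(sprintf("  difference mean %.1f, SD %.1f; higher %d / identical %d / lower %d\n",
              x$mean_diff, x$sd_diff, x$n_higher, x$n_identical, x$n_lower))
  invisible(x)
}

#' Correlation of county and nested-reserve richness
#'
#' Pearson correlation with a two-sided p-value between county inventories
#' and the fully surveyed inventories of reserves nested within them.
#'
#' @param county_richness paired vector.
#' @param reserve_richness paired vector.
#' @return list(r, p, n).
#' @export
nested_reserve_correlation <- function(county_richness, reserve_richness) {
  stopifnot(length(county_richness) == length(reserve_richness))
  if (length(county_richness) < 3) stop("need at least 3 paired units")
  if (stats::sd(county_richness) == 0 || stats::sd(reserve_richness) == 0)
    stop("constant vector: correlation undefined")
  ct <- stats::cor.test(county_richness, reserve_richness, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(county_richness))
}
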