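# ---------------------------------------------------------------------------
# Step 1: scale transforms, removal of the county-area effect, and pruning of
# strongly intercorrelated variables within each hypothesis category.
# ---------------------------------------------------------------------------

#' Apply the analysis-scale transform
#'
#' log10 is applied to richness, area and every covariate flagged
#' \code{"log10"}; variables that can be non-positive (temperatures in
#' 0.1 degC, signed indices) and categorical codes pass through unchanged.
#' The choice is recorded per variable.
#'
#' For an \code{env_matrix} the per-variable transform flags are taken from
#' the object; a plain numeric vector is log10-transformed (it must be
#' strictly positive).
#'
#' @param x an \code{env_matrix} or a strictly positive numeric vector
#'   (richness or area).
#' @return For an \code{env_matrix}: a list(values, transform) where
#'   \code{values} is the analysis-scale data.frame. For a vector: the log10
#'   values.
#' @export
log_transform <- function(x) {
  if (inherits(x, "env_matrix")) {
    vals <- x$values
    for (v in names(vals)) {
      if (x$transform[[v]] == "log10") {
        bad <- which(vals[[v]] <= 0)
        if (length(bad))
          stop(sprintf("non-positive value in log10-flagged variable '%s' at unit %d",
                       v, bad[1]))
        vals[[v]] <- log10(vals[[v]])
      }
    }
    return(list(values = vals, transform = x$transform))
  }
  bad <- which(x <= 0)
  if (length(bad))
    stop("non-positive value at position ", bad[1],
         ": cannot log10-transform")
  log10(x)
}

#' Remove the county-area effect from richness
#'
#' Ordinary least-squares residuals of log richness on an intercept and log
#' area. Residuals sum to zero and are orthogonal to log area.
#'
#' @param log_richness numeric vector (log10 richness).
#' @param log_area numeric vector (log10 area), non-constant.
#' @return residual vector.
#' @export
residualize_on_area <- function(log_richness, log_area) {
  if (length(log_richness) != length(log_area)) stop("length mismatch")
  if (stats::sd(log_area) == 0) stop("constant area: residualization undefined")
  stats::lm.fit(cbind(1, log_area), log_richness)$residuals
}

#' Spearman correlation matrix of one hypothesis category
#'
#' Rank correlation (average ranks for ties) between every pair of variables
#' carrying the given category tag. Pairs involving a constant variable are
#' reported as NA.
#'
#' @param env an \code{env_matrix} (analysis scale is irrelevant: Spearman is
#'   monotone-invariant).
#' @param category one of the category tags in \code{env$category}.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(env, category) {
  stopifnot(inherits(env, "env_matrix"))
  vars <- names(env$category)[env$category == category]
  if (length(vars) < 2) stop("need >= 2 variables in category '", category, "'")
  X <- as.matrix(env$values[vars])
  if (nrow(X) < 3) stop("need n >= 3 observations")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  rho[const, ] <- NA; rho[, const] <- NA
  diag(rho) <- 1
  rho
}

#' Deviance explained by a single predictor
#'
#' For the Gaussian univariate regression of \code{y_resid} on \code{x} this
#' is 1 - RSS/TSS, i.e. the r-squared, in \[0, 1\]. A constant predictor
#' explains nothing (returned as 0 with a warning).
#'
#' @param y_resid response (area-residualized log richness).
#' @param x single predictor.
#' @return proportion of deviance explained.
#' @export
univariate_deviance <- function(y_resid, x) {
  if (length(y_resid) != length(x)) stop("length mismatch")
  if (stats::sd(x) == 0) {
    warning("constant predictor: deviance explained set to 0")
    return(0)
  }
  stats::cor(y_resid, x)^2
}

#' Screen variables within hypothesis categories
#'
#' Within each category, while any pair of retained variables has Spearman
#' |rho| above the threshold, the pair with the largest |rho| is resolved by
#' dropping the member with the lower univariate deviance explained on the
#' area-residualized response (deviance ties broken by keeping the
#' lexicographically smaller name). Cross-category correlations are not
#' pruned.
#'
#' @param env an \code{env_matrix}.
#' @param y_resid area-residualized log richness.
#' @param threshold |rho| above which a pair is "strongly intercorrelated"
#'   (default 0.7).
#' @return object of class \code{screening_result}: list(retained — named by
#'   category, dropped — data.frame logging each drop with its deciding
#'   rho/deviance comparison, threshold, deviance — named vector).
#' @export
screen_variables <- function(env, y_resid, threshold = 0.7) {
  stopifnot(inherits(env, "env_matrix"))
  if (nrow(env$values) != length(y_resid)) stop("length mismatch")
  yv <- log_transform(env)$values  # analysis scale for deviance
  dev <- vapply(names(yv), function(v)
    suppressWarnings(univariate_deviance(y_resid, yv[[v]])), 0)
  cats <- unique(env$category)
  retained <- list()
  drops <- list()
  for (ct in cats) {
    vars <- names(env$category)[env$category == ct]
    if (length(vars) < 2) { retained[[ct]] <- vars; next }
    rho <- suppressWarnings(stats::cor(as.matrix(env$values[vars]),
                                       method = "spearman"))
    keep <- vars
    repeat {
      sub <- abs(rho[keep, keep, drop = FALSE])
      diag(sub) <- 0
      sub[is.na(sub)] <- 0
      if (max(sub) <= threshold) break
      ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      a <- keep[ij[1]]; b <- keep[ij[2]]
      drop_var <- if (dev[a] < dev[b]) a
      else if (dev[b] < dev[a]) b
      else max(a, b)  # deviance tie: keep the lexicographically smaller name
      kept_var <- setdiff(c(a, b), drop_var)
      drops[[length(drops) + 1L]] <- data.frame(
        category = ct, dropped = drop_var, kept = kept_var,
        rho = rho[a, b], deviance_dropped = dev[drop_var],
        deviance_kept = dev[kept_var])
      keep <- setdiff(keep, drop_var)
    }
    retained[[ct]] <- sort(keep)
  }
  structure(list(retained = retained,
                 dropped = if (length(drops)) do.call(rbind, drops)
                 else data.frame(category = character(), dropped = character(),
                                 kept = character(), rho = numeric(),
                                 deviance_dropped = numeric(),
                                 deviance_kept = numeric()),
                 threshold = threshold, deviance = dev),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("screened variables (|rho| threshold", x$threshold, "):\n")
  for (ct in names(x$retained))
    cat(sprintf("  %s: %s\n", ct, paste(x$retained[[ct]], collapse = ", ")))
  cat(sprintf("  dropped: %d variable(s)\n", nrow(x$dropped)))
  invisible(x)
}

#' All retained variables of a screening result
#' @param screening a \code{screening_result}.
#' @return character vector.
#' @export
retained_variables <- function(screening) {
  sort(unname(unlist(screening$retained)))
}

#' Write a screening report as JSON
#' @param screening a \code{screening_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_screening_report <- function(screening, path) {
  jsonlite::write_json(list(threshold = screening$threshold,
                            retained = screening$retained,
                            dropped = screening$dropped,
                            deviance = as.list(screening$deviance)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
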