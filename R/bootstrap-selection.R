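# ---------------------------------------------------------------------------
# Step 2: Gaussian GLMs refitted on bootstrap resamples; variables ranked by
# how often their coefficient reaches significance.
# ---------------------------------------------------------------------------

# OLS with coefficient table via QR; shared by fit_glm and the bootstrap loop.
ols_coef_table <- function(X, y) {
  qrx <- qr(X)
  p <- ncol(X)
  if (qrx$rank < p) return(NULL)
  coefs <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  n <- length(y)
  df <- n - p
  rss <- sum(res^2)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- coefs / se
  list(beta = coefs, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), rss = rss, df = df)
}

#' Fit a Gaussian generalized linear model
#'
#' Gaussian family with identity link (equivalent to OLS); two-sided
#' p-values from the t distribution on n - p - 1 degrees of freedom. An
#' intercept is always included.
#'
#' @param y_resid response (area-residualized log richness).
#' @param X matrix or data.frame of predictors.
#' @return list with \code{coefficients} (data.frame: beta, se, t, p — first
#'   row the intercept), \code{deviance} (residual sum of squares),
#'   \code{null_deviance} (total sum of squares), \code{df}, \code{n}.
#' @export
fit_glm <- function(y_resid, X) {
  X <- as.matrix(X)
  if (ncol(X) && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y_resid)
  if (n <= ncol(X) + 1) stop("need n > p + 1 observations")
  Xd <- cbind("(Intercept)" = 1, X)
  fit <- ols_coef_table(Xd, y_resid)
  if (is.null(fit)) {
    qrx <- qr(Xd)
    drop_cols <- colnames(Xd)[qrx$pivot[seq(qrx$rank + 1, ncol(Xd))]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  list(coefficients = data.frame(beta = fit$beta, se = fit$se, t = fit$t,
                                 p = fit$p, row.names = colnames(Xd)),
       deviance = fit$rss,
       null_deviance = sum((y_resid - mean(y_resid))^2),
       df = fit$df, n = n)
}

#' Bootstrap significance frequencies
#'
#' Each replicate draws n units with replacement, refits the Gaussian GLM,
#' and increments a variable's count when its coefficient's p-value is below
#' \code{alpha}. Rank-deficient resamples are redrawn (logged), up to
#' 10 x reps redraws in total.
#'
#' @param y_resid response.
#' @param X predictor matrix.
#' @param reps number of replicates (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed; counts are reproducible given it.
#' @return object of class \code{selection_report}: counts (named integer),
#'   mean_abs_t (named, tie-break statistic), reps, alpha, redraws, seed.
#' @export
bootstrap_significance <- function(y_resid, X, reps = 1000, alpha = 0.05,
                                   seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y_resid)
  if (n <= ncol(X) + 1) stop("need n > p + 1 observations")
  Xd <- cbind("(Intercept)" = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("rank-deficient full design")
  set.seed(as.integer(seed))
  vars <- colnames(X)
  counts <- stats::setNames(integer(length(vars)), vars)
  sum_abs_t <- stats::setNames(numeric(length(vars)), vars)
  redraws <- 0L
  done <- 0L
  while (done < reps) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- ols_coef_table(Xd[idx, , drop = FALSE], y_resid[idx])
    if (is.null(fit)) {
      redraws <- redraws + 1L
      if (redraws > 10L * reps)
        stop("too many rank-deficient resamples (", redraws, ")")
      next
    }
    pv <- fit$p[-1]
    counts <- counts + (pv < alpha)
    sum_abs_t <- sum_abs_t + abs(fit$t[-1])
    done <- done + 1L
  }
  structure(list(counts = counts, mean_abs_t = sum_abs_t / reps,
                 reps = reps, alpha = alpha, redraws = redraws,
                 seed = as.integer(seed)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("bootstrap selection: %d reps, alpha = %g, %d redraw(s)\n",
              x$reps, x$alpha, x$redraws))
  print(sort(x$counts, decreasing = TRUE))
  invisible(x)
}

#' Select the top-k variables by significance count
#'
#' Variables are ranked by their significance count; ties are broken by the
#' larger mean |t| across replicates, then by variable name. Tie decisions at
#' the selection boundary are logged in the result.
#'
#' @param report a \code{selection_report}.
#' @param k how many variables to select (default 6).
#' @return character vector of the selected variables in rank order, with
#'   attribute \code{tie_log} describing any boundary tie.
#' @export
select_top_k <- function(report, k = 6) {
  stopifnot(inherits(report, "selection_report"))
  vars <- names(report$counts)
  if (k > length(vars)) {
    warning("k exceeds the number of variables; returning all")
    k <- length(vars)
  }
  ord <- order(-report$counts, -report$mean_abs_t[vars], vars)
  ranked <- vars[ord]
  sel <- ranked[seq_len(k)]
  tie_log <- character()
  if (k < length(vars) &&
      report$counts[[ranked[k]]] == report$counts[[ranked[k + 1]]]) {
    tie_log <- sprintf(
      "count tie at rank %d (%d): kept %s (mean |t| %.3f) over %s (mean |t| %.3f)",
      k, report$counts[[ranked[k]]], ranked[k],
      report$mean_abs_t[[ranked[k]]], ranked[k + 1],
      report$mean_abs_t[[ranked[k + 1]]])
  }
  attr(sel, "tie_log") <- tie_log
  sel
}

#' Write a selection report as JSON plus a delimited counts table
#' @param report a \code{selection_report}.
#' @param path JSON output path; a sibling \code{.tsv} with the counts table
#'   is written alongside.
#' @param k selection size recorded in the report.
#' @return \code{path}, invisibly.
#' @export
write_selection_report <- function(report, path, k = 6) {
  sel <- select_top_k(report, k)
  jsonlite::write_json(list(reps = report$reps, alpha = report$alpha,
                            seed = report$seed, redraws = report$redraws,
                            counts = as.list(report$counts),
                            mean_abs_t = as.list(report$mean_abs_t),
                            selected = as.character(sel),
                            tie_log = attr(sel, "tie_log")),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsv <- sub("\\.json$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  utils::write.table(
    data.frame(variable = names(report$counts), count = report$counts,
               mean_abs_t = report$mean_abs_t),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
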