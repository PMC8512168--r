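## Test-retest reliability statistics and the exploratory correlation /
## factor analysis stage, runnable on simulated cohorts or on a deposited
## outcome table with the same 26-variable schema.

#' Intraclass correlation coefficient (two-way, absolute agreement, single
#' measures)
#'
#' Computed from the two-way ANOVA mean squares (rows = subjects, columns =
#' sessions): `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.  The
#' absolute-agreement form penalizes systematic session biases, which is the
#' relevant failure mode for test-retest data.
#'
#' @param test,retest paired numeric vectors
#' @return ICC in [-1, 1]; NA (with a warning) if total variance is zero
#' @export
icc_agreement <- function(test, retest) {
  ok <- stats::complete.cases(test, retest)
  x <- cbind(test[ok], retest[ok])
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(as.vector(x)) == 0) {
    warning("zero total variance; ICC undefined")
    return(NA_real_)
  }
  row_m <- rowMeans(x); col_m <- colMeans(x); gm <- mean(x)
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Standard error of measurement
#'
#' `SEM = pooled_SD * sqrt(1 - ICC)`, in the outcome's own units, with the
#' pooled between-subject SD of both sessions.
#'
#' @param test,retest paired numeric vectors
#' @param icc optionally a precomputed ICC for the same data
#' @export
sem_measure <- function(test, retest, icc = NULL) {
  if (is.null(icc)) icc <- icc_agreement(test, retest)
  ok <- stats::complete.cases(test, retest)
  pooled_sd <- sqrt((stats::var(test[ok]) + stats::var(retest[ok])) / 2)
  pooled_sd * sqrt(pmax(1 - icc, 0))
}

#' Per-outcome reliability report
#'
#' @param test,retest data.frames with identical outcome columns (rows =
#'   listeners)
#' @param vars columns to analyze (default: shared numeric columns)
#' @return data.frame of class `reliability_report`: outcome, icc, sem,
#'   mean_bias (retest - test), n
#' @export
reliability_report <- function(test, retest, vars = NULL) {
  if (is.null(vars))
    vars <- intersect(names(test)[vapply(test, is.numeric, TRUE)],
                      names(retest))
  rows <- lapply(vars, function(v) {
    ok <- stats::complete.cases(test[[v]], retest[[v]])
    if (sum(ok) < 3 || stats::var(c(test[[v]][ok], retest[[v]][ok])) == 0)
      return(data.frame(outcome = v, icc = NA_real_, sem = NA_real_,
                        mean_bias = NA_real_, n = sum(ok)))
    icc <- icc_agreement(test[[v]], retest[[v]])
    data.frame(outcome = v, icc = icc,
               sem = sem_measure(test[[v]], retest[[v]], icc),
               mean_bias = mean(retest[[v]][ok] - test[[v]][ok]),
               n = sum(ok))
  })
  structure(do.call(rbind, rows), class = c("reliability_report", "data.frame"))
}

#' Spearman correlation matrix with a significance mask
#'
#' Pairwise-complete Spearman correlations; p-values via the t approximation
#' (exact AS89 p through [stats::cor.test()] for fewer than 15 pairs).
#'
#' @param table data.frame of outcomes (numeric columns used)
#' @param alpha significance threshold for the mask
#' @return list: `rho`, `p`, `mask` (p < alpha), `n` (pairwise counts)
#' @export
spearman_matrix <- function(table, alpha = 1e-5) {
  num <- table[vapply(table, is.numeric, TRUE)]
  v <- names(num); m <- length(v)
  rho <- p <- nmat <- matrix(NA_real_, m, m, dimnames = list(v, v))
  for (i in seq_len(m)) for (j in i:m) {
    ok <- stats::complete.cases(num[[i]], num[[j]])
    n <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- n
    if (n < 3) next
    if (i == j) { rho[i, j] <- 1; p[i, j] <- 0; next }
    r <- stats::cor(num[[i]][ok], num[[j]][ok], method = "spearman")
    rho[i, j] <- rho[j, i] <- r
    pv <- if (n < 15) {
      suppressWarnings(stats::cor.test(num[[i]][ok], num[[j]][ok],
                                       method = "spearman")$p.value)
    } else if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), n - 2)
    }
    p[i, j] <- p[j, i] <- pv
  }
  list(rho = rho, p = p, mask = p < alpha, n = nmat)
}

#' Parallel analysis for the number of factors
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' chosen quantile of eigenvalues from standard-normal surrogate data of the
#' same dimensions; the retained count is the number of leading observed
#' eigenvalues exceeding their surrogate quantile.
#'
#' @param table data.frame (numeric columns; complete cases used)
#' @param n_sim surrogate datasets
#' @param quantile surrogate eigenvalue quantile
#' @param seed integer
#' @return integer factor count
#' @export
parallel_analysis <- function(table, n_sim = 500, quantile = 0.95, seed = 1) {
  num <- table[vapply(table, is.numeric, TRUE)]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  n <- nrow(num); m <- ncol(num)
  if (n < m + 1) stop("not enough complete rows for parallel analysis")
  ev <- eigen(stats::cor(num), symmetric = TRUE, only.values = TRUE)$values
  sim <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      eigen(stats::cor(matrix(stats::rnorm(n * m), n, m)),
            symmetric = TRUE, only.values = TRUE)$values
    }, numeric(m))
  })
  thr <- apply(sim, 1, stats::quantile, probs = quantile)
  exceeds <- ev > thr
  if (!exceeds[1]) return(0L)
  as.integer(which.min(c(exceeds, FALSE)) - 1)
}

#' Maximum-likelihood factor analysis with varimax rotation
#'
#' Standardizes the (complete-case) table, extracts `n_factors` by maximum
#' likelihood via [stats::factanal()], rotates orthogonally (varimax), and
#' reports per-factor and cumulative variance explained plus the loadings
#' above a reporting threshold.
#'
#' @param table data.frame of outcomes
#' @param n_factors number of factors
#' @param rotation rotation passed to factanal (default "varimax")
#' @param loading_threshold reporting threshold for salient loadings
#' @return object of class `factor_report`
#' @export
factor_analysis_ml <- function(table, n_factors, rotation = "varimax",
                               loading_threshold = 0.65) {
  num <- table[vapply(table, is.numeric, TRUE)]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  sds <- vapply(num, stats::sd, numeric(1))
  num <- num[, sds > 1e-10, drop = FALSE]   # drop constant columns
  if (n_factors < 1) stop("n_factors must be >= 1")
  fa <- tryCatch(
    stats::factanal(scale(num), factors = n_factors, rotation = rotation),
    # near-singular tables: restart from random loadings with a firmer
    # lower bound on the uniquenesses
    error = function(e) stats::factanal(scale(num), factors = n_factors,
                                        rotation = rotation,
                                        control = list(nstart = 20,
                                                       lower = 0.05)))
  L <- unclass(fa$loadings)
  ve <- 100 * colSums(L^2) / ncol(num)
  ord <- order(ve, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]; ve <- ve[ord]
  colnames(L) <- names(ve) <- paste0("F", seq_len(n_factors))
  heywood <- any(1 - fa$uniquenesses > 0.998)
  salient <- lapply(seq_len(n_factors), function(j) {
    sel <- abs(L[, j]) > loading_threshold
    stats::setNames(L[sel, j], rownames(L)[sel])
  })
  names(salient) <- colnames(L)
  structure(list(n_factors = n_factors, loadings = L,
                 variance_explained = ve, cumulative_variance = cumsum(ve),
                 rotation = rotation, loading_threshold = loading_threshold,
                 salient = salient, heywood = heywood,
                 uniquenesses = fa$uniquenesses, n = nrow(num)),
            class = "factor_report")
}

#' @export
print.factor_report <- function(x, ...) {
  cat(sprintf("<factor_report> %d factors (%s), cumulative variance %.1f%% (n = %d)%s\n",
              x$n_factors, x$rotation,
              utils::tail(x$cumulative_variance, 1), x$n,
              if (x$heywood) " [Heywood case]" else ""))
  for (f in names(x$salient)) {
    s <- x$salient[[f]]
    cat(sprintf("  %s (%.1f%%): %s\n", f,
                x$variance_explained[[f]],
                if (length(s)) paste(sprintf("%s=%.2f", names(s), s),
                                     collapse = ", ") else "-"))
  }
  invisible(x)
}

#' Read a reduced outcome table from CSV
#'
#' Validates that the 26 analysis variables are present (extra id/grouping
#' columns are kept); empty cells become NA.
#'
#' @param path CSV file
#' @return data.frame
#' @export
read_bear3_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- bear3_analysis_variables()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("outcome table schema mismatch; missing columns: ",
         paste(missing, collapse = ", "))
  df
}

#' Write a reduced outcome table to CSV
#' @param table data.frame (e.g. from [run_cohort_study()])
#' @param path output CSV
#' @export
write_bear3_dataset <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
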