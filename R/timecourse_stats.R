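## Per-gene quadratic regression over metareplicates: ANOVA F-test against
## the null that all regression coefficients are zero, BH FDR within each
## stratum, R-squared gating, and the post-hoc overfitting filters.

#' Quadratic OLS fit with ANOVA F-test
#'
#' Ordinary least squares of `y = A x^2 + B x + C` on the design
#' `[1, x, x^2]`. Reports `R^2 = 1 - SSE/SST`,
#' `F = (SSR/2) / (SSE/(n-3))` with p-value from `F(2, n-3)`, and
#' two-sided per-coefficient t-tests on `t(n-3)` using the unscaled
#' covariance of the design.
#'
#' @param times observation times (length >= 4, >= 3 distinct values).
#' @param values responses, same length; must not be constant.
#' @return A `regression_fit` list: `n`, `A`, `B`, `C`, `R2`, `F`, `p_F`,
#'   `p_A`, `p_B`, `p_C`, `fitted`, `sigma2`.
#' @export
fit_quadratic <- function(times, values) {
  n <- length(values)
  if (length(times) != n) stop("times and values differ in length")
  if (n < 4) stop("need n >= 4 observations (F with df 2, n-3)")
  if (length(unique(times)) < 3) stop("need >= 3 distinct time values")
  if (max(values) == min(values)) {
    cond <- structure(
      list(message = "constant response (excluded upstream, not a DEG)",
           call = sys.call(-1)),
      class = c("metareplicate_constant_gene", "error", "condition"))
    stop(cond)
  }
  X <- cbind(1, times, times^2)
  qr_X <- qr(X)
  if (qr_X$rank < 3) stop("rank-deficient design")
  coefs <- qr.coef(qr_X, values)
  fitted <- drop(X %*% coefs)
  res <- values - fitted
  sse <- sum(res^2)
  sst <- sum((values - mean(values))^2)
  ssr <- sst - sse
  df_res <- n - 3
  sigma2 <- sse / df_res
  R2 <- 1 - sse / sst
  Fstat <- (ssr / 2) / sigma2
  p_F <- pf(Fstat, 2, df_res, lower.tail = FALSE)
  XtXi <- chol2inv(qr.R(qr_X))
  se <- sqrt(sigma2 * diag(XtXi))
  tstat <- coefs / se
  pcoef <- 2 * pt(abs(tstat), df_res, lower.tail = FALSE)
  structure(list(n = n, A = unname(coefs[3]), B = unname(coefs[2]),
                 C = unname(coefs[1]),
                 R2 = R2, F = Fstat, p_F = p_F,
                 p_A = unname(pcoef[3]), p_B = unname(pcoef[2]),
                 p_C = unname(pcoef[1]),
                 fitted = fitted, sigma2 = sigma2),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("quadratic fit (n=%d): y = %.4g x^2 + %.4g x + %.4g\n",
              x$n, x$A, x$B, x$C))
  cat(sprintf("  R2 = %.4f, F(2,%d) = %.3f, p = %.3g\n",
              x$R2, x$n - 3, x$F, x$p_F))
  invisible(x)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Classic step-up procedure: `q_(i) = min_{j >= i} p_(j) * m / j`, with
#' monotonicity enforced and the result mapped back to input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  q_sorted <- p_values[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Single-nonzero-metareplicate filter
#'
#' A gene whose expression is positive in exactly one metareplicate and
#' zero in all others fits the quadratic perfectly through an outlier;
#' such genes are excluded. All-zero vectors pass (they are handled by the
#' constant-gene rule instead).
#'
#' @param values_across_metacells numeric vector (length >= 2) of a gene's
#'   expression across a stratum's metareplicates.
#' @return `TRUE` to keep the gene, `FALSE` to drop it.
#' @export
single_nonzero_filter <- function(values_across_metacells) {
  if (length(values_across_metacells) < 2) stop("need >= 2 values")
  sum(values_across_metacells > 0) != 1 ||
    any(values_across_metacells[values_across_metacells <= 0] != 0)
}

#' Pooled-variance two-sample t-test against baseline
#'
#' Two-sided, unpaired, equal-variance t-test comparing metacell expression
#' at a day with healthy-control baseline values.
#'
#' @param metacell_values_at_day numeric vector (length >= 2).
#' @param baseline_values numeric vector (length >= 2).
#' @return list with `t`, `p`, `df`.
#' @export
baseline_contrast <- function(metacell_values_at_day, baseline_values) {
  x <- metacell_values_at_day; y <- baseline_values
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need >= 2 values per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1, df = df))
    stop("degenerate contrast: zero pooled variance with unequal means")
  }
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, p = 2 * pt(abs(tstat), df, lower.tail = FALSE), df = df)
}

#' Time-course differential expression over metareplicates
#'
#' For each stratum (each cell type, or all metacells pooled), excludes
#' constant and single-nonzero genes, fits every remaining gene's quadratic
#' regression of expression on day, applies BH FDR within the stratum, and
#' gates DEGs by `q < alpha` and `R^2 > r2_min`. Strata with fewer than
#' `min_n` metareplicates, fewer than 3 distinct days, or fewer than 2 time
#' points are skipped with a warning.
#'
#' @param ms a `metacell_set`.
#' @param alpha FDR threshold (default 0.05).
#' @param r2_min R-squared threshold (default 0.5).
#' @param grouping `"per-type"` fits each cell type separately;
#'   `"all-cells"` pools every metacell into one stratum.
#' @param min_n minimum metareplicates per stratum (default 4).
#' @return list with `fits` (full per-gene table, one row per tested or
#'   filtered gene, with a `status` column) and `degs` (the gated subset,
#'   class `deg_table`).
#' @export
find_timecourse_degs <- function(ms, alpha = 0.05, r2_min = 0.5,
                                 grouping = c("per-type", "all-cells"),
                                 min_n = 4) {
  stopifnot(inherits(ms, "metacell_set"))
  grouping <- match.arg(grouping)
  strata <- if (grouping == "all-cells") list(all = seq_len(nrow(ms$meta)))
            else split(seq_len(nrow(ms$meta)), ms$meta$cell_type)
  fit_rows <- list()
  for (sname in names(strata)) {
    rows <- strata[[sname]]
    days <- ms$meta$day[rows]
    if (length(rows) < min_n || length(unique(days)) < 3) {
      warning("stratum ", sname, " skipped (", length(rows),
              " metareplicates over ", length(unique(days)), " days)")
      next
    }
    expr <- ms$expression[rows, , drop = FALSE]
    genes <- ms$gene_ids
    status <- rep("tested", length(genes))
    vmax <- apply(expr, 2, max); vmin <- apply(expr, 2, min)
    status[vmax == vmin] <- "constant"
    sn_keep <- apply(expr, 2, single_nonzero_filter)
    status[status == "tested" & !sn_keep] <- "single_nonzero"
    test_idx <- which(status == "tested")
    if (!length(test_idx)) next
    res <- lapply(test_idx, function(g) fit_quadratic(days, expr[, g]))
    tab <- data.frame(
      gene = genes[test_idx], cell_type = sname,
      n = length(rows),
      A = vapply(res, `[[`, 0, "A"), B = vapply(res, `[[`, 0, "B"),
      C = vapply(res, `[[`, 0, "C"),
      R2 = vapply(res, `[[`, 0, "R2"), F = vapply(res, `[[`, 0, "F"),
      p_F = vapply(res, `[[`, 0, "p_F"),
      p_A = vapply(res, `[[`, 0, "p_A"), p_B = vapply(res, `[[`, 0, "p_B"),
      p_C = vapply(res, `[[`, 0, "p_C"),
      status = "tested", stringsAsFactors = FALSE)
    tab$q <- benjamini_hochberg(tab$p_F)
    drop_idx <- which(status != "tested")
    if (length(drop_idx)) {
      tab <- rbind(tab, data.frame(
        gene = genes[drop_idx], cell_type = sname, n = length(rows),
        A = NA, B = NA, C = NA, R2 = NA, F = NA, p_F = NA,
        p_A = NA, p_B = NA, p_C = NA,
        status = status[drop_idx], q = NA, stringsAsFactors = FALSE))
    }
    fit_rows[[sname]] <- tab
  }
  fits <- if (length(fit_rows)) do.call(rbind, fit_rows)
          else stop("no stratum satisfied the preconditions")
  rownames(fits) <- NULL
  degs <- fits[fits$status == "tested" & fits$q < alpha & fits$R2 > r2_min, ,
               drop = FALSE]
  rownames(degs) <- NULL
  class(degs) <- c("deg_table", "data.frame")
  list(fits = fits, degs = degs)
}
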