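## Variance and quality diagnostics comparing metacell strategies: mSD
## tables, genes-detected counts, purity summaries, and the
## severity-stratified expression export.

#' Mean per-gene SD across a stratum's metareplicates
#'
#' For each stratum — (cell type, day) by default, or cell type pooled over
#' days with `pooled = TRUE` — computes the sample SD (n-1 denominator) of
#' every gene's expression across the stratum's metareplicates and averages
#' over all genes (the mSD). Strata with fewer than 2 metareplicates are
#' excluded.
#'
#' @param ms a `metacell_set`.
#' @param pooled pool metacells of a type across all days.
#' @return data.frame with `cell_type`, `day` (`NA` when pooled),
#'   `method`, `n_units`, `mSD`.
#' @export
mean_sd_per_stratum <- function(ms, pooled = FALSE) {
  stopifnot(inherits(ms, "metacell_set"))
  key <- if (pooled) ms$meta$cell_type
         else paste(ms$meta$cell_type, ms$meta$day, sep = "|")
  groups <- split(seq_len(nrow(ms$meta)), key)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (!length(groups)) stop("no stratum has >= 2 metareplicates")
  rows <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    sds <- apply(ms$expression[idx, , drop = FALSE], 2, sd)
    data.frame(cell_type = ms$meta$cell_type[idx[1]],
               day = if (pooled) NA_integer_ else ms$meta$day[idx[1]],
               method = ms$meta$method[idx[1]],
               n_units = length(idx), mSD = mean(sds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$cell_type, out$day), , drop = FALSE]
}

#' Variance report across metacell strategies
#'
#' Computes per-stratum mSD tables for each supplied metacell set, their
#' grand-mean mSD per method, and pairwise two-sided pooled-variance
#' t-tests on the stratum mSD values.
#'
#' @param sets named list of `metacell_set` objects.
#' @param pooled passed to [mean_sd_per_stratum()].
#' @return list with `per_stratum` (row-bound mSD tables tagged by set
#'   name), `grand` (per-set mean mSD), and `comparisons` (data.frame of
#'   pairwise t statistics and p-values), class `variance_report`.
#' @export
variance_report <- function(sets, pooled = FALSE) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  tabs <- lapply(names(sets), function(nm) {
    t <- mean_sd_per_stratum(sets[[nm]], pooled = pooled)
    t$set <- nm
    t
  })
  per_stratum <- do.call(rbind, tabs)
  grand <- data.frame(set = names(sets),
                      grand_mSD = vapply(tabs, function(t) mean(t$mSD), 0),
                      n_strata = vapply(tabs, nrow, 0L))
  comparisons <- NULL
  if (length(sets) > 1) {
    pairs <- utils::combn(names(sets), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      ct <- baseline_contrast(per_stratum$mSD[per_stratum$set == a],
                              per_stratum$mSD[per_stratum$set == b])
      data.frame(set_a = a, set_b = b, t = ct$t, p = ct$p, df = ct$df,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(per_stratum = per_stratum, grand = grand,
                 comparisons = comparisons, pooled = pooled),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat("variance report (", if (x$pooled) "pooled across days" else "per (type, day)",
      ")\n", sep = "")
  print(x$grand, row.names = FALSE)
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Genes detected per unit
#'
#' Counts genes with expression strictly greater than zero for every
#' metacell (or cell, via [as_single_cell_set()]).
#'
#' @param ms a `metacell_set`.
#' @return list with `per_unit` (data.frame `id`, `method`, `n_genes`) and
#'   `mean` (mean count).
#' @export
genes_detected <- function(ms) {
  stopifnot(inherits(ms, "metacell_set"))
  counts <- apply(ms$expression, 1, function(v) sum(v > 0))
  list(per_unit = data.frame(id = ms$meta$id, method = ms$meta$method,
                             n_genes = unname(counts),
                             stringsAsFactors = FALSE),
       mean = mean(counts))
}

#' Severity-stratified expression export
#'
#' Long-format table of per-metacell expression through time for selected
#' genes, carrying the severity label, suitable for severity-coloured
#' expression-vs-time plots. No statistics are computed.
#'
#' @param ms a `metacell_set` with severity labels.
#' @param gene_list character vector of gene ids.
#' @return data.frame with columns `gene`, `day`, `metacell`, `expression`,
#'   `severity` (one row per gene x metacell).
#' @export
severity_expression_table <- function(ms, gene_list) {
  stopifnot(inherits(ms, "metacell_set"))
  unknown <- setdiff(gene_list, ms$gene_ids)
  if (length(unknown))
    stop("unknown genes: ", paste(unknown, collapse = ", "))
  if (!length(gene_list))
    return(data.frame(gene = character(0), day = integer(0),
                      metacell = character(0), expression = numeric(0),
                      severity = character(0), stringsAsFactors = FALSE))
  n_mc <- nrow(ms$meta)
  data.frame(
    gene = rep(gene_list, each = n_mc),
    day = rep(ms$meta$day, length(gene_list)),
    metacell = rep(ms$meta$id, length(gene_list)),
    expression = as.vector(ms$expression[, gene_list, drop = FALSE]),
    severity = rep(ms$meta$severity, length(gene_list)),
    stringsAsFactors = FALSE)
}
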