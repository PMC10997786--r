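## The three replicate-generation strategies: heterogeneity-preserving
## kernel-archetype sMetacells, random same-type rMetacells, and per-sample
## pseudobulk, plus typing, purity and analysis filters.

#' Metacell set container
#'
#' @param meta data.frame with one row per metacell: `id`, `method`, `day`,
#'   `cell_type`, `purity`, `n_members`, `sample_id`, `severity`.
#' @param expression metacells x genes numeric matrix of mean normalized
#'   expression, rows named by metacell id.
#' @param members named list of member cell-id character vectors.
#' @param gene_ids gene identifiers (columns of `expression`).
#' @param time_grid source time grid.
#' @param provenance list recording method, params and seed.
#' @return An object of class `metacell_set`.
#' @export
metacell_set <- function(meta, expression, members, gene_ids,
                         time_grid = covid_time_grid(), provenance = list()) {
  stopifnot(nrow(meta) == nrow(expression),
            length(members) == nrow(meta),
            ncol(expression) == length(gene_ids))
  if (any(meta$n_members < 1)) stop("every metacell needs >= 1 member")
  rownames(expression) <- meta$id
  colnames(expression) <- gene_ids
  structure(list(meta = meta, expression = expression, members = members,
                 gene_ids = gene_ids, time_grid = time_grid,
                 provenance = provenance),
            class = "metacell_set")
}

#' @export
print.metacell_set <- function(x, ...) {
  cat("metacell_set: ", nrow(x$meta), " metacells (",
      paste(unique(x$meta$method), collapse = "/"), ") x ",
      length(x$gene_ids), " genes\n", sep = "")
  cat("  days: ", paste(sort(unique(x$meta$day)), collapse = ", "), "\n", sep = "")
  cat("  types: ", paste(sort(unique(x$meta$cell_type)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Modal cell type and purity of a member set
#'
#' The assigned type is the most frequent type among members (ties broken
#' lexicographically); purity is the modal fraction.
#'
#' @param member_types character vector of member cell types (length >= 1).
#' @return list with `cell_type` and `purity`.
#' @export
assign_type_and_purity <- function(member_types) {
  if (length(member_types) < 1) stop("needs >= 1 member")
  tab <- table(member_types)
  top <- names(tab)[tab == max(tab)]
  ty <- sort(top)[1]
  list(cell_type = ty, purity = unname(tab[ty]) / length(member_types))
}

modal_label <- function(x) {
  tab <- table(x)
  sort(names(tab)[tab == max(tab)])[1]
}

#' Number of metacells to request for a time point
#'
#' One metacell per `ratio` cells, rounded to the nearest multiple of 10
#' (half-up) and floored at 10, with optional per-day overrides (e.g.
#' requesting 20 metacells on the last day for a better baseline
#' comparison).
#'
#' @param n_cells cells at the time point.
#' @param ratio cells per metacell (default 75).
#' @param day the day this count is for (only used to look up overrides).
#' @param day_overrides named vector/list mapping day -> count.
#' @return Integer metacell count.
#' @export
target_metacell_count <- function(n_cells, ratio = 75, day = NULL,
                                  day_overrides = NULL) {
  stopifnot(n_cells >= 1)
  if (!is.null(day) && !is.null(day_overrides)) {
    ov <- day_overrides[[as.character(day)]]
    if (!is.null(ov)) return(as.integer(ov))
  }
  raw <- n_cells / ratio
  rounded <- floor(raw / 10 + 0.5) * 10
  as.integer(max(rounded, 10))
}

#' Adaptive-Gaussian k-nearest-neighbour graph
#'
#' Builds a symmetric weighted adjacency on the embedding with kernel
#' `w_ij = exp(-d_ij^2 / (sigma_i sigma_j))`, where `sigma_i` is cell i's
#' distance to its `ceil(k/3)`-th neighbour (the adaptive bandwidth).
#' Edges are kept for the union of directed kNN lists; self-weight is 1.
#'
#' @param embedding cells x d numeric matrix.
#' @param k number of neighbours (`0 < k < n_cells`).
#' @return Sparse symmetric `dgCMatrix` adjacency.
#' @export
build_knn_graph <- function(embedding, k) {
  n <- nrow(embedding)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(dist(embedding))
  nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  kb <- ceiling(k / 3)
  sigma <- vapply(seq_len(n), function(i) d[i, nn[i, kb]], numeric(1))
  sigma <- pmax(sigma, 1e-12)
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nn))
  keep <- cbind(c(ii, jj), c(jj, ii))
  keep <- unique(keep)
  w <- exp(-d[keep]^2 / (sigma[keep[, 1]] * sigma[keep[, 2]]))
  adj <- Matrix::sparseMatrix(i = keep[, 1], j = keep[, 2], x = w,
                              dims = c(n, n))
  adj <- (adj + Matrix::t(adj)) / 2   # symmetrize (same kernel both ways)
  Matrix::diag(adj) <- 1
  methods::as(adj, "CsparseMatrix")
}

## Dense adaptive kernel between all cell pairs (same bandwidths as the
## kNN graph); used for archetype assignment where zero similarity to all
## archetypes must not occur.
dense_kernel <- function(embedding, k) {
  n <- nrow(embedding)
  k <- min(k, n - 1)
  d <- as.matrix(dist(embedding))
  kb <- ceiling(k / 3)
  sigma <- apply(d, 1, function(r) sort(r)[kb + 1])  # +1 skips self
  sigma <- pmax(sigma, 1e-12)
  K <- exp(-d^2 / outer(sigma, sigma))
  diag(K) <- 1
  K
}

## Greedy max-min seeding: start at the densest cell, then repeatedly add
## the cell least similar to the already chosen archetypes.
maxmin_seed <- function(K, n_seeds) {
  n <- nrow(K)
  chosen <- integer(n_seeds)
  chosen[1] <- which.max(rowSums(K))
  best_sim <- K[, chosen[1]]
  for (s in seq_len(n_seeds)[-1]) {
    cand <- setdiff(seq_len(n), chosen[seq_len(s - 1)])
    nxt <- cand[which.min(best_sim[cand])]
    chosen[s] <- nxt
    best_sim <- pmax(best_sim, K[, nxt])
  }
  chosen
}

smetacells_one_day <- function(K, n_metacells, max_iter = 50) {
  n <- nrow(K)
  if (n_metacells > n) stop("n_metacells (", n_metacells, ") exceeds cells (", n, ")")
  if (n_metacells == n) return(list(assign = seq_len(n), archetypes = seq_len(n),
                                    iterations = 0, objective = n))
  arch <- maxmin_seed(K, n_metacells)
  assign_prev <- rep(0L, n)
  iter <- 0
  repeat {
    iter <- iter + 1
    sim <- K[, arch, drop = FALSE]
    assign <- max.col(sim, ties.method = "first")
    # keep archetypes attached to their own group
    assign[arch] <- seq_along(arch)
    if (identical(assign, assign_prev) || iter >= max_iter) break
    assign_prev <- assign
    for (g in seq_along(arch)) {
      mem <- which(assign == g)
      if (!length(mem)) next
      score <- colSums(K[mem, mem, drop = FALSE])
      arch[g] <- mem[which.max(score)]
    }
  }
  keep <- sort(unique(assign))
  assign <- match(assign, keep)
  list(assign = assign, archetypes = arch[keep], iterations = iter,
       objective = sum(K[cbind(seq_len(n), arch[keep][assign])]))
}

make_metacell_rows <- function(x, member_idx_list, method, day, ids,
                               sample_id = NA_character_) {
  norm <- x$normalized
  meta_rows <- vector("list", length(member_idx_list))
  expr <- matrix(0, nrow = length(member_idx_list), ncol = ncol(norm))
  for (i in seq_along(member_idx_list)) {
    mem <- member_idx_list[[i]]
    expr[i, ] <- Matrix::colMeans(norm[mem, , drop = FALSE])
    tp <- assign_type_and_purity(x$cell_meta$cell_type[mem])
    meta_rows[[i]] <- data.frame(
      id = ids[i], method = method, day = day,
      cell_type = tp$cell_type, purity = tp$purity,
      n_members = length(mem),
      sample_id = if (length(sample_id) > 1) sample_id[i] else sample_id,
      severity = modal_label(x$cell_meta$severity[mem]),
      stringsAsFactors = FALSE)
  }
  list(meta = do.call(rbind, meta_rows), expr = expr,
       members = lapply(member_idx_list, function(m) x$cell_meta$cell_id[m]))
}

#' Construct heterogeneity-preserving sMetacells
#'
#' For each day independently, partitions that day's cells into the target
#' number of metacells by a kernel-archetype procedure: greedy max-min
#' seeding of archetype cells on the adaptive-Gaussian kernel, then
#' alternating (i) assignment of each cell to its most similar archetype
#' and (ii) re-selection of each archetype as the member maximizing the
#' within-group kernel sum (kernel medoid), until a fixed point or
#' `max_iter` iterations. Every cell joins exactly one metacell; a
#' metacell's expression is the mean normalized expression of its members.
#'
#' @param x an [aem()] with a normalized layer.
#' @param embedding cells x d embedding matching `x` rows; computed via
#'   [compute_embedding()] if absent from both argument and `x`.
#' @param n_metacells optional fixed count per day; default from
#'   [target_metacell_count()].
#' @param k neighbours for the kernel bandwidth (default 15).
#' @param ratio cells per metacell for the default count rule.
#' @param day_overrides per-day target-count overrides.
#' @param max_iter refinement iteration cap.
#' @param seed recorded in provenance (the procedure is deterministic).
#' @return A `metacell_set` with `method = "seacell_like"`.
#' @export
construct_smetacells <- function(x, embedding = NULL, n_metacells = NULL,
                                 k = 15, ratio = 75, day_overrides = NULL,
                                 max_iter = 50, seed = NULL) {
  x <- ensure_normalized(x)
  if (is.null(embedding)) embedding <- x$embedding
  if (is.null(embedding)) {
    hvg <- select_hvgs(x, min(500, ncol(x$counts)))
    embedding <- compute_embedding(x, hvg)
  }
  stopifnot(nrow(embedding) == nrow(x$counts))
  days <- x$time_grid[x$time_grid %in% x$cell_meta$day]
  out_meta <- list(); out_expr <- list(); out_members <- list()
  for (day in days) {
    cells <- which(x$cell_meta$day == day & x$cell_meta$severity != "control")
    if (!length(cells)) next
    nm <- if (!is.null(n_metacells)) n_metacells
          else min(target_metacell_count(length(cells), ratio, day, day_overrides),
                   length(cells))
    K <- dense_kernel(embedding[cells, , drop = FALSE], k)
    fit <- smetacells_one_day(K, nm, max_iter)
    groups <- unname(split(cells[seq_along(fit$assign)], fit$assign))
    if (length(groups) < nm)
      message("day ", day, ": ", nm - length(groups), " empty metacells dropped")
    ids <- sprintf("sMC_d%02d_%03d", day, seq_along(groups))
    rows <- make_metacell_rows(x, groups, "seacell_like", day, ids)
    out_meta[[length(out_meta) + 1]] <- rows$meta
    out_expr[[length(out_expr) + 1]] <- rows$expr
    out_members <- c(out_members, rows$members)
  }
  if (!length(out_meta)) stop("no cells on the time grid to build sMetacells from")
  metacell_set(do.call(rbind, out_meta), do.call(rbind, out_expr), out_members,
               x$gene_ids, x$time_grid,
               provenance = list(method = "seacell_like",
                                 params = list(k = k, ratio = ratio,
                                               day_overrides = day_overrides,
                                               max_iter = max_iter),
                                 seed = seed))
}

#' Construct random-cell rMetacells
#'
#' Per (day, cell type) stratum, draws `n_replicates` metacells, each the
#' mean normalized expression of `n_per_metacell` cells sampled without
#' replacement within that metacell (different metacells of a stratum may
#' share cells). Strata with fewer than `n_per_metacell` cells are skipped
#' with a warning. rMetacell purity is 1 by construction.
#'
#' @param x an [aem()] with a normalized layer.
#' @param n_per_metacell cells per metacell (default 20).
#' @param n_replicates metacells per stratum (default 3).
#' @param seed integer seed (mandatory).
#' @return A `metacell_set` with `method = "random"`.
#' @export
construct_rmetacells <- function(x, n_per_metacell = 20, n_replicates = 3,
                                 seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  x <- ensure_normalized(x)
  set.seed(as.integer(seed))
  days <- x$time_grid[x$time_grid %in% x$cell_meta$day]
  out_meta <- list(); out_expr <- list(); out_members <- list()
  skipped <- character(0)
  for (day in days) {
    in_day <- x$cell_meta$day == day & x$cell_meta$severity != "control"
    for (ty in sort(unique(x$cell_meta$cell_type[in_day]))) {
      cells <- which(in_day & x$cell_meta$cell_type == ty)
      if (length(cells) < n_per_metacell) {
        skipped <- c(skipped, sprintf("day %s/%s (%d cells)", day, ty, length(cells)))
        next
      }
      groups <- lapply(seq_len(n_replicates), function(r)
        sort(sample(cells, n_per_metacell)))
      ids <- sprintf("rMC_d%02d_%s_%02d", day, ty, seq_len(n_replicates))
      rows <- make_metacell_rows(x, groups, "random", day, ids)
      out_meta[[length(out_meta) + 1]] <- rows$meta
      out_expr[[length(out_expr) + 1]] <- rows$expr
      out_members <- c(out_members, rows$members)
    }
  }
  if (length(skipped))
    warning("strata below ", n_per_metacell, " cells skipped: ",
            paste(skipped, collapse = "; "))
  if (!length(out_meta)) stop("every stratum was below n_per_metacell")
  metacell_set(do.call(rbind, out_meta), do.call(rbind, out_expr), out_members,
               x$gene_ids, x$time_grid,
               provenance = list(method = "random",
                                 params = list(n_per_metacell = n_per_metacell,
                                               n_replicates = n_replicates),
                                 seed = seed))
}

#' Pseudobulk aggregation
#'
#' One pseudo-sample per (sample, cell type) stratum (`by = "sample_type"`)
#' or per sample across all cells (`by = "sample"`): raw counts are summed
#' and the sums normalized as `ln(1 + sum / total * scale_factor)`. Empty
#' strata are omitted.
#'
#' @param x an [aem()] with raw counts.
#' @param by stratification mode.
#' @param scale_factor library-size scale factor.
#' @return A `metacell_set` with `method = "pseudobulk"`.
#' @export
aggregate_pseudobulk <- function(x, by = c("sample_type", "sample"),
                                 scale_factor = 1e4) {
  by <- match.arg(by)
  stopifnot(inherits(x, "aem"))
  infected <- x$cell_meta$severity != "control"
  key <- if (by == "sample_type")
    paste(x$cell_meta$sample_id, x$cell_meta$cell_type, sep = "|")
  else x$cell_meta$sample_id
  groups <- split(which(infected), key[infected])
  groups <- groups[vapply(groups, length, 1L) > 0]
  meta_rows <- list(); expr <- matrix(0, length(groups), ncol(x$counts))
  members <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    mem <- groups[[i]]
    sums <- Matrix::colSums(x$counts[mem, , drop = FALSE])
    expr[i, ] <- log1p(sums / sum(sums) * scale_factor)
    tp <- assign_type_and_purity(x$cell_meta$cell_type[mem])
    meta_rows[[i]] <- data.frame(
      id = paste0("PB_", gsub("[|]", "_", names(groups)[i])),
      method = "pseudobulk",
      day = x$cell_meta$day[mem[1]],
      cell_type = if (by == "sample_type") tp$cell_type else "all",
      purity = tp$purity,
      n_members = length(mem),
      sample_id = x$cell_meta$sample_id[mem[1]],
      severity = modal_label(x$cell_meta$severity[mem]),
      stringsAsFactors = FALSE)
    members[[i]] <- x$cell_meta$cell_id[mem]
  }
  meta <- do.call(rbind, meta_rows)
  metacell_set(meta, expr, members, x$gene_ids, x$time_grid,
               provenance = list(method = "pseudobulk",
                                 params = list(by = by, scale_factor = scale_factor)))
}

#' Treat single cells as degenerate metacells
#'
#' Wraps each (non-control) cell as a singleton unit so the individual-cell
#' regression comparator can run through the same statistics interface.
#'
#' @param x an [aem()] with a normalized layer.
#' @return A `metacell_set` with `method = "single_cell"`.
#' @export
as_single_cell_set <- function(x) {
  x <- ensure_normalized(x)
  keep <- which(x$cell_meta$severity != "control")
  meta <- data.frame(id = x$cell_meta$cell_id[keep], method = "single_cell",
                     day = x$cell_meta$day[keep],
                     cell_type = x$cell_meta$cell_type[keep], purity = 1,
                     n_members = 1L, sample_id = x$cell_meta$sample_id[keep],
                     severity = x$cell_meta$severity[keep],
                     stringsAsFactors = FALSE)
  metacell_set(meta, as.matrix(x$normalized[keep, , drop = FALSE]),
               as.list(x$cell_meta$cell_id[keep]), x$gene_ids, x$time_grid,
               provenance = list(method = "single_cell"))
}

#' Filter a metacell set for analysis
#'
#' Applies the pre-analysis exclusions: cell types whose total member cell
#' count is below `min_cells_per_type` are removed; optionally only
#' metacells above a purity threshold are kept (0.95 reproduces the "pure
#' sMetacell" subset); per-type day masks drop listed days for listed types
#' (e.g. dropping early days for a sparsely sampled type).
#'
#' @param ms a `metacell_set`.
#' @param min_cells_per_type minimum total member cells per assigned type
#'   (default 500; set 0 to disable).
#' @param purity_min optional purity threshold in `[0, 1]`.
#' @param day_masks named list mapping cell type -> days to drop.
#' @return The filtered `metacell_set`.
#' @export
filter_for_analysis <- function(ms, min_cells_per_type = 500,
                                purity_min = NULL, day_masks = NULL) {
  stopifnot(inherits(ms, "metacell_set"))
  keep <- rep(TRUE, nrow(ms$meta))
  if (min_cells_per_type > 0) {
    totals <- tapply(ms$meta$n_members, ms$meta$cell_type, sum)
    low <- names(totals)[totals < min_cells_per_type]
    keep <- keep & !(ms$meta$cell_type %in% low)
  }
  if (!is.null(purity_min)) keep <- keep & ms$meta$purity > purity_min
  if (!is.null(day_masks)) {
    for (ty in names(day_masks))
      keep <- keep & !(ms$meta$cell_type == ty & ms$meta$day %in% day_masks[[ty]])
  }
  if (!any(keep)) stop("filter removed all metacells")
  metacell_set(ms$meta[keep, , drop = FALSE],
               ms$expression[keep, , drop = FALSE],
               ms$members[keep], ms$gene_ids, ms$time_grid,
               provenance = c(ms$provenance,
                              list(filter = list(min_cells_per_type = min_cells_per_type,
                                                 purity_min = purity_min,
                                                 day_masks = day_masks))))
}
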