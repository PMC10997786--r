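# Independent oracles kept deliberately separate from the implementation
# paths they check.

# Normal-equations quadratic OLS + F/t distribution oracle.
oracle_quadratic <- function(times, values) {
  X <- cbind(1, times, times^2)
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% values
  fitted <- drop(X %*% beta)
  n <- length(values)
  sse <- sum((values - fitted)^2)
  sst <- sum((values - mean(values))^2)
  Fstat <- ((sst - sse) / 2) / (sse / (n - 3))
  sigma2 <- sse / (n - 3)
  se <- sqrt(sigma2 * diag(XtXi))
  tstat <- drop(beta) / se
  list(C = unname(beta[1]), B = unname(beta[2]), A = unname(beta[3]),
       R2 = 1 - sse / sst, F = unname(Fstat),
       p_F = unname(stats::pf(Fstat, 2, n - 3, lower.tail = FALSE)),
       p_A = unname(2 * stats::pt(abs(tstat[3]), n - 3, lower.tail = FALSE)))
}

# Literal step-up enumeration of BH (no cummin shortcut).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- seq(i, m)
    q[ord[i]] <- min(1, min(p[ord[j]] * m / j))
  }
  q
}

# Mean silhouette width over all points (euclidean), brute force.
mean_silhouette <- function(X, labels) {
  d <- as.matrix(dist(X))
  n <- nrow(X)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Small default simulation shared by several test files.
tiny_sim <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_cell_types = 3, cells_per_type_day = 40,
         n_genes = 240, n_de_per_trend = 4, type_marker_n = 12,
         state_marker_n = 8),
    list(...))
  simulate_timecourse(do.call(sim_config, args))
}

tiny_aem <- function(seed = 11, ...) tiny_sim(seed, ...)$matrix
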