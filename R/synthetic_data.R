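## Seeded negative-binomial time-course simulator with planted temporal
## programs, cell types, within-type states, patients and severity labels.
## Counts are drawn as NB(mu = libsize * exp(log-mean), size = 1/dispersion)
## with all systematic effects (trend, type/state markers, patient offsets,
## severity steepening, lognormal noise) entering on the log scale.

#' Simulation configuration
#'
#' Captures the stated world the generator emulates: a 10-day PBMC-style
#' time course with several cell types, two transcriptomic states per type,
#' a small patient pool with 1-3 samples per day, severity labels, and
#' planted temporal gene programs covering all eight velocity-trend shapes.
#'
#' @param seed integer seed; mandatory, there is no unseeded generation.
#' @param time_grid sampling days (default [covid_time_grid()]).
#' @param n_cell_types,n_states_per_type number of cell types and of
#'   within-type transcriptomic states.
#' @param cells_per_type_day cells simulated per (cell type, day).
#' @param n_genes total genes.
#' @param n_de_per_trend planted DE genes per trend class (8 classes).
#' @param amplitude planted trajectory range over the window, in natural-log
#'   units of expression.
#' @param noise_sd SD of the lognormal cell-level noise on the log scale.
#' @param libsize_sdlog,libsize_meanlog lognormal library-size factor
#'   parameters; `libsize_meanlog = NULL` centres the factor at mean 1.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param baseline_meanlog,baseline_sdlog per-gene baseline log-mean
#'   distribution.
#' @param n_patients size of the patient pool.
#' @param patients_per_day number of patients sampled per day.
#' @param severity_map named character vector patient id -> "mild"/"severe";
#'   `NULL` marks the first patient severe, the rest mild.
#' @param severity_multiplier trajectory-steepness multiplier applied to
#'   decreasing (interferon-like) planted genes in severe patients.
#' @param type_marker_n,type_offset genes per cell-type marker block and
#'   their log-offset.
#' @param state_marker_n,state_offset genes per (type, state) marker block
#'   and their log-offset.
#' @param patient_sd SD of per-(patient, gene) random log-offsets.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       time_grid = covid_time_grid(),
                       n_cell_types = 5,
                       n_states_per_type = 2,
                       cells_per_type_day = 120,
                       n_genes = 1000,
                       n_de_per_trend = 25,
                       amplitude = 1.0,
                       noise_sd = 0.2,
                       libsize_sdlog = 0.3,
                       libsize_meanlog = NULL,
                       nb_dispersion = 0.1,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1.0,
                       n_patients = 5,
                       patients_per_day = 2,
                       severity_map = NULL,
                       severity_multiplier = 1.5,
                       type_marker_n = 40,
                       type_offset = 2.5,
                       state_marker_n = 25,
                       state_offset = 2.0,
                       patient_sd = 0.1) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires an explicit seed")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (cfg$cells_per_type_day < 1) stop("cells_per_type_day must be >= 1")
  if (cfg$n_cell_types < 1 || cfg$n_genes < 1) stop("counts must be positive")
  if (cfg$amplitude < 0) stop("amplitude must be >= 0")
  if (any(diff(cfg$time_grid) <= 0)) stop("time_grid must be strictly increasing")
  n_de <- 8 * cfg$n_de_per_trend
  n_marker <- cfg$n_cell_types * cfg$type_marker_n +
    cfg$n_cell_types * cfg$n_states_per_type * cfg$state_marker_n
  if (n_de + n_marker > cfg$n_genes)
    stop("n_genes too small for ", n_de, " DE genes + ", n_marker, " marker genes")
  if (cfg$patients_per_day > cfg$n_patients)
    stop("patients_per_day exceeds n_patients")
  if (is.null(cfg$severity_map)) {
    pid <- paste0("patient", seq_len(cfg$n_patients))
    cfg$severity_map <- setNames(c("severe", rep("mild", cfg$n_patients - 1)), pid)
  }
  class(cfg) <- "sim_config"
  cfg
}

trend_constraint_ok <- function(trend_class, A, B, window) {
  tmin <- window[1]; tmax <- window[2]
  vertex <- if (A != 0) -B / (2 * A) else NA_real_
  switch(trend_class,
    INC_CONST = if (A != 0) "A must be 0 for a constant-velocity trend"
                else if (B <= 0) "B must be > 0 for an increasing trend",
    DEC_CONST = if (A != 0) "A must be 0 for a constant-velocity trend"
                else if (B >= 0) "B must be < 0 for a decreasing trend",
    INC_ACCEL = if (A <= 0) "A must be > 0 for increasing accelerating"
                else if (vertex > tmin) "vertex must be <= window start",
    INC_DECEL = if (A >= 0) "A must be < 0 for increasing decelerating"
                else if (vertex < tmax) "vertex must be >= window end",
    DEC_ACCEL = if (A >= 0) "A must be < 0 for decreasing accelerating"
                else if (vertex > tmin) "vertex must be <= window start",
    DEC_DECEL = if (A <= 0) "A must be > 0 for decreasing decelerating"
                else if (vertex < tmax) "vertex must be >= window end",
    MAXIMA    = if (A >= 0) "A must be < 0 for an interior maximum"
                else if (vertex <= tmin || vertex >= tmax) "vertex must be strictly inside the window",
    MINIMA    = if (A <= 0) "A must be > 0 for an interior minimum"
                else if (vertex <= tmin || vertex >= tmax) "vertex must be strictly inside the window",
    stop("unknown trend class: ", trend_class))
}

#' Evaluate a planted trend's mean log-expression
#'
#' Evaluates `A t^2 + B t + C` after verifying that `(A, B, C)` satisfies
#' the closed-form constraints of the named trend class on the window
#' (sign of the quadratic term, vertex position, endpoint ordering).
#'
#' @param trend_class one of [trend_levels()].
#' @param params list or numeric vector with elements `A`, `B`, `C`.
#' @param t time(s) within the window span.
#' @param window numeric length-2 analysis window (default the span of
#'   [covid_time_grid()]).
#' @return Numeric mean log-expression at `t`.
#' @export
trend_mean_function <- function(trend_class, params, t,
                                window = range(covid_time_grid())) {
  p <- as.list(params)
  A <- p$A; B <- p$B; C <- p$C
  if (any(t < window[1] - 1e-9) || any(t > window[2] + 1e-9))
    stop("t outside the window span")
  bad <- trend_constraint_ok(trend_class, A, B, window)
  if (!is.null(bad)) stop(trend_class, ": ", bad)
  A * t^2 + B * t + C
}

#' Canonical planted parameters for a trend class
#'
#' Emits the maximum-curvature member of each class with trajectory range
#' equal to `amplitude` over the window: linear for the `*_CONST` classes,
#' vertex at the window edge for the accelerating/decelerating classes, and
#' vertex at the window midpoint for `MAXIMA`/`MINIMA`. `C` is chosen so
#' the trajectory has mean zero over the grid days, keeping overall
#' expression level stable when added to a gene's baseline.
#'
#' @param trend_class one of [trend_levels()].
#' @param amplitude trajectory range in log units (> 0).
#' @param grid the days the trajectory will be evaluated on.
#' @return list with `A`, `B`, `C`.
#' @export
canonical_trend_params <- function(trend_class, amplitude = 1.0,
                                   grid = covid_time_grid()) {
  stopifnot(amplitude > 0)
  tmin <- min(grid); tmax <- max(grid)
  if (trend_class %in% c("INC_CONST", "DEC_CONST")) {
    B <- amplitude / (tmax - tmin)
    if (trend_class == "DEC_CONST") B <- -B
    A <- 0
  } else {
    vertex <- switch(trend_class,
                     INC_ACCEL = tmin, DEC_ACCEL = tmin,
                     INC_DECEL = tmax, DEC_DECEL = tmax,
                     MAXIMA = (tmin + tmax) / 2, MINIMA = (tmin + tmax) / 2)
    span <- max((tmin - vertex)^2, (tmax - vertex)^2)
    a <- amplitude / span
    if (trend_class %in% c("INC_DECEL", "DEC_ACCEL", "MAXIMA")) a <- -a
    A <- a; B <- -2 * a * vertex
  }
  C0 <- -mean(A * grid^2 + B * grid)
  # validate against the class's own constraint before emitting
  bad <- trend_constraint_ok(trend_class, A, B, c(tmin, tmax))
  if (!is.null(bad)) stop("internal: canonical params violate ", trend_class, ": ", bad)
  list(A = A, B = B, C = C0)
}

#' Closed-form trend label of exact quadratic parameters
#'
#' Classifies noiseless planted parameters by the same decision procedure as
#' [classify_trend()], treating a nonzero quadratic coefficient as
#' significant and using the exact trajectory values on the grid as the day
#' means. Used to prove that every emitted parameter set reproduces its
#' class.
#'
#' @param params list with `A`, `B`, `C`.
#' @param grid days the trajectory is observed on.
#' @return A trend code.
#' @export
classify_trend_closed_form <- function(params, grid = covid_time_grid()) {
  f <- params$A * grid^2 + params$B * grid + params$C
  classify_trend(list(A = params$A, B = params$B, C = params$C,
                      p_A = if (params$A == 0) 1 else 0),
                 range(grid), f)
}

#' Simulate metareplicate-level expression with planted trends
#'
#' Generates gene x observation matrices directly at the metareplicate
#' level: each planted gene follows its canonical class trajectory plus
#' i.i.d. Gaussian noise, each null gene is flat plus noise. This is the
#' generator used by the power, null-control and generate-fit-classify
#' properties, where metacell construction itself is not under test.
#'
#' @param seed integer seed (mandatory).
#' @param n_per_class planted DE genes per trend class.
#' @param n_null additional flat genes.
#' @param amplitude trajectory range in log units.
#' @param noise_sd Gaussian noise SD per observation.
#' @param replicates_per_day metareplicates per day.
#' @param time_grid sampling days.
#' @param baseline constant added to every trajectory.
#' @return list with `values` (genes x observations), `times` (observation
#'   days) and `truth` (data.frame gene, is_de, trend_class, A, B, C).
#' @export
simulate_trend_replicates <- function(seed, n_per_class = 25, n_null = 0,
                                      amplitude = 1.0, noise_sd = 0.2,
                                      replicates_per_day = 4,
                                      time_grid = covid_time_grid(),
                                      baseline = 5) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  times <- rep(time_grid, each = replicates_per_day)
  classes <- rep(trend_levels(), each = n_per_class)
  n_de <- length(classes)
  n_genes <- n_de + n_null
  gene <- sprintf("gene%04d", seq_len(n_genes))
  truth <- data.frame(gene = gene,
                      is_de = c(rep(TRUE, n_de), rep(FALSE, n_null)),
                      trend_class = c(classes, rep(NA_character_, n_null)),
                      A = 0, B = 0, C = baseline,
                      stringsAsFactors = FALSE)
  values <- matrix(rnorm(n_genes * length(times), sd = noise_sd),
                   nrow = n_genes, dimnames = list(gene, NULL))
  for (i in seq_len(n_de)) {
    p <- canonical_trend_params(classes[i], amplitude, time_grid)
    truth$A[i] <- p$A; truth$B[i] <- p$B; truth$C[i] <- p$C + baseline
    values[i, ] <- values[i, ] + p$A * times^2 + p$B * times + p$C + baseline
  }
  if (n_null > 0) values[(n_de + 1):n_genes, ] <- values[(n_de + 1):n_genes, ] + baseline
  list(values = values, times = times, truth = truth)
}

#' Simulate a full time-course count matrix with planted programs
#'
#' Draws a cells x genes negative-binomial count matrix over the
#' configuration's time grid. Per-gene log-means combine a lognormal
#' baseline, the planted class trajectory for DE genes, cell-type marker
#' and within-type state-marker offsets, per-(patient, gene) random
#' offsets, and lognormal cell-level noise; severe patients' decreasing
#' planted genes are steepened by the severity multiplier. Fully
#' reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an [aem()] with the normalized layer
#'   computed) and `truth` (list of `genes` and `cells` data.frames).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  days <- cfg$time_grid
  types <- paste0("type", seq_len(cfg$n_cell_types))
  states <- seq_len(cfg$n_states_per_type)
  gene <- sprintf("gene%04d", seq_len(cfg$n_genes))

  ## gene roles: [DE block][type-marker blocks][state-marker blocks][rest]
  n_de <- 8 * cfg$n_de_per_trend
  de_class <- rep(trend_levels(), each = cfg$n_de_per_trend)
  idx <- n_de
  type_markers <- list()
  for (ty in types) {
    type_markers[[ty]] <- if (cfg$type_marker_n > 0) idx + seq_len(cfg$type_marker_n) else integer(0)
    idx <- idx + cfg$type_marker_n
  }
  state_markers <- list()
  for (ty in types) for (s in states) {
    key <- paste0(ty, "_s", s)
    state_markers[[key]] <- if (cfg$state_marker_n > 0) idx + seq_len(cfg$state_marker_n) else integer(0)
    idx <- idx + cfg$state_marker_n
  }

  baseline <- rnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  traj <- matrix(0, nrow = 3, ncol = cfg$n_genes)  # A, B, C rows
  if (n_de > 0 && cfg$amplitude > 0) {
    for (i in seq_len(n_de)) {
      p <- canonical_trend_params(de_class[i], cfg$amplitude, days)
      stopifnot(identical(classify_trend_closed_form(p, days), de_class[i]))
      traj[, i] <- c(p$A, p$B, p$C)
    }
  }

  pid <- names(cfg$severity_map)
  patient_off <- matrix(rnorm(cfg$n_patients * cfg$n_genes, sd = cfg$patient_sd),
                        nrow = cfg$n_patients, dimnames = list(pid, NULL))

  ## cell table: deterministic layout, per day x type x state x patient
  meta_list <- list()
  for (di in seq_along(days)) {
    day_pids <- pid[((2 * (di - 1) + seq_len(cfg$patients_per_day) - 1) %% cfg$n_patients) + 1]
    for (ty in types) {
      n <- cfg$cells_per_type_day
      state <- rep(states, length.out = n)
      patient <- rep(day_pids, length.out = n)
      meta_list[[length(meta_list) + 1]] <- data.frame(
        day = days[di], cell_type = ty, state = state, patient_id = patient,
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta_list)
  n_cells <- nrow(meta)
  meta$cell_id <- sprintf("cell%05d", seq_len(n_cells))
  meta$sample_id <- sprintf("d%02d_%s", meta$day, meta$patient_id)
  meta$severity <- unname(cfg$severity_map[meta$patient_id])

  meanlog <- if (is.null(cfg$libsize_meanlog)) -cfg$libsize_sdlog^2 / 2 else cfg$libsize_meanlog
  libsize <- rlnorm(n_cells, meanlog, cfg$libsize_sdlog)

  ## log-mean per cell x gene
  logmu <- matrix(baseline, nrow = n_cells, ncol = cfg$n_genes, byrow = TRUE)
  if (n_de > 0 && cfg$amplitude > 0) {
    tmat <- cbind(meta$day^2, meta$day, 1)           # cells x 3
    de_val <- tmat %*% traj[, seq_len(n_de), drop = FALSE]
    steep <- ifelse(meta$severity == "severe", cfg$severity_multiplier, 1)
    dec <- grepl("^DEC", de_class)
    de_val[, dec] <- de_val[, dec] * steep
    logmu[, seq_len(n_de)] <- logmu[, seq_len(n_de)] + de_val
  }
  for (ty in types) {
    rows <- meta$cell_type == ty
    logmu[rows, type_markers[[ty]]] <- logmu[rows, type_markers[[ty]]] + cfg$type_offset
    for (s in states) {
      key <- paste0(ty, "_s", s)
      r2 <- rows & meta$state == s
      logmu[r2, state_markers[[key]]] <- logmu[r2, state_markers[[key]]] + cfg$state_offset
    }
  }
  logmu <- logmu + patient_off[meta$patient_id, , drop = FALSE]
  if (cfg$noise_sd > 0)
    logmu <- logmu + matrix(rnorm(n_cells * cfg$n_genes, sd = cfg$noise_sd),
                            nrow = n_cells)
  mu <- libsize * exp(logmu)
  counts <- matrix(rnbinom(n_cells * cfg$n_genes, mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = n_cells)
  zero_tot <- rowSums(counts) == 0
  if (any(zero_tot)) counts[zero_tot, 1] <- 1L  # keep every cell normalizable

  cell_meta <- meta[, c("cell_id", "sample_id", "patient_id", "day",
                        "cell_type", "severity")]
  mat <- aem(counts, cell_meta, gene, time_grid = days)
  mat <- ensure_normalized(mat)

  affected <- paste(types, collapse = ",")
  genes_truth <- data.frame(
    gene = gene,
    is_de = seq_len(cfg$n_genes) <= n_de,
    trend_class = c(de_class, rep(NA_character_, cfg$n_genes - n_de)),
    A = traj[1, ], B = traj[2, ], C = traj[3, ] + baseline,
    affected_cell_types = ifelse(seq_len(cfg$n_genes) <= n_de, affected, ""),
    stringsAsFactors = FALSE)
  cells_truth <- cbind(cell_meta, state = meta$state)
  list(matrix = mat, truth = list(genes = genes_truth, cells = cells_truth),
       config = cfg)
}
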