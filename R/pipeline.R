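## Orchestration: a single JSON-serializable run configuration, staged
## execution (simulate -> metacells -> degs -> trends -> diagnostics) with
## one mandatory seed, and a subcommand CLI.

#' Pipeline run configuration
#'
#' @param seed mandatory integer seed governing every random stage.
#' @param sim a [sim_config()] or list of its arguments; `NULL` disables
#'   simulation (then `input_dir` must point at MTX + TSV inputs).
#' @param input_dir directory with `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `cell_meta.tsv` (ignored when `sim` is given).
#' @param ratio cells per sMetacell.
#' @param day_overrides named per-day sMetacell count overrides (e.g.
#'   `list("28" = 20)`).
#' @param k kernel neighbourhood size.
#' @param n_per_metacell,n_replicates rMetacell parameters.
#' @param alpha,r2_min,min_n,min_cells_per_type DEG-test parameters.
#' @param day_masks named list cell type -> days to drop before testing.
#' @param scale_factor normalization scale factor.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, sim = NULL, input_dir = NULL,
                       ratio = 75, day_overrides = list("28" = 20), k = 15,
                       n_per_metacell = 20, n_replicates = 3,
                       alpha = 0.05, r2_min = 0.5, min_n = 4,
                       min_cells_per_type = 500, day_masks = NULL,
                       scale_factor = 1e4) {
  if (missing(seed) || is.null(seed)) stop("run_config requires a seed")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (is.null(cfg$sim) && is.null(cfg$input_dir))
    stop("either sim or input_dir must be supplied")
  class(cfg) <- "run_config"
  cfg
}

log_line <- function(con, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  writeLines(msg, con)
  message(msg)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

config_to_json <- function(cfg) {
  ser <- lapply(unclass(cfg), function(v) if (inherits(v, "sim_config")) unclass(v) else v)
  jsonlite::toJSON(ser, auto_unbox = TRUE, null = "null", pretty = TRUE,
                   digits = NA)
}

#' Run the full metacell time-course pipeline
#'
#' Stages: (optional) simulation, normalization and embedding, metacell
#' construction by all three strategies, analysis filtering, per-type and
#' all-cells DEG testing, trend classification, and variance diagnostics.
#' Every output is a TSV written under `out_dir`, alongside the resolved
#' configuration (`config.json`) and a line-delimited log recording item
#' counts in and out of each filter. Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; partial outputs are retained on error.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  writeLines(config_to_json(config), file.path(out_dir, "config.json"))

  stage <- "simulate"
  result <- tryCatch({
    if (!is.null(config$sim)) {
      sim_cfg <- if (inherits(config$sim, "sim_config")) config$sim
                 else do.call(sim_config, c(config$sim, list(seed = config$seed)))
      sim <- simulate_timecourse(sim_cfg)
      mat <- sim$matrix
      write_expression_matrix(mat, file.path(out_dir, "simulated"))
      write_tsv(sim$truth$genes, file.path(out_dir, "truth_genes.tsv"))
      write_tsv(sim$truth$cells, file.path(out_dir, "truth_cells.tsv"))
      log_line(logf, stage, nrow(mat$counts), " cells x ", ncol(mat$counts),
               " genes simulated (seed ", sim_cfg$seed, ")")
    } else {
      mat <- read_expression_matrix(
        file.path(config$input_dir, "matrix.mtx"),
        file.path(config$input_dir, "features.tsv"),
        file.path(config$input_dir, "barcodes.tsv"),
        file.path(config$input_dir, "cell_meta.tsv"))
      log_line(logf, stage, "loaded ", nrow(mat$counts), " cells from ",
               config$input_dir)
    }

    stage <- "preprocess"
    mat <- ensure_normalized(mat, config$scale_factor)
    hvg <- select_hvgs(mat, min(500, ncol(mat$counts)))
    emb <- compute_embedding(mat, hvg)
    log_line(logf, stage, length(hvg), " HVGs, ", ncol(emb), " components")

    stage <- "metacells"
    smc <- construct_smetacells(mat, emb, ratio = config$ratio,
                                day_overrides = config$day_overrides,
                                k = config$k, seed = config$seed)
    rmc <- construct_rmetacells(mat, config$n_per_metacell,
                                config$n_replicates, seed = config$seed)
    pb <- aggregate_pseudobulk(mat, scale_factor = config$scale_factor)
    for (nm in c("smetacells", "rmetacells", "pseudobulk")) {
      ms <- list(smetacells = smc, rmetacells = rmc, pseudobulk = pb)[[nm]]
      write_tsv(ms$meta, file.path(out_dir, paste0(nm, "_meta.tsv")))
      write_tsv(cbind(id = ms$meta$id, as.data.frame(ms$expression)),
                file.path(out_dir, paste0(nm, "_expression.tsv")))
      memb <- data.frame(id = rep(ms$meta$id, lengths(ms$members)),
                         cell_id = unlist(ms$members))
      write_tsv(memb, file.path(out_dir, paste0(nm, "_membership.tsv")))
      log_line(logf, stage, nm, ": ", nrow(ms$meta), " units")
    }

    stage <- "filter"
    smc_f <- filter_for_analysis(smc, config$min_cells_per_type,
                                 day_masks = config$day_masks)
    log_line(logf, stage, nrow(smc$meta), " -> ", nrow(smc_f$meta),
             " sMetacells after type/day filters")

    stage <- "degs"
    per_type <- find_timecourse_degs(smc_f, config$alpha, config$r2_min,
                                     "per-type", config$min_n)
    all_cells <- find_timecourse_degs(smc_f, config$alpha, config$r2_min,
                                      "all-cells", config$min_n)
    write_tsv(per_type$fits, file.path(out_dir, "fits_per_type.tsv"))
    write_tsv(all_cells$fits, file.path(out_dir, "fits_all_cells.tsv"))
    log_line(logf, stage, nrow(per_type$fits), " fits, ",
             nrow(per_type$degs), " per-type DEGs; ",
             nrow(all_cells$degs), " all-cells DEGs")

    stage <- "trends"
    degs <- assign_trends(per_type$degs, smc_f, alpha = config$alpha)
    degs_all <- assign_trends(all_cells$degs, smc_f, alpha = config$alpha)
    write_tsv(degs, file.path(out_dir, "degs_per_type.tsv"))
    write_tsv(degs_all, file.path(out_dir, "degs_all_cells.tsv"))
    log_line(logf, stage, "trends assigned (",
             paste(names(table(degs$trend)), table(degs$trend),
                   sep = "=", collapse = ", "), ")")

    stage <- "diagnostics"
    vr <- variance_report(list(smetacells = smc, rmetacells = rmc))
    write_tsv(vr$per_stratum, file.path(out_dir, "variance_per_stratum.tsv"))
    write_tsv(vr$grand, file.path(out_dir, "variance_grand.tsv"))
    if (!is.null(vr$comparisons))
      write_tsv(vr$comparisons, file.path(out_dir, "variance_comparisons.tsv"))
    gd <- rbind(genes_detected(smc)$per_unit, genes_detected(rmc)$per_unit)
    write_tsv(gd, file.path(out_dir, "genes_detected.tsv"))
    if (nrow(degs)) {
      sev <- severity_expression_table(smc, unique(degs$gene))
      write_tsv(sev, file.path(out_dir, "severity_expression.tsv"))
    }
    log_line(logf, stage, "variance + detection diagnostics written")
    TRUE
  }, error = function(e) {
    log_line(logf, stage, "ERROR: ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out_dir)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `metacells`, `degs`, `trends`, `diagnose`,
#' `run-all`. All read a JSON config (`--config`) or fall back to package
#' defaults, require `--seed`, and write into `--out`. `run-all` executes
#' every stage; the individual subcommands run the same pipeline but are
#' provided for discoverability of the stage outputs.
#'
#' @param args character vector of command-line arguments (default: the
#'   actual command line).
#' @return Exit status 0 invisibly on success.
#' @export
metareplicate_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: metareplicate <simulate|metacells|degs|trends|diagnose|run-all> ",
         "--seed N --out DIR [--config FILE]")
  cmd <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--seed", type = "integer"),
      optparse::make_option("--out", type = "character", default = "metareplicate_out"),
      optparse::make_option("--config", type = "character", default = NULL))),
    args = args[-1])
  if (is.null(opts$seed)) stop("--seed is mandatory")
  extra <- if (!is.null(opts$config))
    jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()
  extra$seed <- opts$seed
  if (is.null(extra$sim) && is.null(extra$input_dir)) extra$sim <- list()
  cfg <- do.call(run_config, extra)
  known <- c("simulate", "metacells", "degs", "trends", "diagnose", "run-all")
  if (!cmd %in% known) stop("unknown subcommand: ", cmd)
  if (cmd == "simulate") {
    sim_cfg <- if (inherits(cfg$sim, "sim_config")) cfg$sim
               else do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    sim <- simulate_timecourse(sim_cfg)
    write_expression_matrix(sim$matrix, opts$out)
    write_tsv(sim$truth$genes, file.path(opts$out, "truth_genes.tsv"))
    write_tsv(sim$truth$cells, file.path(opts$out, "truth_cells.tsv"))
    writeLines(jsonlite::toJSON(unclass(sim_cfg), auto_unbox = TRUE,
                                null = "null", pretty = TRUE, digits = NA),
               file.path(opts$out, "sim_config.json"))
  } else {
    run_pipeline(cfg, opts$out)
  }
  invisible(0L)
}
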