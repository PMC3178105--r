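#' Default run configuration
#'
#' Configuration for [run_pipeline()]: a nested list with blocks
#' `simulation` (n, n_unknown, missing_rate, error_rate, map = "default"
#' or "reduced"), `scan` (step, eps, n_perm, alphas), `error_check` (eps,
#' cutoff) and `diagnostics` (window_bp, step_bp, cM_per_Mb), plus a
#' top-level `seed`.  `read_run_config()` reads a YAML file and merges it
#' over these defaults.
#'
#' @return A configuration list.
#' @export
default_config <- function() {
  list(seed = 1,
       simulation = list(n_progeny = 520, n_unknown = 53, missing_rate = 0.01,
                         error_rate = 5e-4, map = "reduced"),
       scan = list(step = 1, eps = 1e-4, n_perm = 200,
                   alphas = c(0.05, 0.01)),
       error_check = list(eps = 1e-4, cutoff = 4),
       diagnostics = list(window_bp = 5e6, step_bp = 1e6, cM_per_Mb = 1.2))
}

#' @rdname default_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  stopifnot(cfg$simulation$missing_rate >= 0, cfg$simulation$missing_rate <= 1,
            cfg$simulation$error_rate >= 0, cfg$simulation$error_rate <= 1,
            cfg$simulation$n_unknown <= cfg$simulation$n_progeny,
            cfg$scan$step >= 0, cfg$scan$eps > 0, cfg$scan$eps < 0.5)
  cfg
}

.cfg_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the full simulated-cross analysis pipeline
#'
#' Simulates a cross, summarizes its map, computes genotype error flags,
#' runs the binary-trait scan with permutation thresholds, LOD-drop
#' support intervals, variance-explained estimates and the two-locus
#' table, and runs the genetic-vs-physical map diagnostics.  All tables
#' are written as TSV into `outdir` together with a JSON run summary and
#' a log file.  The run is deterministic given the configuration seed.
#'
#' @param config A configuration list ([default_config()]) or the path
#'   to a YAML file.
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages?
#' @return The run summary, invisibly (also written to
#'   `outdir/summary.json`).
#' @export
run_pipeline <- function(config = default_config(), outdir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    note("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  note("binqtl ", as.character(utils::packageVersion("binqtl")),
       ", seed ", config$seed, ", config md5 ", .cfg_hash(config))

  sim <- config$simulation
  map <- if (identical(sim$map, "default")) default_map() else reduced_map()
  model <- default_penetrance(map)
  cross <- stage("simulate", sim_cross(
    n = sim$n_progeny, map = map, model = model, n_unknown = sim$n_unknown,
    missing_rate = sim$missing_rate, error_rate = sim$error_rate,
    seed = config$seed))
  write_cross(cross, file.path(outdir, "cross.csv"))
  physmap <- sim_physical_map(map, config$diagnostics$cM_per_Mb)
  write_physical_map(physmap, file.path(outdir, "physmap.tsv"))

  msum <- stage("map summary", map_summary(map, n_meioses = 2 * sim$n_progeny))

  flags <- stage("error LOD", calc_error_lod(
    cross, eps = config$error_check$eps, cutoff = config$error_check$cutoff))
  fsum <- flag_summary(flags)
  utils::write.table(flags[flags$flagged, , drop = FALSE],
                     file.path(outdir, "error_flags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sc <- config$scan
  gp <- stage("genotype probabilities", genoprob(cross, sc$step, sc$eps))
  scan <- stage("scan", scan_binary(cross, sc$step, sc$eps, gp = gp))
  utils::write.table(scan$result, file.path(outdir, "scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  perm <- stage("permutations", perm_threshold(
    cross, n_perm = sc$n_perm, alphas = sc$alphas, step = sc$step,
    eps = sc$eps, seed = config$seed + 1L, gp = gp))
  peaks <- summary(scan, thresholds = perm$thresholds)
  utils::write.table(peaks, file.path(outdir, "peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  model_loci <- data.frame(chr = c(model$locus1$chr, model$locus2$chr),
                           pos = c(model$locus1$pos, model$locus2$pos))
  ve <- stage("variance explained",
              variance_explained(cross, model_loci, gp = gp))
  tl <- stage("two-locus table", two_locus_table(
    cross, list(chr = model$locus1$chr, pos = model$locus1$pos),
    list(chr = model$locus2$chr, pos = model$locus2$pos)))
  utils::write.table(tl$table, file.path(outdir, "two_locus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rates <- stage("recombination rate", recomb_rate(
    map, physmap, config$diagnostics$window_bp, config$diagnostics$step_bp))
  utils::write.table(rates, file.path(outdir, "recomb_rate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = config$seed,
    config_md5 = .cfg_hash(config),
    package_version = as.character(utils::packageVersion("binqtl")),
    map = msum,
    error_flags = fsum,
    thresholds = as.list(perm$thresholds),
    peaks = peaks[, c("chr", "pos", "lod", "ci_lo", "ci_hi", "signif")],
    variance_pct = list(per_locus = ve$per_locus, joint = ve$joint),
    epistasis_lod = tl$epistasis_lod,
    genome_mean_cM_per_Mb = attr(rates, "genome_mean"))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  note("done")
  invisible(summary)
}
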