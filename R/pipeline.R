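# Orchestration: a single run() over the stages simulate -> cv -> fit ->
# report -> recover, a manifest of every artifact, and a small CLI
# dispatcher. Configuration is a plain named list (or a JSON file).

#' Default run configuration
#'
#' @param out_dir output directory (created if needed).
#' @param map,genotypes,phenotypes,genes optional input TSV paths; when map /
#'   genotypes / phenotypes are absent a synthetic dataset is generated.
#' @param trait trait column to analyze (default first).
#' @param model "full" (all pairwise interactions) or "main_effects_only".
#' @param prior either list(a=, b=) or the string "cv" (exactly one mode).
#' @param alpha significance level (default 0.01).
#' @param radius_cM grouping/gene-association radius (default 20).
#' @param highlight_cM gene highlight radius (default 2).
#' @param seed master seed.
#' @param tol,max_sweeps,block_size solver controls.
#' @param sim named list overriding [sim_config()] fields.
#' @param truth optional truth JSON path for recovery scoring.
#' @param tol_cM recovery mapping tolerance (default 5).
#' @return named list.
#' @export
run_config <- function(out_dir, map = NULL, genotypes = NULL, phenotypes = NULL,
                       genes = NULL, trait = NULL, model = "full",
                       prior = list(a = 0.5, b = 0.5), alpha = 0.01,
                       radius_cM = 20, highlight_cM = 2, seed = 1,
                       tol = 1e-4, max_sweeps = 50, block_size = 256,
                       sim = list(), truth = NULL, tol_cM = 5) {
  cfg <- as.list(environment())
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!cfg$model %in% c("full", "main_effects_only")) {
    stop("model must be 'full' or 'main_effects_only'")
  }
  cv_mode <- identical(cfg$prior, "cv")
  explicit <- is.list(cfg$prior) && all(c("a", "b") %in% names(cfg$prior))
  if (cv_mode == explicit) stop("prior must be exactly one of list(a, b) or \"cv\"")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  invisible(cfg)
}

#' Run the whole pipeline
#'
#' Stages, in order: load or simulate inputs; cross-validate (a, b) if
#' requested; fit the empirical-Bayes Lasso; write the report tables; score
#' recovery against the planted truth when available. Every output file is
#' recorded in `manifest.json`; identical configurations produce identical
#' artifacts.
#'
#' @param config a [run_config()] list or path to a JSON file of one.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- formals(run_config)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]]) && !identical(nm, "out_dir")) {
      config[[nm]] <- eval(defaults[[nm]])
    }
  }
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage_order <- character(0)
  emit <- function(name) {
    files <<- c(files, name)
    file.path(out, name)
  }
  logmsg <- function(...) message("[epiQTL] ", sprintf(...))

  # --- stage: inputs ---
  truth <- NULL
  if (is.null(config$map) || is.null(config$genotypes) || is.null(config$phenotypes)) {
    stage_order <- c(stage_order, "simulate")
    sim_args <- utils::modifyList(list(seed = config$seed), as.list(config$sim))
    cfg <- do.call(sim_config, sim_args)
    ds <- simulate_imf2_dataset(cfg)
    map <- ds$map; G <- ds$G; y <- ds$y; truth <- ds$truth
    write_bin_map(map, emit("map.tsv"))
    write_genotypes(G, emit("genotypes.tsv"))
    write_phenotypes(y, emit("phenotypes.tsv"))
    write_truth(truth, emit("truth.json"))
    logmsg("simulated %d individuals x %d bins (seed %d)", nrow(G), ncol(G), cfg$seed)
  } else {
    stage_order <- c(stage_order, "load")
    map <- read_bin_map(config$map)
    G <- read_genotypes(config$genotypes, map)
    y <- read_phenotypes(config$phenotypes, trait = config$trait, G = G)
    if (!is.null(config$truth)) truth <- read_truth(config$truth)
  }
  catalog <- if (!is.null(config$genes)) read_gene_catalog(config$genes, map)
  include_int <- config$model == "full"
  spec <- design_spec(G, include_int)
  logmsg("%s model: k = %s candidate effects", config$model,
         format(spec$k, big.mark = ","))
  controls <- eblasso_controls(tol = config$tol, max_sweeps = config$max_sweeps,
                               block_size = config$block_size)

  # --- stage: cv ---
  if (identical(config$prior, "cv")) {
    stage_order <- c(stage_order, "cv")
    cv <- cv_path(G, y, include_int, controls, seed = config$seed)
    utils::write.table(cv$table, emit("cv_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cv$best, emit("best_ab.json"), auto_unbox = TRUE, digits = NA)
    ab <- cv$best
    logmsg("CV selected (a, b) = (%g, %g)", ab$a, ab$b)
  } else {
    ab <- config$prior
  }

  # --- stage: fit ---
  stage_order <- c(stage_order, "fit")
  fit <- eblasso_fit(G, y, spec, prior_spec(ab$a, ab$b), controls)
  logmsg("fit: %d active effects, converged = %s", nrow(fit$active), fit$converged)

  # --- stage: report ---
  stage_order <- c(stage_order, "report")
  rep_ <- qtl_report(fit, y, map, catalog, alpha = config$alpha,
                     radius = config$radius_cM, highlight = config$highlight_cM)
  write_effect_table(rep_$significant, emit("effects.tsv"),
                     metadata = list(a = ab$a, b = ab$b, mu = fit$mu,
                                     sigma2_e = fit$sigma2_e,
                                     total_h2 = rep_$total_h2))
  if (!is.null(rep_$groups)) {
    utils::write.table(rep_$groups, emit("groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rep_$genes)) {
    utils::write.table(rep_$genes, emit("gene_assoc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  edges <- effect_edges(rep_$significant, map)
  utils::write.table(edges, emit("edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- stage: recover ---
  recovery <- NULL
  if (!is.null(truth)) {
    stage_order <- c(stage_order, "recover")
    recovery <- score_recovery(rep_$significant, truth, map, tol_cM = config$tol_cM)
    jsonlite::write_json(recovery[c("power", "fdr", "fdr_defined", "n_sig")],
                         emit("recovery.json"), auto_unbox = TRUE, digits = NA)
    logmsg("recovery: power = %.3f, FDR = %.3f", recovery$power, recovery$fdr)
  }

  manifest <- list(
    package = "epiQTL",
    version = as.character(utils::packageVersion("epiQTL")),
    config = config[setdiff(names(config), "out_dir")],
    config_hash = config_hash(config),
    seed = config$seed,
    stages = stage_order,
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest, list(fit = fit, report = rep_, recovery = recovery)))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

effect_edges <- function(sig, map) {
  if (!nrow(sig)) {
    return(data.frame(source_bin = character(0), target_bin = character(0),
                      family = character(0), abs_beta = numeric(0)))
  }
  data.frame(source_bin = map$bin_id[sig$i], target_bin = map$bin_id[sig$j],
             family = sig$family, abs_beta = abs(sig$beta_hat),
             stringsAsFactors = FALSE)
}

write_truth <- function(truth, path) {
  jsonlite::write_json(list(effects = truth$effects, mu = truth$mu,
                            sigma2_e = truth$sigma2_e),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_truth(as.data.frame(x$effects), mu = x$mu, sigma2_e = x$sigma2_e)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `cv`, `fit`, `report` (all folded into one
#' `run`), and `recover`. Flags are `--key=value` pairs overriding a JSON
#' `--config=FILE`; `run` executes every configured stage.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status 0 invisibly; stops on error.
#' @export
qtl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: epiqtl <run|simulate|recover> [--config=FILE] [--key=value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[[1]]
  opts <- parse_cli_flags(args[-1])
  config <- if (!is.null(opts$config)) {
    jsonlite::read_json(opts$config, simplifyVector = TRUE)
  } else list()
  config <- utils::modifyList(config, opts[setdiff(names(opts), "config")])
  if (cmd %in% c("run", "fit", "report", "cv", "simulate")) {
    if (cmd == "cv") config$prior <- "cv"
    if (is.null(config$out_dir)) stop("--out_dir required")
    run_pipeline(config)
  } else if (cmd == "recover") {
    # consumes an effects table + truth + map, emits recovery.json
    for (req in c("effects", "truth", "map", "out")) {
      if (is.null(config[[req]])) stop("--", req, " required for recover")
    }
    map <- read_bin_map(config$map)
    eff <- read_effect_table(config$effects)
    fam <- paste0(ifelse(eff$family_i == "add", "A", "D"),
                  ifelse(eff$family_j == "add", "A", "D"))
    fam[eff$locus_i == eff$locus_j] <- ifelse(
      eff$family_i[eff$locus_i == eff$locus_j] == "add", "A", "D")
    reports <- data.frame(family = fam, i = eff$locus_i, j = eff$locus_j)
    truth <- read_truth(config$truth)
    rec <- score_recovery(reports, truth, map,
                          tol_cM = config$tol_cM %||% 5)
    jsonlite::write_json(rec[c("power", "fdr", "fdr_defined", "n_sig")],
                         config$out, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}

parse_cli_flags <- function(args) {
  out <- list()
  for (a in args) {
    if (!grepl("^--[A-Za-z_]+", a)) stop("bad flag: ", a)
    kv <- sub("^--", "", a)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num)) num else val
    } else {
      out[[kv]] <- TRUE
    }
  }
  out
}
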