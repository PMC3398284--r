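#' Run the full competition-analysis pipeline from one configuration
#'
#' Orchestrates simulate -> normalise -> fit -> classify -> enrich ->
#' compare from a single configuration (a nested list or a YAML file path).
#' Stages are run in order; any stage not requested is skipped. All outputs
#' are written under `out_dir` as TSV (plus a JSON run report) and every
#' source of randomness derives from the single `seed`, so identical
#' configurations give identical outputs.
#'
#' Configuration sections (all optional except `seed`):
#' \describe{
#'   \item{simulate}{`n_strains`, `mu_ref`, `mode`, `dilution_rate`,
#'     `sample_times`, `n_bio_reps`, `n_tech_reps`, `depth`, `noise_cv`,
#'     `experiment`, and an `effects` sub-list passed to
#'     [effect_distribution()].}
#'   \item{input}{`matrix`, `samplesheet` (TSV paths) — used when no
#'     simulation stage is requested; `exclusions` (optional path).}
#'   \item{fit}{`alpha`, `pseudocount`, `min_points`.}
#'   \item{enrich}{`gmt` (path), `min_set_size`.}
#'   \item{compare}{`fcc_matrix` (TSV path of gene x experiment FCC'
#'     values); defaults to the fitted results when >= 2 experiments were
#'     fitted.}
#' }
#'
#' @param config Nested list or path to a YAML file.
#' @param out_dir Output directory (created if absent).
#' @param stages Character vector of stages to run, in
#'   `c("simulate", "fit", "enrich", "compare")`.
#' @return The run report (named list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "fit", "enrich", "compare")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)
  # fail fast on referenced input paths
  for (p in c(config$input$matrix, config$input$samplesheet,
              config$input$exclusions, config$enrich$gmt,
              config$compare$fcc_matrix))
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist: ", p, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = stages)
  log_stage <- function(stage, ...)
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)

  dataset <- NULL
  if ("simulate" %in% stages) {
    sc <- config$simulate %||% list()
    eff <- do.call(effect_distribution, sc$effects %||% list())
    log_stage("simulate", "pool of ", sc$n_strains %||% 5800, " strains")
    pool <- sample_pool(sc$n_strains %||% 5800, eff,
                        mu_ref = sc$mu_ref %||% 0.32, seed = config$seed)
    cfg <- culture_config(
      mode = sc$mode %||% "turbidostat",
      dilution_rate = sc$dilution_rate,
      sample_times = sc$sample_times %||% c(0, 24, 48, 72, 96),
      n_bio_reps = sc$n_bio_reps %||% 2, n_tech_reps = sc$n_tech_reps %||% 2,
      depth = sc$depth %||% 1e6, noise_cv = sc$noise_cv %||% 0.2,
      seed = config$seed + 1L)
    traj <- simulate_proportions(pool, cfg)
    dataset <- observe(traj, cfg, experiment = sc$experiment %||% "SIM")
    write_dataset(dataset, file.path(out_dir, "abundance.tsv"),
                  file.path(out_dir, "samples.tsv"))
    truth <- data.frame(strain_id = pool$strain_id, mu = pool$mu,
                        true_fcc = pool$mu - sum(pool$mu * pool$p0))
    utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$simulate <- list(n_strains = nrow(pool),
                            n_samples = ncol(dataset$matrix),
                            mean_mu = mean(pool$mu))
  } else if (!is.null(config$input)) {
    log_stage("input", "reading ", config$input$matrix)
    dataset <- read_dataset(config$input$matrix, config$input$samplesheet)
  }

  fitres <- NULL
  if ("fit" %in% stages) {
    if (is.null(dataset))
      stop("fit stage requires a simulate stage or an input section",
           call. = FALSE)
    if (!is.null(config$input$exclusions))
      dataset <- apply_exclusions(dataset,
                                  read_exclusion_list(config$input$exclusions))
    fc <- config$fit %||% list()
    log_stage("fit", "alpha = ", fc$alpha %||% 0.05)
    fitres <- fit_fitness(dataset,
                          pseudocount = fc$pseudocount %||% 0.5,
                          min_points = fc$min_points %||% 3,
                          alpha = fc$alpha %||% 0.05)
    write_fitness(fitres, file.path(out_dir, "fitness.tsv"))
    tab <- table(factor(fitres$hfc_class, c("HI", "HP", "NS")),
                 useNA = "always")
    report$fit <- list(n_hi = unname(tab["HI"]), n_hp = unname(tab["HP"]),
                       n_ns = unname(tab["NS"]),
                       n_na = sum(is.na(fitres$hfc_class)))
  }

  if ("enrich" %in% stages && !is.null(config$enrich$gmt)) {
    if (is.null(fitres)) stop("enrich stage requires a fit stage",
                              call. = FALSE)
    log_stage("enrich", "gene sets from ", config$enrich$gmt)
    sets <- read_gmt(config$enrich$gmt)
    one_exp <- fitres[fitres$experiment == fitres$experiment[1], ]
    scores <- stats::setNames(one_exp$fcc_prime, one_exp$strain_id)
    enr <- lr_enrichment(scores, sets,
                         min_size = config$enrich$min_set_size %||% 3)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- enr[order(enr$p_value), ]
    report$enrich <- list(n_sets_tested = nrow(enr),
                          top_sets = utils::head(top$set_id, 5))
  }

  if ("compare" %in% stages) {
    fcc_mat <- NULL
    if (!is.null(config$compare$fcc_matrix)) {
      tab <- utils::read.delim(config$compare$fcc_matrix,
                               check.names = FALSE)
      fcc_mat <- as.matrix(tab[, -1, drop = FALSE])
      rownames(fcc_mat) <- tab[[1]]
    } else if (!is.null(fitres) &&
               length(unique(fitres$experiment)) >= 2) {
      fcc_mat <- stats::xtabs(fcc_prime ~ strain_id + experiment,
                              data = fitres)
      fcc_mat <- matrix(fcc_mat, nrow(fcc_mat), ncol(fcc_mat),
                        dimnames = dimnames(fcc_mat))
    }
    if (!is.null(fcc_mat)) {
      log_stage("compare", ncol(fcc_mat), " experiments")
      cm <- correlation_matrix(fcc_mat)
      utils::write.table(cm$rho, file.path(out_dir, "correlation.tsv"),
                         sep = "\t", quote = FALSE)
      hc <- cluster_experiments(cm$rho)
      dendrogram_newick(hc, file.path(out_dir, "experiments.nwk"))
      report$compare <- list(experiments = colnames(cm$rho),
                             rho = cm$rho)
    }
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(report)
}
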