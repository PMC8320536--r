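#' Full pipeline configuration
#'
#' Composes the input paths, the analysis thresholds ([dpcnet_config()]),
#' the synthetic-generator settings and the validation options used by
#' [run_pipeline()] / [run_stage()]. Any nested list may be given
#' partially; it is merged over the defaults.
#'
#' @param input list of paths: `expression`, `labels`, `methylation`,
#'   `methylation_annotation`, `mutations`, `ppi`, optional `ppi_mapping`.
#'   Paths left NULL default to `<output_dir>/inputs/<name>` as written by
#'   the `simulate` stage.
#' @param output_dir directory for stage artifacts and the manifest
#' @param seed integer seed used by `simulate` and `validate`
#' @param analysis list of [dpcnet_config()] arguments
#' @param synthetic list of [synthetic_config()] overrides for `simulate`
#' @param validation list: `folds` (default 5), `oversample` (default TRUE),
#'   `reference_gene_lists` (named character vector of one-symbol-per-line
#'   files for hypergeometric enrichment)
#' @param barcode_prefix see [read_expression()]
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(input = list(), output_dir = tempfile("dpcnet_"),
                            seed = 1, analysis = list(), synthetic = list(),
                            validation = list(), barcode_prefix = 0L) {
  val <- utils::modifyList(
    list(folds = 5, oversample = TRUE, reference_gene_lists = NULL),
    validation)
  structure(list(input = input, output_dir = output_dir, seed = seed,
                 analysis = do.call(dpcnet_config, analysis),
                 synthetic = synthetic, validation = val,
                 barcode_prefix = barcode_prefix),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the [pipeline_config()] arguments; missing fields take
#' the defaults. Fields given on top of a profile file (e.g. the bundled
#' kidney-cancer profile under
#' `system.file("extdata/profiles", package = "dpcnet")`) override it.
#'
#' @param path YAML file
#' @param ... overrides (same names as [pipeline_config()] arguments)
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  dots <- list(...)
  for (nm in names(dots)) {
    y[[nm]] <- if (is.list(y[[nm]]) && is.list(dots[[nm]]))
      utils::modifyList(y[[nm]], dots[[nm]]) else dots[[nm]]
  }
  keep <- intersect(names(y), names(formals(pipeline_config)))
  do.call(pipeline_config, y[keep])
}

# default artifact / input locations inside the output directory
input_path <- function(config, key) {
  p <- config$input[[key]]
  if (!is.null(p)) return(p)
  default <- c(expression = "expression.tsv", labels = "labels.tsv",
               methylation = "methylation.tsv",
               methylation_annotation = "methylation_annotation.tsv",
               mutations = "mutations.tsv", ppi = "ppi.txt")
  file.path(config$output_dir, "inputs", default[[key]])
}

artifact_path <- function(config, name) file.path(config$output_dir, name)

require_artifact <- function(config, name, stage) {
  p <- artifact_path(config, name)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s': run the '%s' stage first", name, stage))
  p
}

has_layer <- function(config, key) file.exists(input_path(config, key))

update_manifest <- function(config, stage, entry) {
  mp <- artifact_path(config, "manifest.json")
  manifest <- if (file.exists(mp))
    jsonlite::read_json(mp, simplifyVector = TRUE) else list()
  manifest$seed <- config$seed
  manifest[[stage]] <- entry
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

read_filtered_expression <- function(config, stage = "preprocess") {
  read_expression(require_artifact(config, "filtered_expression.tsv", stage),
                  require_artifact(config, "labels.tsv", stage))
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `preprocess`, `pccn`, `pcorn`, `diffnet`, `diffmn`,
#' `rank`, `validate`. Each stage reads the previous stage's files from the
#' output directory (an actionable error names the required stage when an
#' artifact is missing), writes its own artifacts, and records its counts
#' in `manifest.json`.
#'
#' @param stage stage name
#' @param config a [pipeline_config()]
#' @return the stage's manifest entry (named list of counts), invisibly
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, c("simulate", "preprocess", "pccn", "pcorn",
                              "diffnet", "diffmn", "rank", "validate"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  entry <- switch(stage,
    simulate = stage_simulate(config),
    preprocess = stage_preprocess(config),
    pccn = stage_pccn(config),
    pcorn = stage_pcorn(config),
    diffnet = stage_diffnet(config),
    diffmn = stage_diffmn(config),
    rank = stage_rank(config),
    validate = stage_validate(config))
  update_manifest(config, stage, entry)
  invisible(entry)
}

stage_simulate <- function(config) {
  syn <- config$synthetic
  if (is.null(syn$seed)) syn$seed <- config$seed
  sim <- simulate_omics(do.call(synthetic_config, syn))
  write_omics(sim, file.path(config$output_dir, "inputs"))
  list(n_genes = sim$config$n_genes,
       n_tumor = sim$config$n_tumor, n_normal = sim$config$n_normal,
       ppi_edges = n_edges(sim$ppi),
       n_disease_genes = length(sim$truth$disease_genes),
       seed = sim$config$seed)
}

stage_preprocess <- function(config) {
  pp <- config$analysis$preprocess
  ed <- read_expression(input_path(config, "expression"),
                        input_path(config, "labels"),
                        barcode_prefix = config$barcode_prefix)
  expr <- filter_expressed_genes(ed$expr, pp$min_expressed_fraction,
                                 pp$presence_threshold)
  ppi <- read_ppi(input_path(config, "ppi"), config$input$ppi_mapping)
  background <- build_background_network(ppi, expr, pp$ppi_min_confidence)
  utils::write.table(
    data.frame(gene = rownames(expr), expr, check.names = FALSE),
    artifact_path(config, "filtered_expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(ed$labels), group = as.character(ed$labels)),
    artifact_path(config, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(background, artifact_path(config, "background.tsv"))
  entry <- list(genes_input = nrow(ed$expr), genes_expressed = nrow(expr),
                ppi_edges = n_edges(ppi),
                background_edges = n_edges(background),
                background_nodes = n_nodes(background))
  if (has_layer(config, "methylation")) {
    meth <- read_methylation(input_path(config, "methylation"),
                             input_path(config, "methylation_annotation"))
    fm <- filter_methylation_sites(meth)
    utils::write.table(
      data.frame(site = rownames(fm$values), fm$values, check.names = FALSE),
      artifact_path(config, "filtered_methylation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(site = names(fm$site_gene), gene = unname(fm$site_gene)),
      artifact_path(config, "filtered_methylation_annotation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    entry$sites_input <- nrow(meth$values)
    entry$sites_kept <- nrow(fm$values)
  }
  entry
}

stage_pccn <- function(config) {
  ed <- read_filtered_expression(config)
  background <- read_network(require_artifact(config, "background.tsv",
                                              "preprocess"))
  alpha <- config$analysis$significance$pearson_alpha
  out <- list()
  for (g in c("tumor", "normal")) {
    net <- build_pccn(ed$expr, background, ed$labels, g, alpha)
    write_network(net, artifact_path(config, sprintf("pccn_%s.tsv", g)))
    out[[paste0("pccn_", g, "_edges")]] <- n_edges(net)
    out[[paste0("pccn_", g, "_nodes")]] <- n_nodes(net)
  }
  out
}

stage_pcorn <- function(config) {
  ed <- read_filtered_expression(config)
  alpha <- config$analysis$significance$partial_alpha
  out <- list()
  for (g in c("tumor", "normal")) {
    pccn <- read_network(require_artifact(config, sprintf("pccn_%s.tsv", g),
                                          "pccn"))
    net <- build_pcorn(pccn, ed$expr, ed$labels, g, alpha,
                       exhaustive_k = config$analysis$exhaustive_k)
    write_network(net, artifact_path(config, sprintf("pcorn_%s.tsv", g)))
    out[[paste0("pcorn_", g, "_edges")]] <- n_edges(net)
    out[[paste0("pcorn_", g, "_nodes")]] <- n_nodes(net)
  }
  out
}

stage_diffnet <- function(config) {
  nt <- read_network(require_artifact(config, "pcorn_tumor.tsv", "pcorn"))
  nn <- read_network(require_artifact(config, "pcorn_normal.tsv", "pcorn"))
  dp <- diff_network(nt, nn)
  write_network(dp, artifact_path(config, "diff_pcorn.tsv"))
  list(common_edges = length(intersect(edge_keys(nt), edge_keys(nn))),
       diff_pcorn_edges = n_edges(dp), diff_pcorn_nodes = n_nodes(dp),
       tumor_origin = sum(dp$edges$origin == "tumor_only"),
       normal_origin = sum(dp$edges$origin == "normal_only"))
}

stage_diffmn <- function(config) {
  dp <- read_network(require_artifact(config, "diff_pcorn.tsv", "diffnet"))
  mv <- require_artifact(config, "filtered_methylation.tsv", "preprocess")
  ma <- require_artifact(config, "filtered_methylation_annotation.tsv",
                         "preprocess")
  meth <- read_methylation(mv, ma)
  labels <- read_labels(require_artifact(config, "labels.tsv", "preprocess"))
  mn <- build_diff_mn(dp, meth, labels,
                      config$analysis$diff_network$meth_score_threshold)
  write_network(mn, artifact_path(config, "diff_mn.tsv"))
  list(diff_mn_edges = n_edges(mn), diff_mn_nodes = n_nodes(mn))
}

stage_rank <- function(config) {
  dp <- read_network(require_artifact(config, "diff_pcorn.tsv", "diffnet"))
  rk <- config$analysis$ranking
  set1 <- degree_filter(dp, rk$diff_pcorn_min_degree)
  if (file.exists(artifact_path(config, "diff_mn.tsv"))) {
    mn <- read_network(artifact_path(config, "diff_mn.tsv"))
    set2 <- degree_filter(mn, rk$diff_mn_min_degree)
  } else {
    mn <- NULL
    set2 <- set1
  }
  mut <- read_mutations(input_path(config, "mutations"))
  freq <- variation_frequency(mut, genes = union(set1, set2))
  cand <- rank_candidates(set1, set2, freq, dp, mn, top_k = rk$top_k)
  utils::write.table(as.data.frame(cand),
                     artifact_path(config, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(candidate_set1 = length(set1), candidate_set2 = length(set2),
       overlap = nrow(cand), selected = sum(cand$selected),
       selected_genes = attr(cand, "selected"))
}

stage_validate <- function(config) {
  cand <- utils::read.delim(require_artifact(config, "candidates.tsv", "rank"),
                            stringsAsFactors = FALSE)
  sel <- cand$gene[cand$selected]
  ed <- read_filtered_expression(config)
  val <- config$validation
  report <- list(selected_genes = sel)
  if (length(sel) >= 1) {
    cls <- classify_cv(ed$expr, sel, ed$labels, folds = val$folds,
                       oversample = val$oversample, seed = config$seed)
    clu <- cluster_samples(ed$expr, sel, ed$labels)
    dt <- per_gene_differential_test(ed$expr, sel, ed$labels)
    report$auc <- cls$auc
    report$fold_count <- cls$fold_count
    report$oversampled <- cls$oversampled
    report$roc_points <- cls$roc_points
    report$normal_cluster_recall <- clu$normal_cluster_recall
    report$differential_expression <- dt
    refs <- val$reference_gene_lists
    if (length(refs)) {
      if (is.null(names(refs))) names(refs) <- basename(unlist(refs))
      universe <- rownames(ed$expr)
      report$enrichment <- lapply(refs, function(f) {
        known <- intersect(readLines(f), universe)
        x <- length(intersect(sel, known))
        list(N = length(universe), M = length(known), n = length(sel), x = x,
             p = hypergeom_tail(length(universe), length(known),
                                length(sel), x))
      })
    }
  }
  jsonlite::write_json(report, artifact_path(config, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report[c("selected_genes", "auc", "normal_cluster_recall")]
}

#' Run the whole pipeline
#'
#' Executes `preprocess`, `pccn`, `pcorn`, `diffnet`, `diffmn` (when a
#' methylation layer is present), `rank` (when mutations are present) and
#' `validate` in order, writing each stage's artifact under
#' `config$output_dir`. With `simulate = TRUE` a synthetic dataset is
#' generated first and used as input. A stage failure aborts with the stage
#' name; stages already completed keep their manifest entries. Re-running
#' with the same inputs, config and seed reproduces the identical manifest.
#'
#' @param config a [pipeline_config()]
#' @param simulate generate synthetic inputs first
#' @return the manifest (named list of per-stage counts)
#' @export
run_pipeline <- function(config, simulate = FALSE) {
  stages <- c(if (simulate) "simulate", "preprocess", "pccn", "pcorn",
              "diffnet")
  for (st in stages) run_pipeline_stage(st, config)
  if (has_layer(config, "methylation") &&
      file.exists(artifact_path(config, "filtered_methylation.tsv")))
    run_pipeline_stage("diffmn", config)
  if (has_layer(config, "mutations")) {
    run_pipeline_stage("rank", config)
    run_pipeline_stage("validate", config)
  }
  jsonlite::read_json(artifact_path(config, "manifest.json"),
                      simplifyVector = TRUE)
}

run_pipeline_stage <- function(st, config) {
  tryCatch(run_stage(st, config),
           error = function(e)
             stop(sprintf("pipeline stage '%s' failed: %s",
                          st, conditionMessage(e)), call. = FALSE))
}
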