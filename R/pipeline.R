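stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Pipeline configuration
#'
#' Bundles every parameter of the end-to-end analysis
#' (simulate/load atlas -> co-expression network -> candidate selection ->
#' screening groups -> optional qPCR screen). The defaults reproduce the
#' reference parameterization of the mining procedure: k = 500 neighbors,
#' top-10 cap per bait, screening groups of up to 4, and the >5-fold
#' overexpression / >2-fold, p < 0.05 advancement gate.
#'
#' @param atlas path to an expression TSV, or `NULL` when `simulate` is
#'   given.
#' @param simulate an [atlas_config()] used to generate the atlas when no
#'   `atlas` path is supplied.
#' @param baits path to a bait gene-list file, or a character vector;
#'   `NULL` with `simulate` uses the planted pathway genes.
#' @param regulators path to a regulator gene-list file, or a character
#'   vector; `NULL` with `simulate` uses the planted regulators.
#' @param qpcr optional qPCR CSV path for the screening stage.
#' @param reference_genes,control,treatment,oe_genes screening-stage
#'   settings (see [normalize_qpcr()], [fold_changes()], [apply_gate()]).
#' @param out_dir output directory for all stage outputs and the manifest.
#' @param k neighborhood size (default 500).
#' @param cap per-bait candidate cap (default 10); `k >= cap` required.
#' @param max_group_size screening-group size limit (default 4).
#' @param oe_threshold,target_threshold,alpha gate thresholds (5, 2, 0.05).
#' @param method similarity method, `"pearson"` or `"spearman"`.
#' @param log_offset pseudo-count for the log2 transform (default 1).
#' @param min_expression optional expression filter (default off).
#' @param seed integer seed controlling all randomness.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(atlas = NULL, simulate = NULL, baits = NULL,
                            regulators = NULL, qpcr = NULL,
                            reference_genes = c("N2227", "SAND"),
                            control = "GUS", treatment = NULL,
                            oe_genes = NULL, out_dir = "coexminer_out",
                            k = 500, cap = 10, max_group_size = 4,
                            oe_threshold = 5, target_threshold = 2,
                            alpha = 0.05,
                            method = c("pearson", "spearman"),
                            log_offset = 1, min_expression = NULL,
                            seed = 1) {
  method <- match.arg(method)
  if (is.null(atlas) && is.null(simulate))
    stop("config needs either an `atlas` path or a `simulate` atlas_config")
  if (!is.null(simulate) && !inherits(simulate, "atlas_config"))
    stop("`simulate` must be an atlas_config()")
  if (!is.numeric(k) || !is.numeric(cap) || cap < 1 || k < cap)
    stop("config rejected: require k >= cap >= 1")
  if (max_group_size < 1) stop("`max_group_size` must be >= 1")
  structure(list(atlas = atlas, simulate = simulate, baits = baits,
                 regulators = regulators, qpcr = qpcr,
                 reference_genes = reference_genes, control = control,
                 treatment = treatment, oe_genes = oe_genes,
                 out_dir = out_dir, k = as.integer(k), cap = as.integer(cap),
                 max_group_size = as.integer(max_group_size),
                 oe_threshold = oe_threshold,
                 target_threshold = target_threshold, alpha = alpha,
                 method = method, log_offset = log_offset,
                 min_expression = min_expression, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_gene_list <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) read_gene_list(x)
  else as.character(x)
}

#' Run the full mining pipeline
#'
#' Executes every stage in order — atlas (simulated or loaded), log2
#' preprocessing, similarity ranking, mutual-rank KNN network, bait-driven
#' candidate selection, screening-group assembly, and (when qPCR data is
#' configured) screen evaluation — writing each stage's output as TSV under
#' `config$out_dir` together with a JSON run manifest recording parameters,
#' input/output checksums and versions. Given a fixed seed the outputs are
#' bit-identical across reruns.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory stage results (`atlas`,
#'   `truth`, `ranking`, `network`, `candidates`, `groups`, optionally
#'   `screen`) and `manifest` (the parsed manifest).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  inputs <- character(0)
  truth <- NULL

  if (!is.null(config$atlas)) {
    stage_log("atlas", "reading expression atlas from %s", config$atlas)
    atlas <- tryCatch(read_expression_tsv(config$atlas),
                      error = function(e) stop("stage atlas: ", conditionMessage(e)))
    inputs <- c(inputs, config$atlas)
  } else {
    stage_log("atlas", "simulating atlas (seed %d)", config$simulate$seed)
    sim <- simulate_atlas(config$simulate)
    atlas <- sim$atlas; truth <- sim$truth
    write_expression_tsv(atlas, out("atlas.tsv"), out("sample_meta.tsv"))
    write_planted_truth(truth, out("planted_truth.tsv"))
  }

  baits <- if (!is.null(config$baits)) resolve_gene_list(config$baits)
           else if (!is.null(truth)) pathway_list(truth)
           else stop("stage select: no baits configured")
  regulators <- if (!is.null(config$regulators)) resolve_gene_list(config$regulators)
                else if (!is.null(truth)) regulator_list(truth)
                else stop("stage select: no regulators configured")
  if (is.character(config$baits) && length(config$baits) == 1 &&
      file.exists(config$baits)) inputs <- c(inputs, config$baits)
  if (is.character(config$regulators) && length(config$regulators) == 1 &&
      file.exists(config$regulators)) inputs <- c(inputs, config$regulators)
  write_gene_list(baits, out("baits.txt"))
  write_gene_list(regulators, out("regulators.txt"))

  stage_log("network", "computing %s similarity ranking", config$method)
  tr <- tryCatch(preprocess_atlas(atlas, log_offset = config$log_offset,
                                  min_expression = config$min_expression),
                 error = function(e) stop("stage network: ", conditionMessage(e)))
  ranking <- compute_similarity(tr, method = config$method)
  k_eff <- min(config$k, length(ranking$genes) - 1L)
  if (k_eff < config$k)
    stage_log("network", "k truncated to %d (rankable genes - 1)", k_eff)
  network <- build_knn(ranking, k_eff)
  export_edges(network, out("edges.tsv"))
  stage_log("network", "%d genes, %d undirected edges (k = %d)",
            length(network$genes), nrow(network$edges), k_eff)

  stage_log("select", "searching %d bait neighborhoods for %d regulators",
            length(baits), length(regulators))
  candidates <- tryCatch(
    select_candidates(ranking, baits, regulators, k = k_eff, cap = config$cap),
    error = function(e) stop("stage select: ", conditionMessage(e)))
  write_candidates(candidates, out("candidates.tsv"))
  relative_rank_matrix(candidates, out("relative_ranks.tsv"))
  stage_log("select", "%d candidates selected", length(candidates$candidates))

  groups <- NULL
  if (length(candidates$candidates)) {
    groups <- assign_groups(candidates, max_size = config$max_group_size)
    write_groups(groups, out("groups.tsv"))
    stage_log("groups", "%d screening groups assembled", length(groups$groups))
  } else {
    stage_log("groups", "no candidates; skipping group assembly")
  }

  screen <- NULL
  if (!is.null(config$qpcr)) {
    stage_log("screen", "evaluating qPCR screen from %s", config$qpcr)
    if (is.null(config$treatment) || is.null(config$oe_genes))
      stop("stage screen: `treatment` and `oe_genes` must be configured")
    dataset <- tryCatch(
      read_qpcr_csv(config$qpcr, reference_genes = config$reference_genes,
                    control = config$control),
      error = function(e) stop("stage screen: ", conditionMessage(e)))
    inputs <- c(inputs, config$qpcr)
    nrq <- normalize_qpcr(dataset)
    res <- fold_changes(nrq, treatment = config$treatment,
                        control = config$control)
    decision <- apply_gate(res, oe_genes = config$oe_genes,
                           oe_threshold = config$oe_threshold,
                           target_threshold = config$target_threshold,
                           alpha = config$alpha)
    res$hit <- res$gene %in% decision$triggered_by
    utils::write.table(res, out("screen_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(utils::capture.output(print(decision)), out("screen_decision.txt"))
    screen <- list(nrq = nrq, results = res, decision = decision)
    stage_log("screen", "advance = %s", decision$advance)
  }

  outputs <- list.files(config$out_dir, pattern = "\\.(tsv|txt)$",
                        full.names = TRUE)
  manifest <- list(
    package = "coexminer",
    version = as.character(utils::packageVersion("coexminer")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = list(k = config$k, cap = config$cap,
                      max_group_size = config$max_group_size,
                      oe_threshold = config$oe_threshold,
                      target_threshold = config$target_threshold,
                      alpha = config$alpha, method = config$method,
                      log_offset = config$log_offset,
                      seed = config$seed),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(sort(outputs))),
                                      basename(sort(outputs)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage_log("manifest", "wrote %s", out("manifest.json"))

  invisible(list(atlas = atlas, truth = truth, ranking = ranking,
                 network = network, candidates = candidates, groups = groups,
                 screen = screen, manifest = manifest))
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys match the arguments of [pipeline_config()]; a nested
#' `simulate:` block with keys `modules` (list of `id`, `pathway_genes`,
#' `regulators`, `active` sample indices), `n_samples`,
#' `background_genes`, `noise_sd`, `seed` builds an [atlas_config()] with
#' [block_profile()] activity designs.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file is read (CLI flags).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    s <- y$simulate
    mods <- lapply(s$modules, function(m) {
      atlas_module(m$id, m$pathway_genes, m$regulators,
                   block_profile(s$n_samples, unlist(m$active)))
    })
    y$simulate <- atlas_config(
      modules = mods,
      background_genes = if (is.null(s$background_genes)) 100 else s$background_genes,
      n_samples = s$n_samples,
      noise_sd = if (is.null(s$noise_sd)) 0.25 else s$noise_sd,
      seed = if (is.null(s$seed)) 1 else s$seed)
  }
  args <- utils::modifyList(y, list(...))
  do.call(pipeline_config, args)
}
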