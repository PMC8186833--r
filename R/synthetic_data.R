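#' @importFrom stats rnorm runif
NULL

# Run code with a private, seed-determined RNG stream, restoring the caller's.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specify a planted co-expression module
#'
#' A module is a set of genes sharing one activity profile across samples:
#' `pathway_genes` stand in for biosynthesis pathway genes (usable as baits)
#' and `regulators` for the transcription factors regulating them; both get
#' identical expected expression so the regulators land in the pathway genes'
#' co-expression neighborhoods.
#'
#' @param id character module id, used as a prefix for its gene ids.
#' @param pathway_genes number of pathway (bait-eligible) genes, >= 1.
#' @param regulators number of planted regulator genes, >= 0.
#' @param activity non-negative numeric activity profile, one value per
#'   atlas sample; expected expression of every module gene in sample `s`
#'   is proportional to `activity[s]`.
#' @return a list of class `atlas_module`.
#' @seealso [block_profile()] for organ/treatment-style block designs.
#' @export
atlas_module <- function(id, pathway_genes, regulators, activity) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("module `id` must be a non-empty string")
  if (!is.numeric(pathway_genes) || pathway_genes < 1)
    stop(sprintf("module '%s': `pathway_genes` must be >= 1", id))
  if (!is.numeric(regulators) || regulators < 0)
    stop(sprintf("module '%s': `regulators` must be >= 0", id))
  if (!is.numeric(activity) || length(activity) == 0)
    stop(sprintf("module '%s': `activity` must be a numeric profile", id))
  if (anyNA(activity) || any(!is.finite(activity)))
    stop(sprintf("module '%s': `activity` contains NaN/NA or non-finite values", id))
  if (any(activity < 0))
    stop(sprintf("module '%s': `activity` must be non-negative", id))
  structure(list(id = id,
                 pathway_genes = as.integer(pathway_genes),
                 regulators = as.integer(regulators),
                 activity = as.numeric(activity)),
            class = "atlas_module")
}

#' Block activity profile
#'
#' Convenience constructor for organ/treatment-style block designs: the
#' profile is `level` on the `active` samples and 0 elsewhere, which makes
#' module genes two-valued at zero noise and decouples pathway branches the
#' way organ-specific expression does.
#'
#' @param n_samples total number of samples.
#' @param active integer indices of samples where the module is on.
#' @param level positive activity level in active samples.
#' @return numeric vector of length `n_samples`.
#' @export
block_profile <- function(n_samples, active, level = 1) {
  stopifnot(n_samples >= 1, all(active >= 1), all(active <= n_samples),
            level > 0)
  p <- numeric(n_samples)
  p[active] <- level
  p
}

#' Configuration for a synthetic expression atlas
#'
#' Describes the statistical structure the downstream analysis assumes:
#' co-expressed modules of pathway genes with planted regulators, unstructured
#' background genes, log-normal multiplicative noise, and TPM column closure.
#'
#' @param modules list of [atlas_module()] specifications. Every sample must
#'   have at least one module with nonzero activity.
#' @param background_genes number of background genes with profiles
#'   independent of any module.
#' @param n_samples number of samples; defaults to 82, the size of a typical
#'   multi-organ/treatment compendium.
#' @param noise_sd standard deviation, on the natural-log scale, of the
#'   multiplicative noise applied per gene per sample.
#' @param background_profile_sd log-scale sd of the per-gene background
#'   profiles (independent of `noise_sd`, so background genes vary even in
#'   noise-free atlases).
#' @param tpm_total every sample column is rescaled to sum to this total
#'   (TPM closure), default 1e6.
#' @param seed integer; fully determines the simulated atlas.
#' @param n_genes optional expected total gene count; if supplied it must
#'   equal module members plus background genes (a consistency check).
#' @return list of class `atlas_config`.
#' @export
atlas_config <- function(modules, background_genes = 100, n_samples = 82,
                         noise_sd = 0.25, background_profile_sd = 1,
                         tpm_total = 1e6, seed = 1, n_genes = NULL) {
  if (!is.list(modules) || length(modules) == 0)
    stop("`modules` must be a non-empty list of atlas_module objects")
  modules <- lapply(modules, function(m) {
    if (!inherits(m, "atlas_module"))
      stop("`modules` entries must be created with atlas_module()")
    m
  })
  ids <- vapply(modules, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate module ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("`n_samples` must be a positive count")
  for (m in modules)
    if (length(m$activity) != n_samples)
      stop(sprintf("module '%s': `activity` has length %d but n_samples is %d",
                   m$id, length(m$activity), n_samples))
  act <- vapply(modules, `[[`, numeric(n_samples), "activity")
  act <- matrix(act, nrow = n_samples)
  uncovered <- which(apply(act, 1, max) <= 0)
  if (length(uncovered))
    stop("`modules`: samples with no nonzero module activity: ",
         paste(uncovered, collapse = ", "))
  if (!is.numeric(background_genes) || background_genes < 0)
    stop("`background_genes` must be a non-negative count")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number")
  if (!is.numeric(tpm_total) || tpm_total <= 0)
    stop("`tpm_total` must be positive")
  total <- sum(vapply(modules, function(m) m$pathway_genes + m$regulators,
                      integer(1))) + as.integer(background_genes)
  if (!is.null(n_genes) && n_genes != total)
    stop(sprintf("`n_genes` (%d) does not match modules + background (%d)",
                 n_genes, total))
  structure(list(modules = modules,
                 background_genes = as.integer(background_genes),
                 n_samples = as.integer(n_samples),
                 noise_sd = noise_sd,
                 background_profile_sd = background_profile_sd,
                 tpm_total = tpm_total,
                 seed = as.integer(seed),
                 n_genes = total),
            class = "atlas_config")
}

#' Simulate a synthetic expression atlas with planted regulators
#'
#' Generates a TPM genes x samples matrix in which each module gene's
#' expected expression is proportional to its module's activity profile,
#' multiplicative log-normal noise (sd `noise_sd` on the log scale) is
#' applied per gene per sample, background genes follow independent
#' log-normal profiles, and every sample column is rescaled to sum to
#' `tpm_total`. The planted truth (which genes are pathway members,
#' regulators or background) is returned alongside for recovery tests.
#'
#' @param config an [atlas_config()].
#' @return list with elements `atlas` (an [expression_atlas()]) and
#'   `truth` (class `planted_truth`: per-module pathway/regulator gene ids
#'   plus background ids).
#' @examples
#' cfg <- atlas_config(
#'   modules = list(
#'     atlas_module("leaf", 5, 2, block_profile(12, 1:6)),
#'     atlas_module("root", 5, 2, block_profile(12, 7:12))),
#'   background_genes = 20, n_samples = 12, noise_sd = 0.1, seed = 7)
#' sim <- simulate_atlas(cfg)
#' colSums(sim$atlas$values)[1:3]   # each 1e6
#' regulator_list(sim$truth)
#' @export
simulate_atlas <- function(config) {
  if (!inherits(config, "atlas_config"))
    stop("`config` must be created with atlas_config()")
  ns <- config$n_samples
  with_seed(config$seed, {
    rows <- list()
    truth_modules <- list()
    for (m in config$modules) {
      n_mem <- m$pathway_genes + m$regulators
      # one baseline per module: genes are exact scalar multiples at zero
      # noise, so within-module log-scale correlation is exactly 1
      base <- 2 ^ runif(1, 5, 9)
      expected <- base * m$activity
      block <- matrix(rep(expected, each = n_mem), nrow = n_mem)
      if (config$noise_sd > 0)
        block <- block * exp(matrix(rnorm(n_mem * ns, 0, config$noise_sd),
                                    nrow = n_mem))
      path_ids <- sprintf("%s_P%03d", m$id, seq_len(m$pathway_genes))
      reg_ids <- if (m$regulators > 0)
        sprintf("%s_R%02d", m$id, seq_len(m$regulators)) else character(0)
      rownames(block) <- c(path_ids, reg_ids)
      rows[[m$id]] <- block
      truth_modules[[m$id]] <- list(pathway = path_ids, regulators = reg_ids)
    }
    nb <- config$background_genes
    bg_ids <- character(0)
    if (nb > 0) {
      bg_base <- 2 ^ runif(nb, 3, 10)
      bg <- bg_base * exp(matrix(rnorm(nb * ns, 0, config$background_profile_sd),
                                 nrow = nb))
      if (config$noise_sd > 0)
        bg <- bg * exp(matrix(rnorm(nb * ns, 0, config$noise_sd), nrow = nb))
      bg_ids <- sprintf("BG_%04d", seq_len(nb))
      rownames(bg) <- bg_ids
      rows[["..background"]] <- bg
    }
    values <- do.call(rbind, unname(rows))
    values <- pmax(values, 0)
    # TPM closure: rescale each sample column to the fixed total
    values <- sweep(values, 2, colSums(values) / config$tpm_total, "/")
    sample_ids <- sprintf("S%03d", seq_len(ns))
    colnames(values) <- sample_ids
    act <- vapply(config$modules, `[[`, numeric(ns), "activity")
    act <- matrix(act, nrow = ns)
    dominant <- vapply(seq_len(ns), function(s) {
      config$modules[[which.max(act[s, ])]]$id
    }, character(1))
    meta <- data.frame(sample = sample_ids, organ = dominant,
                       treatment = "none", stringsAsFactors = FALSE)
    atlas <- expression_atlas(values, meta)
    truth <- structure(list(modules = truth_modules, background = bg_ids),
                       class = "planted_truth")
    list(atlas = atlas, truth = truth)
  })
}

#' All planted regulator gene ids
#'
#' Flattens a `planted_truth` into the regulator gene list consumed by
#' [select_candidates()], emulating an annotation-derived regulator set.
#'
#' @param truth a `planted_truth` from [simulate_atlas()].
#' @return character vector of regulator gene ids.
#' @export
regulator_list <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  unlist(lapply(truth$modules, `[[`, "regulators"), use.names = FALSE)
}

#' All planted pathway (bait-eligible) gene ids
#'
#' @param truth a `planted_truth` from [simulate_atlas()].
#' @param module optional module id to restrict to.
#' @return character vector of pathway gene ids.
#' @export
pathway_list <- function(truth, module = NULL) {
  stopifnot(inherits(truth, "planted_truth"))
  mods <- if (is.null(module)) truth$modules else truth$modules[module]
  unlist(lapply(mods, `[[`, "pathway"), use.names = FALSE)
}

#' Simulate a qPCR screening dataset
#'
#' Generates quantification-cycle (Cq) data whose expected
#' efficiency-corrected relative quantities reproduce specified true fold
#' changes between treatment conditions and a control, with reference genes
#' varying only by noise. Technical replicates are measured with independent
#' noise and averaged into one Cq per biological replicate before export,
#' mirroring standard qPCR practice.
#'
#' @param fold_changes named list: one element per treatment condition, each
#'   a named numeric vector of true fold changes (vs the control) per gene.
#'   Genes absent from a condition default to fold change 1. All fold
#'   changes must be > 0.
#' @param reference_genes character, >= 1 gene id with true fold change 1
#'   everywhere.
#' @param control label of the control condition (e.g. `"GUS"`).
#' @param n_replicates biological replicates per condition, >= 2.
#' @param cq_sd per-biological-replicate Cq noise sd, in cycles.
#' @param tech_sd per-technical-replicate measurement noise sd (cycles);
#'   `n_technical` measurements are averaged.
#' @param n_technical technical replicates per reaction (default 2).
#' @param efficiencies named numeric amplification efficiencies (fold per
#'   cycle); unnamed scalar or missing genes default to 2 (100% efficiency).
#' @param base_cq baseline Cq per gene in the control (scalar or named).
#' @param seed integer seed; fully determines the dataset.
#' @return a [qpcr_dataset()].
#' @examples
#' d <- simulate_qpcr(list(OE = c(TF1 = 40, STR = 4)),
#'                    reference_genes = c("N2227", "SAND"),
#'                    control = "GUS", n_replicates = 4, cq_sd = 0.1, seed = 3)
#' head(d$records)
#' @export
simulate_qpcr <- function(fold_changes, reference_genes, control = "control",
                          n_replicates = 4, cq_sd = 0.1, tech_sd = 0,
                          n_technical = 2, efficiencies = NULL, base_cq = 25,
                          seed = 1) {
  if (!is.list(fold_changes) || is.null(names(fold_changes)) ||
      any(!nzchar(names(fold_changes))))
    stop("`fold_changes` must be a named list (condition -> named fold-change vector)")
  if (control %in% names(fold_changes))
    stop("`control` condition must not appear in `fold_changes`")
  for (cond in names(fold_changes)) {
    fc <- fold_changes[[cond]]
    if (!is.numeric(fc) || is.null(names(fc)))
      stop(sprintf("fold changes for condition '%s' must be a named numeric vector", cond))
    if (any(fc <= 0))
      stop(sprintf("fold changes must be > 0 (condition '%s', gene %s)",
                   cond, names(fc)[which(fc <= 0)[1]]))
  }
  if (length(reference_genes) < 1)
    stop("at least one reference gene is required")
  if (n_replicates < 2)
    stop("`n_replicates` must be >= 2 per condition")
  genes <- union(unique(unlist(lapply(fold_changes, names))), reference_genes)
  eff <- rep(2, length(genes)); names(eff) <- genes
  if (!is.null(efficiencies)) {
    if (is.null(names(efficiencies)) && length(efficiencies) == 1) {
      eff[] <- efficiencies
    } else {
      eff[names(efficiencies)] <- efficiencies
    }
  }
  if (any(eff <= 1))
    stop("amplification efficiencies must be > 1 (fold per cycle)")
  base <- rep(base_cq[1], length(genes)); names(base) <- genes
  if (!is.null(names(base_cq))) base[names(base_cq)] <- base_cq
  conditions <- c(control, names(fold_changes))
  with_seed(seed, {
    recs <- vector("list", length(conditions) * n_replicates)
    k <- 0
    for (cond in conditions) {
      fc <- rep(1, length(genes)); names(fc) <- genes
      if (cond != control) {
        v <- fold_changes[[cond]]
        fc[names(v)] <- v
        fc[reference_genes] <- 1
      }
      for (r in seq_len(n_replicates)) {
        k <- k + 1
        # lower Cq = more template: a true fold change f needs a Cq shift
        # of -log(f)/log(E) cycles
        mu <- base - log(fc) / log(eff) + rnorm(length(genes), 0, cq_sd)
        cq <- if (tech_sd > 0) {
          vapply(mu, function(x) mean(x + rnorm(n_technical, 0, tech_sd)),
                 numeric(1))
        } else mu
        recs[[k]] <- data.frame(sample = sprintf("%s_rep%d", cond, r),
                                condition = cond, gene = genes,
                                cq = unname(cq), stringsAsFactors = FALSE)
      }
    }
    qpcr_dataset(do.call(rbind, recs), reference_genes = reference_genes,
                 control = control, efficiencies = eff)
  })
}
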