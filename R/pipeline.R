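#' Pipeline configuration
#'
#' Bundles the inputs and stage settings for [run_pipeline()]. Defaults
#' mirror the conventional chip workflow: per-population QC, merge,
#' merged QC, LD pruning at (50, 5, 0.2), then the analysis stages.
#'
#' @param inputs Either a named list of [geno_data] objects (names become
#'   population labels when the datasets carry none) or a data frame with
#'   columns `ped`, `map` naming PED/MAP pairs to read.
#' @param qc A [qc_config()].
#' @param prune_window,prune_step,prune_r2 LD-pruning parameters.
#' @param stages Character vector of stages to run, from
#'   `c("diversity", "kinship", "amova", "fst", "pca", "admixture",
#'   "ld_decay", "ld_chromosome", "ne")`.
#' @param admixture_K K values scored by cross-validation.
#' @param ne NE stage settings, an [ne_config()].
#' @param n_permutations AMOVA permutations.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for all stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs,
                            qc = qc_config(),
                            prune_window = 50L, prune_step = 5L,
                            prune_r2 = 0.2,
                            stages = c("diversity", "kinship", "amova",
                                       "fst", "pca", "admixture",
                                       "ld_decay", "ld_chromosome", "ne"),
                            admixture_K = 1:5,
                            ne = ne_config(),
                            n_permutations = 1000L,
                            out_dir = tempfile("snppop_run_"),
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(inputs = inputs, qc = qc, prune_window = prune_window,
         prune_step = prune_step, prune_r2 = prune_r2, stages = stages,
         admixture_K = admixture_K, ne = ne,
         n_permutations = n_permutations, out_dir = out_dir, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the end-to-end workflow
#'
#' Per-population QC, merge, merged QC, autosome subsetting, LD pruning,
#' then the enabled analysis stages. Diversity, kinship, PCA and
#' admixture run on the LD-pruned panel; LD decay, per-chromosome LD and
#' Ne use the un-pruned post-QC autosomal SNPs (pruning would
#' mechanically depress r2). Every output table is written as TSV with a
#' provenance header (config hash, seed, thresholds); a failed stage
#' aborts with a stage-named error, retaining the outputs already
#' written.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with the in-memory results
#'   (`qc_reports`, `merged`, `pruned_ids`, plus one entry per stage run).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(level, ...) {
    msg <- sprintf("[%s] %s", level, sprintf(...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("ERROR", "stage %s failed: %s", name, conditionMessage(e))
      stop(sprintf("stage %s: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  header <- provenance_header(config)
  emit <- function(tbl, file) {
    write_tsv_with_header(tbl, file.path(config$out_dir, file), header)
  }
  results <- list()

  datasets <- stage("input", {
    ins <- config$inputs
    if (is.data.frame(ins)) {
      ins <- purrr::pmap(ins, function(ped, map, ...) read_ped_map(ped, map))
    }
    stopifnot(length(ins) >= 1L)
    ins
  })

  qc_rep <- list()
  post_qc <- stage("qc", {
    lapply(seq_along(datasets), function(k) {
      r <- run_qc(datasets[[k]], config$qc)
      pop <- unique(r$dataset$samples$population)
      qc_rep[[k]] <<- dplyr::mutate(
        r$report, population = paste(pop, collapse = "+"), .before = 1L)
      r$dataset
    })
  })
  merged <- stage("merge", {
    if (length(post_qc) > 1L) merge_datasets(post_qc) else post_qc[[1L]]
  })
  merged <- stage("merged-qc", {
    r <- run_qc(merged, config$qc)
    qc_rep[[length(qc_rep) + 1L]] <- dplyr::mutate(
      r$report, population = "Merged", .before = 1L)
    r$dataset
  })
  results$qc_reports <- dplyr::bind_rows(qc_rep)
  emit(results$qc_reports, "qc_report.tsv")

  merged <- stage("autosomes", subset_autosomes(merged))
  results$merged <- merged

  pruned_ids <- stage("prune", {
    ld_prune(merged, config$prune_window, config$prune_step,
             config$prune_r2)
  })
  results$pruned_ids <- pruned_ids
  pruned <- merged[, pruned_ids]
  logf("INFO", "LD pruning retained %d of %d SNPs", length(pruned_ids),
       n_snps(merged))

  run <- function(nm) nm %in% config$stages

  if (run("diversity")) {
    results$diversity <- stage("diversity",
                               diversity_summary(merged, pruned_ids))
    emit(results$diversity, "diversity_summary.tsv")
  }
  if (run("kinship")) {
    results$kinship <- stage("kinship", pairwise_pihat(pruned))
    emit(results$kinship, "kinship.tsv")
  }
  if (run("amova")) {
    results$amova <- stage("amova", amova(
      pruned, n_permutations = config$n_permutations, seed = config$seed))
    emit(tidy(results$amova), "amova.tsv")
  }
  if (run("fst")) {
    results$fst <- stage("fst", fst_weir_cockerham(pruned))
    emit(tibble::tibble(global_fst = results$fst$global), "fst_global.tsv")
    emit(results$fst$per_snp, "fst_per_snp.tsv")
  }
  if (run("pca")) {
    results$pca <- stage("pca", pca_genotypes(pruned, k = 3L))
    emit(results$pca$scores, "pca_eigenvectors.tsv")
    emit(tibble::tibble(component = seq_along(results$pca$var_fraction),
                        eigenvalue = results$pca$values[
                          seq_along(results$pca$var_fraction)],
                        var_fraction = results$pca$var_fraction),
         "pca_eigenvalues.tsv")
  }
  if (run("admixture")) {
    results$admixture_cv <- stage("admixture", admixture_cv(
      pruned, config$admixture_K, seed = config$seed))
    emit(results$admixture_cv, "admixture_cv.tsv")
    best_K <- attr(results$admixture_cv, "best_K")
    results$admixture <- stage("admixture", admixture_em(
      pruned, best_K, seed = config$seed))
    emit(results$admixture$Q, sprintf("admixture_Q_K%d.tsv", best_K))
  }
  if (run("ld_decay")) {
    results$ld_decay <- stage("ld_decay", ld_decay_table(merged))
    emit(results$ld_decay, "ld_decay.tsv")
  }
  if (run("ld_chromosome")) {
    results$ld_chromosome <- stage("ld_chromosome",
                                   per_chromosome_ld(merged))
    emit(results$ld_chromosome, "ld_per_chromosome.tsv")
  }
  if (run("ne")) {
    results$ne <- stage("ne", ne_trajectory(merged, config$ne))
    emit(results$ne, "ne_trajectory.tsv")
  }
  logf("INFO", "pipeline finished: %d stages", length(config$stages))
  invisible(results)
}

provenance_header <- function(config) {
  cfg <- config
  cfg$inputs <- NULL    # datasets and output location don't belong in
  cfg$out_dir <- NULL   # the analytic-settings hash
  c(
    sprintf("# snppop %s", as.character(utils::packageVersion("snppop"))),
    sprintf("# seed=%d config_hash=%s", config$seed, rlang::hash(cfg)),
    sprintf("# qc: sample_call>=%g snp_call>=%g maf>=%g hwe_p>=%g",
            config$qc$sample_call_threshold, config$qc$snp_call_threshold,
            config$qc$maf_threshold, config$qc$hwe_p_threshold),
    sprintf("# prune: window=%d step=%d r2=%g", config$prune_window,
            config$prune_step, config$prune_r2)
  )
}

write_tsv_with_header <- function(tbl, path, header) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(tbl, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
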