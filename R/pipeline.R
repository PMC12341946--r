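#' Configure a full pipeline run
#'
#' Either a simulation block (a [sim_config()]) or paths to a count matrix
#' and design table must be supplied. Thresholds mirror the individual
#' stage defaults.
#'
#' @param sim A [sim_config()], or `NULL` to read counts from disk.
#' @param counts_path,design_path TSV paths (used when `sim` is `NULL`).
#' @param gene_sets_path Optional GMT / two-column TSV of gene sets; when
#'   given, over-representation is run for each direction x memory-effect
#'   gene group against the filtered-gene universe.
#' @param cpm_threshold,min_samples_fraction Low-count filter settings.
#' @param fc_lo,fc_hi,prob_threshold Fold-change category settings
#'   (`fc_hi > fc_lo > 1`).
#' @param alpha Per-term stepwise significance level.
#' @param fdr BH FDR for the time filter and the classification gate.
#' @param gate Classification significance gate (see [classify_genes()]).
#' @param baseline_time Reference time for pairwise DE.
#' @param seed Integer seed applied to the simulation.
#' @param out_dir Optional directory; when given, every table is written as
#'   TSV.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, counts_path = NULL, design_path = NULL,
                       gene_sets_path = NULL, cpm_threshold = 1,
                       min_samples_fraction = 0.5, fc_lo = 1.2, fc_hi = 2.0,
                       prob_threshold = 0.8, alpha = 0.05, fdr = 0.05,
                       gate = "combined", baseline_time = 0, seed = 1L,
                       out_dir = NULL) {
  if (is.null(sim) && (is.null(counts_path) || is.null(design_path))) {
    rlang::abort("supply either a sim config or counts_path + design_path")
  }
  if (!(fc_hi > fc_lo && fc_lo > 1)) rlang::abort("need fc_hi > fc_lo > 1")
  if (alpha <= 0 || alpha >= 1 || fdr <= 0 || fdr >= 1) {
    rlang::abort("alpha and fdr must lie in (0, 1)")
  }
  structure(
    list(sim = sim, counts_path = counts_path, design_path = design_path,
         gene_sets_path = gene_sets_path, cpm_threshold = cpm_threshold,
         min_samples_fraction = min_samples_fraction, fc_lo = fc_lo,
         fc_hi = fc_hi, prob_threshold = prob_threshold, alpha = alpha,
         fdr = fdr, gate = gate, baseline_time = baseline_time,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [run_config()] arguments; a `sim:` mapping is passed
#' to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    for (nm in c("class_proportions", "strain_proportions",
                 "interaction_proportions", "direction_proportions")) {
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    }
    if (!is.null(sim_args$times)) sim_args$times <- unlist(sim_args$times)
    y$sim <- do.call(sim_config, sim_args)
  }
  do.call(run_config, y)
}

#' Run the full transcriptional-memory pipeline
#'
#' Simulate (or read) counts, filter, normalize (TMM), run PCA QC, call
#' pairwise differential expression against the time-zero baseline of each
#' condition with fold-change categories and transition tables, fit the
#' per-gene time-course model, filter time-significant genes, refine by
#' backward stepwise elimination, classify memory / strain / interaction
#' effects, summarize overlaps, and (optionally) run gene-set
#' over-representation per direction x memory-effect group. Re-running with
#' the same configuration reproduces every table exactly.
#'
#' @param config A [run_config()].
#' @return An object of class `memory_run`: the configuration echo, stage
#'   gene counts, and all result tables (`norm`, `pca`, `de`, `categories`,
#'   `transitions`, `fits`, `classes`, `overlap`, `enrichment`, `truth`
#'   and `recovery` when simulated).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    sim <- simulate_counts(sim_cfg)
    counts <- sim$counts
    design <- sim$design
    truth <- sim$truth
  } else {
    counts <- read_counts(config$counts_path)
    design <- read_design(config$design_path)
    truth <- NULL
  }
  n_input <- nrow(counts)

  filtered <- filter_low_counts(counts, config$cpm_threshold,
                                config$min_samples_fraction)
  factors <- tmm_factors(filtered)
  norm <- normalize_counts(filtered, factors)
  pca <- pca_qc(norm, design)
  rlang::inform("note: hidden-batch correction is not applied (counts are assumed batch-free)")

  de <- de_vs_baseline(norm, design, baseline_time = config$baseline_time)
  cats <- categorize_fc(de, config$fc_lo, config$fc_hi,
                        config$prob_threshold)
  times <- sort(unique(cats$time))
  transitions <- if (length(times) >= 2) {
    transition_table(dplyr::filter(cats, .data$time == times[1]),
                     dplyr::filter(cats, .data$time == times[2]))
  } else NULL

  fits <- fit_timecourse(norm, design) %>%
    filter_time_significant(fdr = config$fdr) %>%
    backward_stepwise(alpha = config$alpha)
  classes <- classify_genes(fits, gate = config$gate, fdr = config$fdr,
                            alpha = config$alpha)
  overlap <- overlap_summary(classes)

  enrichment <- NULL
  if (!is.null(config$gene_sets_path)) {
    sets <- read_gene_sets(config$gene_sets_path)
    universe <- filtered$gene_id
    groups <- classes %>%
      dplyr::filter(.data$memory_effect %in%
                      c("dampened", "enhanced", "reversed"),
                    !is.na(.data$direction))
    enrichment <- groups %>%
      dplyr::group_by(.data$direction, .data$memory_effect) %>%
      dplyr::group_modify(function(g, key) {
        fisher_enrich(g$gene_id, sets, universe, filter = FALSE)
      }) %>%
      dplyr::ungroup()
  }

  recovery <- NULL
  if (!is.null(truth)) recovery <- recovery_summary(classes, truth)

  report <- structure(
    list(config = config,
         n_input = n_input,
         n_filtered = nrow(filtered),
         n_time_significant = nrow(fits$genes),
         factors = factors, norm = norm, pca = pca, de = de,
         categories = cats, transitions = transitions, fits = fits,
         classes = classes, overlap = overlap, enrichment = enrichment,
         truth = truth, recovery = recovery),
    class = "memory_run"
  )
  if (!is.null(config$out_dir)) .write_run(report, config$out_dir)
  report
}

#' Compare recovered classes with simulation truth
#'
#' Joins the classifier output with the truth table of [simulate_counts()]
#' and reports, per factor, the fraction of (time-significant) genes whose
#' recovered label equals the declared one.
#'
#' @param classes A [classify_genes()] result.
#' @param truth The `truth` tibble of a simulation.
#' @return A tibble: `effect`, `n`, `n_correct`, `accuracy`.
#' @export
recovery_summary <- function(classes, truth) {
  j <- dplyr::inner_join(classes, truth, by = "gene_id")
  pairs <- list(memory = c("memory_effect", "memory_class"),
                strain = c("strain_effect", "strain_class"),
                interaction = c("interaction_effect", "interaction_class"))
  purrr::imap(pairs, function(cols, eff) {
    ok <- j[[cols[1]]] == j[[cols[2]]]
    tibble::tibble(effect = eff, n = nrow(j), n_correct = sum(ok),
                   accuracy = mean(ok))
  }) %>%
    dplyr::bind_rows()
}

.write_run <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, name) {
    if (!is.null(x)) readr::write_tsv(x, file.path(dir, name))
  }
  wt(report$factors, "tmm_factors.tsv")
  wt(report$norm$log2, "normalized_log2.tsv")
  wt(report$pca$scores, "pca_scores.tsv")
  wt(report$de, "de_pairwise.tsv")
  wt(report$categories, "fc_categories.tsv")
  wt(report$transitions, "transitions.tsv")
  wt(report$fits$final, "gene_fits.tsv")
  wt(report$fits$time_filter, "time_filter.tsv")
  wt(report$classes, "classes.tsv")
  wt(report$overlap, "overlap.tsv")
  wt(report$enrichment, "enrichment.tsv")
  wt(report$truth, "truth.tsv")
  wt(report$recovery, "recovery.tsv")
  invisible(dir)
}

#' @export
print.memory_run <- function(x, ...) {
  cat("Transcriptional-memory pipeline run (seed ", x$config$seed, ")\n",
      sep = "")
  cat("  genes: input ", x$n_input, " -> filtered ", x$n_filtered,
      " -> time-significant ", x$n_time_significant, "\n", sep = "")
  if (!is.null(x$classes)) {
    tab <- table(x$classes$memory_effect)
    cat("  memory effects:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$recovery)) {
    cat("  truth recovery:",
        paste(x$recovery$effect, sprintf("%.3f", x$recovery$accuracy),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
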