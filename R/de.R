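# rows of `design` matching every field of a condition spec
.match_condition <- function(design, cond) {
  bad <- setdiff(names(cond), names(design))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown design column(s) in condition: ",
                        paste(bad, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(design))
  for (nm in names(cond)) keep <- keep & design[[nm]] == cond[[nm]]
  which(keep)
}

#' Empirical noise-distribution differential expression probability
#'
#' For each gene, compares the between-condition signal against the pooled
#' within-condition replicate noise, on the linear normalized (CPM-TMM)
#' scale with a small pseudocount. The signal is the pair
#' `(M, D)` = (log2 ratio of condition means, absolute difference of
#' condition means). The noise distribution collects `(M, D)` from every
#' within-condition replicate pair of both conditions, across all genes.
#' The probability of differential expression is the fraction of noise
#' pairs strictly dominated by the signal:
#' `prob = mean(|M_noise| < |M| & D_noise < D)`.
#'
#' @param norm A `memory_norm` object.
#' @param design Design tibble with a `sample` column.
#' @param cond_a,cond_b Named lists selecting the two conditions, e.g.
#'   `list(strain = "WT", memory = "memory", time = 15)`. `cond_a` is the
#'   numerator of the fold change.
#' @param pseudocount Added to linear values before ratios (default 0.5).
#' @return A tibble with `gene_id`, `M`, `D`, `prob` and `signed_fc`
#'   (ratio of means when >= 1, else the negated reciprocal, so
#'   `|signed_fc| >= 1` always and a 2-fold drop is -2).
#' @export
noiseq_probability <- function(norm, design, cond_a, cond_b,
                               pseudocount = 0.5) {
  stopifnot(inherits(norm, "memory_norm"))
  m <- .as_count_matrix(norm$cpm)
  ia <- .match_condition(design, cond_a)
  ib <- .match_condition(design, cond_b)
  if (length(ia) == 0 || length(ib) == 0) {
    rlang::abort("a condition matches no sample in the design")
  }
  if (length(ia) < 2 || length(ib) < 2) {
    rlang::abort("each condition needs at least 2 replicates")
  }
  ca <- match(design$sample[ia], colnames(m))
  cb <- match(design$sample[ib], colnames(m))
  ea <- m[, ca, drop = FALSE] + pseudocount
  eb <- m[, cb, drop = FALSE] + pseudocount
  ma <- rowMeans(ea)
  mb <- rowMeans(eb)
  M <- log2(ma / mb)
  D <- abs(ma - mb)

  noise <- .noise_pairs(list(ea, eb))
  prob <- .dominance_fraction(abs(M), D, abs(noise$M), noise$D)
  ratio <- ma / mb
  tibble::tibble(
    gene_id = rownames(m),
    M = unname(M), D = unname(D), prob = prob,
    signed_fc = unname(ifelse(ratio >= 1, ratio, -1 / ratio))
  )
}

# pooled within-condition replicate-pair (M, D) values across all genes
.noise_pairs <- function(cond_mats) {
  Ms <- list()
  Ds <- list()
  k <- 0
  for (e in cond_mats) {
    r <- ncol(e)
    for (i in seq_len(r - 1)) {
      for (j in seq(i + 1, r)) {
        k <- k + 1
        Ms[[k]] <- log2(e[, i] / e[, j])
        Ds[[k]] <- abs(e[, i] - e[, j])
      }
    }
  }
  list(M = unlist(Ms, use.names = FALSE), D = unlist(Ds, use.names = FALSE))
}

# fraction of noise pairs strictly dominated by each signal pair
.dominance_fraction <- function(sig_m, sig_d, noise_m, noise_d) {
  nn <- length(noise_m)
  vapply(seq_along(sig_m), function(g) {
    sum(noise_m < sig_m[g] & noise_d < sig_d[g]) / nn
  }, numeric(1))
}

#' Pairwise differential expression against the time-zero baseline
#'
#' Runs [noiseq_probability()] for every strain x memory condition at each
#' post-baseline time point, always against time `baseline_time` of the
#' same strain and memory condition.
#'
#' @param norm A `memory_norm` object.
#' @param design Design tibble (sample, strain, memory, time).
#' @param baseline_time Reference time in minutes (default 0).
#' @param pseudocount Passed to [noiseq_probability()].
#' @return A tibble with `strain`, `memory`, `time` and the per-gene
#'   [noiseq_probability()] columns.
#' @export
de_vs_baseline <- function(norm, design, baseline_time = 0,
                           pseudocount = 0.5) {
  combos <- design %>%
    dplyr::filter(.data$time != baseline_time) %>%
    dplyr::distinct(.data$strain, .data$memory, .data$time)
  purrr::pmap(combos, function(strain, memory, time) {
    noiseq_probability(
      norm, design,
      cond_a = list(strain = strain, memory = memory, time = time),
      cond_b = list(strain = strain, memory = memory, time = baseline_time),
      pseudocount = pseudocount
    ) %>%
      dplyr::mutate(strain = strain, memory = memory, time = time,
                    .before = 1)
  }) %>%
    dplyr::bind_rows()
}

#' Five-level fold-change categories
#'
#' Labels each gene `strong_up`, `up`, `unchanged`, `down` or `strong_down`:
#' genes whose differential-expression probability is below
#' `prob_threshold` or whose absolute fold change is below `fc_lo` are
#' `unchanged`; significant genes with `|signed_fc|` above `fc_hi` are
#' strong, the rest are plain up/down.
#'
#' @param de Output of [noiseq_probability()] or [de_vs_baseline()].
#' @param fc_lo,fc_hi Fold-change cutoffs (defaults 1.2 and 2).
#' @param prob_threshold Minimum DE probability (default 0.8).
#' @return `de` with an added ordered factor column `label`.
#' @export
categorize_fc <- function(de, fc_lo = 1.2, fc_hi = 2.0,
                          prob_threshold = 0.8) {
  stopifnot(fc_hi > fc_lo, fc_lo > 1)
  lev <- c("strong_down", "down", "unchanged", "up", "strong_up")
  afc <- abs(de$signed_fc)
  up <- de$signed_fc > 0
  lab <- ifelse(
    de$prob < prob_threshold | afc < fc_lo, "unchanged",
    ifelse(afc > fc_hi,
           ifelse(up, "strong_up", "strong_down"),
           ifelse(up, "up", "down"))
  )
  dplyr::mutate(de, label = factor(lab, levels = lev))
}

#' Category transition table between two time points
#'
#' Counts, per strain x memory condition, how many genes move from each
#' fold-change category at one time to each category at a later time — the
#' numbers behind a Sankey/alluvial display of the time course.
#'
#' @param cat_a,cat_b Outputs of [categorize_fc()] at the earlier and later
#'   time (must cover the same genes per condition).
#' @return A tibble with the condition columns, `from`, `to` and `n`
#'   (all 25 label pairs per condition, zeros included). Per condition the
#'   counts sum to the number of genes.
#' @export
transition_table <- function(cat_a, cat_b) {
  grp <- intersect(c("strain", "memory"), names(cat_a))
  a <- dplyr::select(cat_a, dplyr::all_of(c(grp, "gene_id")), from = "label")
  b <- dplyr::select(cat_b, dplyr::all_of(c(grp, "gene_id")), to = "label")
  joined <- dplyr::inner_join(a, b, by = c(grp, "gene_id"))
  if (nrow(joined) != nrow(a)) {
    rlang::abort("the two category tables do not cover the same genes")
  }
  out <- joined %>%
    dplyr::count(dplyr::across(dplyr::all_of(grp)), .data$from, .data$to)
  if (length(grp) > 0) {
    out <- tidyr::complete(out, tidyr::nesting(!!!rlang::syms(grp)),
                           .data$from, .data$to, fill = list(n = 0L))
  } else {
    out <- tidyr::complete(out, .data$from, .data$to, fill = list(n = 0L))
  }
  out <- tibble::as_tibble(out)
  class(out) <- c("memory_transitions", class(out))
  out
}
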