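#' Filter genes with low counts
#'
#' Removes genes whose counts-per-million (CPM = count / library size * 1e6)
#' fall below `cpm_threshold` in too many samples. A gene is retained when
#' its CPM is at least the threshold in at least `min_samples_fraction` of
#' the samples. Library sizes are the raw column totals. Gene order is
#' preserved and the operation is idempotent.
#'
#' @param counts Count tibble (`gene_id` + one integer column per sample)
#'   or matrix.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param min_samples_fraction Fraction of samples that must reach the
#'   cutoff (default 0.5).
#' @return The filtered count tibble.
#' @export
filter_low_counts <- function(counts, cpm_threshold = 1,
                              min_samples_fraction = 0.5) {
  m <- .as_count_matrix(counts)
  if (any(m < 0)) rlang::abort("counts must be non-negative")
  lib <- colSums(m)
  cpm <- sweep(m, 2, lib, "/") * 1e6
  keep <- rowSums(cpm >= cpm_threshold) >= min_samples_fraction * ncol(m)
  if (!any(keep)) {
    rlang::abort(paste0("no gene passes the low-count filter (cpm >= ",
                        cpm_threshold, " in >= ", min_samples_fraction,
                        " of samples)"))
  }
  if (is.matrix(counts)) counts[keep, , drop = FALSE] else counts[keep, ]
}

# one pairwise TMM factor: weighted trimmed mean of M-values of obs vs ref
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  pos <- obs > 0 & ref > 0
  o <- obs[pos] / n_obs
  r <- ref[pos] / n_ref
  M <- log2(o / r)
  A <- 0.5 * log2(o * r)
  # binomial asymptotic variance of M; weights are its reciprocal
  v <- (n_obs - obs[pos]) / (n_obs * obs[pos]) +
    (n_ref - ref[pos]) / (n_ref * ref[pos])
  if (max(abs(M)) < 1e-6) return(1)
  nn <- length(M)
  lo_m <- floor(nn * logratio_trim) + 1
  hi_m <- nn + 1 - lo_m
  lo_a <- floor(nn * abs_trim) + 1
  hi_a <- nn + 1 - lo_a
  rk_m <- rank(M)
  rk_a <- rank(A)
  keep <- rk_m >= lo_m & rk_m <= hi_m & rk_a >= lo_a & rk_a <= hi_a
  f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  2^f
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values normalization: for each sample against a
#' reference sample, per-gene log ratios (M) and average log abundances (A)
#' are computed on the library-size scale, genes with a zero in either
#' sample are excluded, the most extreme 2 x `logratio_trim` of M values and
#' 2 x `abs_trim` of A values are trimmed, and the factor is the weighted
#' mean of the surviving M values with inverse asymptotic-variance weights.
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param counts Count tibble or matrix.
#' @param ref_sample Reference sample name; by default the sample whose
#'   upper-quartile CPM is closest to the mean upper-quartile.
#' @param logratio_trim,abs_trim Two-sided trim fractions on M and A.
#' @return A tibble with columns `sample`, `lib_size`, `norm_factor`.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, logratio_trim = 0.3,
                        abs_trim = 0.05) {
  m <- .as_count_matrix(counts)
  if (ncol(m) < 2) rlang::abort("TMM needs at least 2 samples")
  lib <- colSums(m)
  zero <- lib == 0
  if (any(zero)) {
    rlang::abort(paste0("sample(s) with all-zero counts: ",
                        paste(colnames(m)[zero], collapse = ", ")))
  }
  if (is.null(ref_sample)) {
    uq <- apply(sweep(m, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref_i <- which.min(abs(uq - mean(uq)))
  } else {
    ref_i <- match(ref_sample, colnames(m))
    if (is.na(ref_i)) rlang::abort(paste0("unknown ref_sample: ", ref_sample))
  }
  f <- vapply(seq_len(ncol(m)), function(j) {
    .tmm_pair(m[, j], m[, ref_i], lib[j], lib[ref_i], logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble::tibble(sample = colnames(m), lib_size = unname(lib),
                 norm_factor = unname(f))
}

#' Normalize counts to log2 CPM with TMM effective library sizes
#'
#' CPM are computed against the effective library size (raw total x TMM
#' factor), then shifted by a pseudocount and log2-transformed. The linear
#' CPM matrix is retained alongside, as the differential-expression step
#' works on the linear scale.
#'
#' @param counts Count tibble or matrix.
#' @param factors Output of [tmm_factors()] (computed if `NULL`).
#' @param pseudocount Added on the CPM scale before log2 (default 1).
#' @return An object of class `memory_norm`: list with `log2` and `cpm`
#'   value tibbles (`gene_id` + samples), `samples` (sample, lib_size,
#'   norm_factor) and `pseudocount`.
#' @export
normalize_counts <- function(counts, factors = NULL, pseudocount = 1) {
  m <- .as_count_matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(m)
  stopifnot(all(c("sample", "lib_size", "norm_factor") %in% names(factors)))
  idx <- match(colnames(m), factors$sample)
  if (anyNA(idx)) rlang::abort("factors table does not cover all samples")
  eff <- factors$lib_size[idx] * factors$norm_factor[idx]
  cpm <- sweep(m, 2, eff, "/") * 1e6
  structure(
    list(log2 = .as_value_tibble(log2(cpm + pseudocount)),
         cpm = .as_value_tibble(cpm),
         samples = factors[idx, ],
         pseudocount = pseudocount),
    class = "memory_norm"
  )
}

#' @export
print.memory_norm <- function(x, ...) {
  cat("Normalized expression (log2 CPM-TMM + ", x$pseudocount, "): ",
      nrow(x$log2), " genes x ", nrow(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' PCA quality control of normalized expression
#'
#' Principal component analysis of the samples on the log2 normalized
#' matrix (genes as variables, centered, unscaled), used as a first look at
#' the structure of the experiment: in a stress time course the first
#' component typically tracks time.
#'
#' @param norm A `memory_norm` object.
#' @param design Optional design tibble joined onto the scores by `sample`.
#' @param n_pcs Number of components to report.
#' @return An object of class `memory_pca`: list with `scores` (tibble:
#'   sample, PC columns, design columns if given) and `var_explained`
#'   (fractions of total variance, non-increasing).
#' @export
pca_qc <- function(norm, design = NULL, n_pcs = 10) {
  stopifnot(inherits(norm, "memory_norm"))
  m <- .as_count_matrix(norm$log2)
  if (ncol(m) < 3) rlang::abort("PCA QC needs at least 3 samples")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- dplyr::bind_cols(
    tibble::tibble(sample = colnames(m)),
    tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  )
  if (!is.null(design)) scores <- dplyr::left_join(scores, design, by = "sample")
  structure(
    list(scores = scores,
         var_explained = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)),
    class = "memory_pca"
  )
}
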