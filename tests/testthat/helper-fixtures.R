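# shared fixture builders, all generated in code
suppressPackageStartupMessages({
  library(dplyr)
  library(tidyr)
})

# counts tibble from a plain matrix
counts_tibble <- function(m, genes = sprintf("g%02d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("s%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal two-condition design (one factor column "group")
two_group_design <- function(n_reps = 2) {
  tibble::tibble(
    sample = c(sprintf("A_r%d", seq_len(n_reps)), sprintf("B_r%d", seq_len(n_reps))),
    group = rep(c("A", "B"), each = n_reps)
  )
}

# full factorial design used by the regression tests
factorial_design <- function(n_reps = 3, times = c(0, 15, 20)) {
  d <- tidyr::expand_grid(strain = c("WT", "mip6d"),
                          memory = c("no_memory", "memory"),
                          time = times, replicate = seq_len(n_reps))
  d$sample <- sprintf("%s_%s_t%g_r%d", d$strain, d$memory, d$time, d$replicate)
  d[, c("sample", "strain", "memory", "time", "replicate")]
}

# normalized object with equal library sizes and unit factors, so the cpm
# matrix is an exact rescaling of the input values
norm_from_matrix <- function(m, genes = sprintf("g%02d", seq_len(nrow(m)))) {
  cts <- counts_tibble(m, genes)
  lib <- colSums(m)
  factors <- tibble::tibble(sample = colnames(cts)[-1], lib_size = lib,
                            norm_factor = rep(1, ncol(m)))
  normalize_counts(cts, factors)
}

# normalized object whose log2 slot is exactly `m` (for regression tests)
norm_from_log2 <- function(m, design = NULL,
                           genes = sprintf("g%02d", seq_len(nrow(m)))) {
  if (!is.null(design)) colnames(m) <- design$sample
  rownames(m) <- genes
  structure(
    list(log2 = memorytc:::.as_value_tibble(m),
         cpm = memorytc:::.as_value_tibble(2^m),
         samples = tibble::tibble(sample = colnames(m), lib_size = 1e6,
                                  norm_factor = 1),
         pseudocount = 0),
    class = "memory_norm"
  )
}

# independent literal transcription of the published effect rules, used as
# the classification oracle (scalar, branch-by-branch)
oracle_effect <- function(bt, bi, sig, tol = 1e-9) {
  if (abs(bt) <= tol) return("not_applicable")
  if (!sig) return("no_change")
  s <- bt + bi
  if (s != 0 && sign(s) == -sign(bt)) return("reversed")
  if (abs(s) > abs(bt) + tol) return("enhanced")
  if (abs(s) < abs(bt) - tol) return("dampened")
  "no_change"
}

oracle_interaction <- function(bt, btm, bts, btms, sig, tol = 1e-9) {
  if (abs(bt) <= tol) return("not_applicable")
  if (!sig) return("no_change")
  net <- bt + btm + bts + btms
  additive <- bt + btm + bts
  if (net != 0 && sign(net) == -sign(bt)) return("reversed")
  if (abs(net) > abs(additive) + tol) return("enhanced")
  if (abs(net) < abs(additive) - tol) return("dampened")
  "no_change"
}

# brute-force TMM pairwise factor straight from the published definition,
# written with explicit loops/order() rather than rank arithmetic
oracle_tmm_pair <- function(obs, ref, logratio_trim = 0.3, abs_trim = 0.05) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  keep <- which(obs > 0 & ref > 0)
  M <- A <- w <- numeric(length(keep))
  for (i in seq_along(keep)) {
    g <- keep[i]
    po <- obs[g] / n_obs
    pr <- ref[g] / n_ref
    M[i] <- log2(po / pr)
    A[i] <- 0.5 * log2(po * pr)
    w[i] <- (n_obs - obs[g]) / (n_obs * obs[g]) +
      (n_ref - ref[g]) / (n_ref * ref[g])
  }
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  keep_m <- keep_a <- rep(FALSE, n)
  lo_m <- floor(n * logratio_trim) + 1
  lo_a <- floor(n * abs_trim) + 1
  keep_m[order(M)[lo_m:(n + 1 - lo_m)]] <- TRUE
  keep_a[order(A)[lo_a:(n + 1 - lo_a)]] <- TRUE
  sel <- keep_m & keep_a
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}

# exhaustive double-loop recount of the noise-dominance probability
oracle_noiseq_prob <- function(cpm_a, cpm_b, pseudocount = 0.5) {
  ea <- cpm_a + pseudocount
  eb <- cpm_b + pseudocount
  M <- log2(rowMeans(ea) / rowMeans(eb))
  D <- abs(rowMeans(ea) - rowMeans(eb))
  noise_m <- c()
  noise_d <- c()
  for (e in list(ea, eb)) {
    for (i in seq_len(ncol(e) - 1)) {
      for (j in seq(i + 1, ncol(e))) {
        noise_m <- c(noise_m, log2(e[, i] / e[, j]))
        noise_d <- c(noise_d, abs(e[, i] - e[, j]))
      }
    }
  }
  out <- numeric(nrow(ea))
  for (g in seq_len(nrow(ea))) {
    hits <- 0
    for (k in seq_along(noise_m)) {
      if (abs(noise_m[k]) < abs(M[g]) && noise_d[k] < D[g]) hits <- hits + 1
    }
    out[g] <- hits / length(noise_m)
  }
  out
}
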