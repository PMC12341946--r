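# OLS with per-coefficient t-tests; X columns must be named
.ols <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  aliased <- is.na(beta)
  df <- fit$df.residual
  res <- fit$residuals
  rss <- sum(res^2)
  sigma2 <- if (df > 0) rss / df else NA_real_
  se <- rep(NA_real_, length(beta))
  if (!any(aliased) && df > 0) {
    R <- qr.R(fit$qr)
    piv <- fit$qr$pivot
    cov_unscaled <- chol2inv(R)
    ord <- order(piv)
    se <- sqrt(diag(cov_unscaled)[ord] * sigma2)
  }
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  list(beta = beta, se = se, statistic = tval, p = pval, df = df,
       rss = rss, sigma = sqrt(sigma2),
       r2 = if (tss > 0) 1 - rss / tss else NA_real_,
       degenerate = any(aliased))
}

#' Fit the full time-course model to one gene
#'
#' Ordinary least squares of a gene's (log2-scale) expression on the
#' 12-column design of [build_design()], with per-coefficient t-tests.
#'
#' @param y Numeric expression vector, one value per design row.
#' @param X Design matrix from [build_design()].
#' @return A tibble with one row per term: `term`, `estimate`, `se`,
#'   `statistic`, `p`, plus attributes `r2`, `sigma`, `df` and `degenerate`
#'   (TRUE when the fit is rank deficient; aliased terms get NA).
#' @export
fit_gene <- function(y, X) {
  stopifnot(length(y) == nrow(X))
  f <- .ols(X, y)
  out <- tibble::tibble(term = colnames(X), estimate = unname(f$beta),
                        se = unname(f$se), statistic = unname(f$statistic),
                        p = unname(f$p))
  attr(out, "r2") <- f$r2
  attr(out, "sigma") <- f$sigma
  attr(out, "df") <- f$df
  attr(out, "degenerate") <- f$degenerate
  out
}

#' Fit the time-course model to every gene
#'
#' Fits the full quadratic factorial model of [mtc_terms()] to each gene of
#' a normalized matrix by OLS on the log2 scale, and computes per gene the
#' F-test of the whole time family (the 8 columns involving `t` or `t^2`)
#' against the time-free reduced model. That F-test p-value drives the
#' time-significance filter; the per-term t-tests drive the later stepwise
#' refinement.
#'
#' @param norm A `memory_norm` object.
#' @param design Design tibble (sample, strain, memory, time).
#' @param ref_strain,ref_memory Passed to [build_design()].
#' @return An object of class `memory_fits`: list with `coef` (long tibble:
#'   gene_id, term, estimate, se, statistic, p for the full model), `genes`
#'   (gene_id, r2, sigma, df, p_time), the design matrix `X`, the response
#'   matrix `Y`, and the `design` tibble.
#' @export
fit_timecourse <- function(norm, design, ref_strain = NULL,
                           ref_memory = NULL) {
  stopifnot(inherits(norm, "memory_norm"))
  X <- build_design(design, ref_strain, ref_memory)
  Y <- .as_count_matrix(norm$log2)
  idx <- match(rownames(X), colnames(Y))
  if (anyNA(idx)) rlang::abort("design samples missing from the normalized matrix")
  Y <- Y[, idx, drop = FALSE]

  n <- nrow(X)
  p <- ncol(X)
  qx <- qr(X)
  coefs <- qr.coef(qx, t(Y))            # p x genes
  fitted <- X %*% coefs
  rss <- colSums((t(Y) - fitted)^2)
  df <- n - p
  sigma2 <- rss / df
  cov_unscaled <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot)]
  se <- sqrt(outer(diag(cov_unscaled), sigma2)) # p x genes
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df)
  ybar <- rowMeans(Y)
  tss <- rowSums((Y - ybar)^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)

  time_cols <- grepl("^t", colnames(X))
  X0 <- X[, !time_cols, drop = FALSE]
  q0 <- qr(X0)
  rss0 <- colSums((t(Y) - X0 %*% qr.coef(q0, t(Y)))^2)
  k <- sum(time_cols)
  fstat <- ((rss0 - rss) / k) / (rss / df)
  p_time <- stats::pf(fstat, k, df, lower.tail = FALSE)

  genes <- rownames(Y)
  coef_tbl <- tibble::tibble(
    gene_id = rep(genes, each = p),
    term = rep(colnames(X), times = length(genes)),
    estimate = as.vector(coefs),
    se = as.vector(se),
    statistic = as.vector(tval),
    p = as.vector(pval)
  )
  structure(
    list(coef = coef_tbl,
         genes = tibble::tibble(gene_id = genes, r2 = unname(r2),
                                sigma = unname(sqrt(sigma2)), df = df,
                                p_time = unname(p_time)),
         X = X, Y = Y, design = design,
         alpha = NULL, final = NULL, time_filter = NULL),
    class = "memory_fits"
  )
}

#' Keep genes with a significant time trend
#'
#' Tests each gene's association with time via the F-test of the full model
#' against the model with every linear and quadratic time term removed,
#' adjusts the p-values across genes by Benjamini-Hochberg, and keeps genes
#' with adjusted p at or below `fdr`. Under a flat null the F-test p-values
#' are uniform, so the fraction of flat genes retained is FDR-controlled.
#'
#' @param fits A `memory_fits` object.
#' @param fdr BH false-discovery-rate cutoff (default 0.05).
#' @return The `memory_fits` object restricted to time-significant genes,
#'   with a `time_filter` tibble recording `p_time`, `q_time` and `kept`
#'   for every input gene.
#' @export
filter_time_significant <- function(fits, fdr = 0.05) {
  stopifnot(inherits(fits, "memory_fits"))
  q <- stats::p.adjust(fits$genes$p_time, method = "BH")
  kept <- q <= fdr
  filter_tbl <- tibble::tibble(gene_id = fits$genes$gene_id,
                               p_time = fits$genes$p_time,
                               q_time = q, kept = kept)
  keep_ids <- filter_tbl$gene_id[kept]
  fits$genes <- dplyr::filter(fits$genes, .data$gene_id %in% keep_ids)
  fits$coef <- dplyr::filter(fits$coef, .data$gene_id %in% keep_ids)
  fits$Y <- fits$Y[rownames(fits$Y) %in% keep_ids, , drop = FALSE]
  fits$time_filter <- filter_tbl
  fits
}

#' Hierarchy-respecting backward stepwise refinement
#'
#' Per gene, iteratively removes the least significant removable term with
#' p > `alpha` and refits, until every removable retained term is
#' significant. A term is removable only when no retained higher-order term
#' marginalizes it (contains its factors and at least its polynomial
#' degree), so e.g. `t:memory:strain` in the model forces `t:memory`,
#' `t:strain`, `t`, `memory:strain`, `memory` and `strain` to stay. The
#' intercept is never removed; an intercept-only model is a legal endpoint.
#'
#' @param fits A `memory_fits` object (typically after
#'   [filter_time_significant()]).
#' @param alpha Per-term significance level (default 0.05).
#' @return The `memory_fits` object with a `final` long tibble (gene_id,
#'   term, estimate, se, p, retained; dropped terms have NA estimates) and
#'   per-gene `r2_final` appended to `genes`.
#' @export
backward_stepwise <- function(fits, alpha = 0.05) {
  stopifnot(inherits(fits, "memory_fits"))
  X <- fits$X
  marg <- .marginalizers()
  terms <- colnames(X)
  p <- length(terms)
  genes <- rownames(fits$Y)

  one_gene <- function(y) {
    retained <- rep(TRUE, p)
    repeat {
      f <- .ols(X[, retained, drop = FALSE], y)
      pv <- rep(NA_real_, p)
      pv[retained] <- f$p
      removable <- retained & terms != "intercept" &
        !vapply(seq_len(p), function(i) any(retained & marg[i, ]), logical(1))
      cand <- which(removable & pv > alpha)
      if (length(cand) == 0) {
        est <- se <- rep(NA_real_, p)
        est[retained] <- f$beta
        se[retained] <- f$se
        return(list(estimate = est, se = se, p = pv, retained = retained,
                    r2 = f$r2))
      }
      retained[cand[which.max(pv[cand])]] <- FALSE
    }
  }

  res <- lapply(seq_along(genes), function(g) one_gene(fits$Y[g, ]))
  fits$final <- tibble::tibble(
    gene_id = rep(genes, each = p),
    term = rep(terms, times = length(genes)),
    estimate = unlist(lapply(res, `[[`, "estimate"), use.names = FALSE),
    se = unlist(lapply(res, `[[`, "se"), use.names = FALSE),
    p = unlist(lapply(res, `[[`, "p"), use.names = FALSE),
    retained = unlist(lapply(res, `[[`, "retained"), use.names = FALSE)
  )
  fits$genes$r2_final <- vapply(res, `[[`, numeric(1), "r2")
  fits$alpha <- alpha
  fits
}

#' @export
print.memory_fits <- function(x, ...) {
  cat("Time-course fits:", nrow(x$genes), "genes,",
      ncol(x$X), "model terms\n")
  if (!is.null(x$time_filter)) {
    cat("  time filter: ", sum(x$time_filter$kept), "/",
        nrow(x$time_filter), " genes kept\n", sep = "")
  }
  if (!is.null(x$final)) {
    cat("  stepwise refinement done (alpha =", x$alpha, ")\n")
  }
  invisible(x)
}
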