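#' Classify a factor's effect on a gene's time trend
#'
#' Compares the modulated slope `beta_time + beta_interaction` with the
#' reference slope `beta_time`:
#'
#' * opposite signs — the factor flips the trend: `reversed` (the sign
#'   check takes precedence over the magnitude check);
#' * larger magnitude (by more than `tol`) — `enhanced`;
#' * smaller magnitude (by more than `tol`) — `dampened` (an exact sum of
#'   zero is total suppression and is also `dampened`: no opposite sign
#'   exists);
#' * within `tol`, or `significant` is `FALSE` — `no_change`.
#'
#' All arguments are vectorized.
#'
#' @param beta_time Reference linear slope (log2 units per minute); must be
#'   nonzero — genes without a linear trend get `not_applicable`.
#' @param beta_interaction The factor's linear interaction coefficient
#'   (use 0 for terms dropped by the stepwise refinement).
#' @param significant Logical: is the interaction coefficient significant?
#'   `FALSE` forces `no_change` regardless of magnitudes.
#' @param tol Tolerance on the magnitude comparison (default 1e-9).
#' @return Character vector in `enhanced`, `dampened`, `reversed`,
#'   `no_change`, `not_applicable`.
#' @export
classify_effect <- function(beta_time, beta_interaction, significant,
                            tol = 1e-9) {
  n <- max(length(beta_time), length(beta_interaction), length(significant))
  bt <- rep_len(beta_time, n)
  bi <- rep_len(beta_interaction, n)
  sig <- rep_len(significant, n)
  s <- bt + bi
  out <- rep("no_change", n)
  out[abs(s) > abs(bt) + tol] <- "enhanced"
  out[abs(s) < abs(bt) - tol] <- "dampened"
  out[sign(s) != 0 & sign(s) == -sign(bt)] <- "reversed"
  out[!sig] <- "no_change"
  out[abs(bt) <= tol] <- "not_applicable"
  out
}

#' @rdname classify_effect
#' @param beta_time_strain Linear time-by-strain interaction coefficient.
#' @export
classify_strain <- function(beta_time, beta_time_strain, significant,
                            tol = 1e-9) {
  classify_effect(beta_time, beta_time_strain, significant, tol)
}

#' Classify the memory-by-strain interaction effect
#'
#' The three-way coefficient `beta_tms` captures departures from additivity
#' of the memory and strain modulations. The net slope in the doubly
#' exposed cell (memory = 1, mutant strain),
#' `net = beta_time + beta_tm + beta_ts + beta_tms`, is compared with the
#' additive expectation `beta_time + beta_tm + beta_ts`: a sign flip of the
#' net slope relative to `beta_time` is `reversed`; a larger magnitude than
#' the additive expectation is `enhanced`; smaller is `dampened`. A
#' non-significant (or dropped) `beta_tms` gives `no_change`.
#'
#' @param beta_time,beta_tm,beta_ts,beta_tms Linear slope coefficients
#'   (dropped terms as 0); vectorized.
#' @param significant Logical significance of `beta_tms`.
#' @param tol Magnitude-comparison tolerance.
#' @return Character vector as in [classify_effect()].
#' @export
classify_interaction <- function(beta_time, beta_tm, beta_ts, beta_tms,
                                 significant, tol = 1e-9) {
  n <- max(length(beta_time), length(beta_tm), length(beta_ts),
           length(beta_tms), length(significant))
  bt <- rep_len(beta_time, n)
  net <- bt + rep_len(beta_tm, n) + rep_len(beta_ts, n) + rep_len(beta_tms, n)
  additive <- net - rep_len(beta_tms, n)
  out <- rep("no_change", n)
  out[abs(net) > abs(additive) + tol] <- "enhanced"
  out[abs(net) < abs(additive) - tol] <- "dampened"
  out[sign(net) != 0 & sign(net) == -sign(bt)] <- "reversed"
  out[!rep_len(significant, n)] <- "no_change"
  out[abs(bt) <= tol] <- "not_applicable"
  out
}

#' Direction of the heat-shock response
#'
#' A gene is `induced` when its fitted expression rises over the time course
#' in the reference cell (wild type, no memory) and `repressed` when it
#' falls. The sign of the linear slope decides; when the linear term is
#' absent (or exactly zero) the sign of the fitted net change between the
#' first and last time point, `beta_t * (t_max - t_min) +
#' beta_t2 * (t_max^2 - t_min^2)`, is used instead.
#'
#' @param beta_t,beta_t2 Linear and quadratic time coefficients in the
#'   reference cell (dropped terms as 0); vectorized.
#' @param t_min,t_max First and last time point (minutes).
#' @param tol Values within `tol` of zero count as zero.
#' @return Character vector: `induced`, `repressed`, or `NA` when the gene
#'   has no fitted time trend at all.
#' @export
assign_direction <- function(beta_t, beta_t2, t_min = 0, t_max = 20,
                             tol = 1e-9) {
  n <- max(length(beta_t), length(beta_t2))
  bt <- rep_len(beta_t, n)
  bt2 <- rep_len(beta_t2, n)
  net <- bt * (t_max - t_min) + bt2 * (t_max^2 - t_min^2)
  key <- ifelse(abs(bt) > tol, bt, net)
  ifelse(abs(key) <= tol, NA_character_,
         ifelse(key > 0, "induced", "repressed"))
}

#' Classify every fitted gene's memory, strain and interaction effects
#'
#' Applies [classify_effect()], [classify_strain()] and
#' [classify_interaction()] to the stepwise-refined fits. Only the linear
#' interaction coefficients are used for the labels (quadratic interactions
#' are ignored by the classification, as they are nearly collinear with the
#' linear ones over a short time course); dropped coefficients count as 0.
#'
#' Two routes of evidence are available for calling a factor significant,
#' and the default combines them:
#'
#' * `"stepwise"` — the coefficient survived backward elimination and its
#'   final-model p-value passes BH adjustment across genes. High power, but
#'   p-values of retained terms are selection-biased (a removable retained
#'   term has p below the stepwise alpha by construction).
#' * `"family"` — the F-test comparing the full model with the model
#'   lacking both of the factor's time-interaction columns (linear and
#'   quadratic) passes BH across genes. Selection-free (uniform p under the
#'   null, so genuinely FDR-controlled) and robust to the strong
#'   linear-quadratic collinearity, but a 2-df test with somewhat less
#'   power for purely linear modulation.
#' * `"combined"` (default) — either route suffices.
#' * `"pointwise"` — raw final-model p <= `alpha` (no multiplicity
#'   adjustment), for comparability with single-gene analyses.
#'
#' Whatever the gate, a factor whose linear coefficient was dropped yields
#' a modulated slope equal to the reference slope and hence `no_change`.
#'
#' @param fits A `memory_fits` object after [backward_stepwise()].
#' @param gate `"combined"`, `"stepwise"`, `"family"` or `"pointwise"`.
#' @param fdr,alpha Cutoffs for the gates.
#' @param tol Magnitude-comparison tolerance.
#' @param t_min,t_max Time range for [assign_direction()]; defaults are
#'   taken from the design.
#' @return A tibble of class `memory_classes`: `gene_id`, `direction`,
#'   `memory_effect`, `strain_effect`, `interaction_effect`, and the
#'   coefficients used (`beta_t`, `beta_t2`, `beta_t_memory`,
#'   `beta_t_strain`, `beta_t_memory_strain`).
#' @export
classify_genes <- function(fits, gate = c("combined", "stepwise", "family",
                                          "pointwise"),
                           fdr = 0.05, alpha = 0.05, tol = 1e-9,
                           t_min = NULL, t_max = NULL) {
  stopifnot(inherits(fits, "memory_fits"))
  if (is.null(fits$final)) {
    rlang::abort("run backward_stepwise() before classify_genes()")
  }
  gate <- match.arg(gate)
  if (is.null(t_min)) t_min <- min(fits$design$time)
  if (is.null(t_max)) t_max <- max(fits$design$time)

  wide <- function(col, fill) {
    fits$final %>%
      dplyr::select("gene_id", "term", dplyr::all_of(col)) %>%
      tidyr::pivot_wider(names_from = "term", values_from = dplyr::all_of(col),
                         values_fill = fill)
  }
  est <- wide("estimate", NA_real_)
  pv <- wide("p", NA_real_)
  ret <- wide("retained", FALSE)

  g0 <- function(x) ifelse(is.na(x), 0, x)
  fam <- if (gate %in% c("combined", "family")) {
    .family_tests(fits, est$gene_id)
  } else NULL
  sig_of <- function(term) {
    fam_sig <- if (!is.null(fam)) stats::p.adjust(fam[[term]], "BH") <= fdr
    if (gate == "family") return(fam_sig)
    p <- ifelse(ret[[term]], pv[[term]], 1)
    p[is.na(p)] <- 1
    step_sig <- if (gate == "pointwise") p <= alpha & ret[[term]]
                else stats::p.adjust(p, "BH") <= fdr & ret[[term]]
    if (gate == "combined") step_sig | fam_sig else step_sig
  }

  bt <- g0(est$t)
  bt2 <- g0(est$t2)
  out <- tibble::tibble(
    gene_id = est$gene_id,
    direction = assign_direction(bt, bt2, t_min, t_max, tol),
    memory_effect = classify_effect(bt, g0(est$t_memory),
                                    sig_of("t_memory"), tol),
    strain_effect = classify_strain(bt, g0(est$t_strain),
                                    sig_of("t_strain"), tol),
    interaction_effect = classify_interaction(
      bt, g0(est$t_memory), g0(est$t_strain), g0(est$t_memory_strain),
      sig_of("t_memory_strain"), tol),
    beta_t = bt, beta_t2 = bt2,
    beta_t_memory = g0(est$t_memory),
    beta_t_strain = g0(est$t_strain),
    beta_t_memory_strain = g0(est$t_memory_strain)
  )
  class(out) <- c("memory_classes", class(out))
  out
}

# full-vs-reduced F-test per factor family: p-values of dropping
# {t_factor, t2_factor} from the full model, per gene, keyed by the
# linear term name so sig_of() can look them up
.family_tests <- function(fits, gene_order) {
  X <- fits$X
  Y <- fits$Y[match(gene_order, rownames(fits$Y)), , drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  df <- n - p
  rss_full <- colSums((t(Y) - X %*% qr.coef(qr(X), t(Y)))^2)
  fams <- list(t_memory = c("t_memory", "t2_memory"),
               t_strain = c("t_strain", "t2_strain"),
               t_memory_strain = c("t_memory_strain", "t2_memory_strain"))
  lapply(fams, function(cols) {
    X0 <- X[, setdiff(colnames(X), cols), drop = FALSE]
    rss0 <- colSums((t(Y) - X0 %*% qr.coef(qr(X0), t(Y)))^2)
    fstat <- ((rss0 - rss_full) / length(cols)) / (rss_full / df)
    unname(stats::pf(fstat, length(cols), df, lower.tail = FALSE))
  })
}

#' Overlap of genes affected by memory, strain and their interaction
#'
#' Counts genes in every combination of "significantly affected by memory",
#' "... by strain" and "... by the interaction" (an effect label other than
#' `no_change`/`not_applicable`), the numbers behind an UpSet display.
#'
#' @param classes A [classify_genes()] result.
#' @return A tibble with logical columns `memory`, `strain`, `interaction`
#'   (all 8 combinations) and `n`; the counts sum to the number of genes.
#' @export
overlap_summary <- function(classes) {
  hit <- function(x) x %in% c("enhanced", "dampened", "reversed")
  tab <- classes %>%
    dplyr::mutate(memory = hit(.data$memory_effect),
                  strain = hit(.data$strain_effect),
                  interaction = hit(.data$interaction_effect)) %>%
    dplyr::count(.data$memory, .data$strain, .data$interaction)
  tidyr::complete(tab,
                  memory = c(FALSE, TRUE), strain = c(FALSE, TRUE),
                  interaction = c(FALSE, TRUE), fill = list(n = 0L)) %>%
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Compare class proportions of a gene subset against the background
#'
#' For each effect category, tests whether its proportion in a user-supplied
#' gene subset (e.g. targets of a chromatin regulator) differs from its
#' proportion among all classified genes, with a two-proportion z-test
#' (pooled standard error) and a normal-approximation 95% confidence
#' interval on the difference (unpooled standard error).
#'
#' @param subset_ids Character vector of gene IDs (intersected with the
#'   classified genes).
#' @param classes A [classify_genes()] result (the background).
#' @param effect Which effect column to tabulate: `"interaction"`,
#'   `"memory"` or `"strain"`.
#' @param conf_level Confidence level for the interval.
#' @return A tibble: `category`, `n_subset`, `n_background`, `prop_subset`,
#'   `prop_background`, `diff`, `ci_lo`, `ci_hi`, `z`, `p`.
#' @export
proportion_test <- function(subset_ids, classes,
                            effect = c("interaction", "memory", "strain"),
                            conf_level = 0.95) {
  effect <- match.arg(effect)
  col <- paste0(effect, "_effect")
  sub <- classes$gene_id %in% subset_ids
  if (!any(sub)) rlang::abort("no subset gene is present among the classified genes")
  n1 <- sum(sub)
  n0 <- nrow(classes)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  cats <- sort(unique(classes[[col]]))
  purrr::map(cats, function(cc) {
    x1 <- sum(classes[[col]][sub] == cc)
    x0 <- sum(classes[[col]] == cc)
    p1 <- x1 / n1
    p0 <- x0 / n0
    d <- p1 - p0
    pp <- (x1 + x0) / (n1 + n0)
    se_pool <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n0))
    se_un <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
    z <- if (se_pool == 0 || d == 0) 0 else d / se_pool
    tibble::tibble(category = cc, n_subset = x1, n_background = x0,
                   prop_subset = p1, prop_background = p0, diff = d,
                   ci_lo = d - zq * se_un, ci_hi = d + zq * se_un,
                   z = z, p = if (z == 0) 1 else 2 * stats::pnorm(-abs(z)))
  }) %>%
    dplyr::bind_rows()
}
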