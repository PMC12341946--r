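#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale first. Then, per
#' condition and biological replicate, `dCt = Ct_target - Ct_reference`;
#' `ddCt = dCt - dCt_calibrator` (paired by biological replicate); and the
#' relative quantity is `RQ = 2^-ddCt`, assuming perfect doubling per cycle.
#' By construction `RQ = 1` for every calibrator replicate, and RQ is
#' invariant to adding a constant to every Ct.
#'
#' @param ct Tibble with columns `gene`, `condition`, `bio_rep`,
#'   `tech_rep`, `ct` (cycles, finite and > 0).
#' @param target Target gene name.
#' @param reference_gene Reference gene (e.g. `SCR1`), required in every
#'   (condition, biological replicate) cell.
#' @param calibrator_condition Condition whose dCt is subtracted (e.g. the
#'   unstressed time zero).
#' @return A tibble per (condition, biological replicate): `gene`,
#'   `condition`, `bio_rep`, `delta_ct`, `delta_delta_ct`, `rq`.
#' @export
ddct <- function(ct, target, reference_gene, calibrator_condition) {
  need <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0) {
    rlang::abort(paste0("Ct table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    rlang::abort("Ct values must be finite and > 0")
  }
  if (!calibrator_condition %in% ct$condition) {
    rlang::abort(paste0("calibrator condition '", calibrator_condition,
                        "' absent from the Ct table"))
  }
  mean_ct <- ct %>%
    dplyr::filter(.data$gene %in% c(target, reference_gene)) %>%
    dplyr::group_by(.data$gene, .data$condition, .data$bio_rep) %>%
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  cells <- dplyr::distinct(mean_ct, .data$condition, .data$bio_rep)
  ref <- dplyr::filter(mean_ct, .data$gene == reference_gene)
  missing_ref <- dplyr::anti_join(cells, ref, by = c("condition", "bio_rep"))
  if (nrow(missing_ref) > 0) {
    rlang::abort(paste0(
      "reference gene '", reference_gene, "' missing in cell(s): ",
      paste(paste0(missing_ref$condition, "/rep", missing_ref$bio_rep),
            collapse = ", ")))
  }
  tgt <- dplyr::filter(mean_ct, .data$gene == target)
  if (nrow(tgt) == 0) {
    rlang::abort(paste0("target gene '", target, "' absent from the Ct table"))
  }
  dct <- dplyr::inner_join(
    dplyr::select(tgt, "condition", "bio_rep", ct_target = "ct"),
    dplyr::select(ref, "condition", "bio_rep", ct_ref = "ct"),
    by = c("condition", "bio_rep")
  ) %>%
    dplyr::mutate(delta_ct = .data$ct_target - .data$ct_ref)
  cal <- dct %>%
    dplyr::filter(.data$condition == calibrator_condition) %>%
    dplyr::select("bio_rep", delta_ct_cal = "delta_ct")
  if (nrow(cal) == 0) {
    rlang::abort(paste0("no target measurement in calibrator condition '",
                        calibrator_condition, "'"))
  }
  dct %>%
    dplyr::inner_join(cal, by = "bio_rep") %>%
    dplyr::mutate(gene = target,
                  delta_delta_ct = .data$delta_ct - .data$delta_ct_cal,
                  rq = 2^(-.data$delta_delta_ct)) %>%
    dplyr::select("gene", "condition", "bio_rep", "delta_ct",
                  "delta_delta_ct", "rq")
}

#' Per-condition summary of relative quantities
#'
#' Mean and standard error of both the relative quantity and the ddCt, per
#' condition (error bars on either scale are conventional).
#'
#' @param rq A [ddct()] result.
#' @return A tibble: `gene`, `condition`, `n`, `mean_rq`, `se_rq`,
#'   `mean_ddct`, `se_ddct`.
#' @export
ddct_summary <- function(rq) {
  rq %>%
    dplyr::group_by(.data$gene, .data$condition) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_rq = mean(.data$rq),
      se_rq = stats::sd(.data$rq) / sqrt(dplyr::n()),
      mean_ddct = mean(.data$delta_delta_ct),
      se_ddct = stats::sd(.data$delta_delta_ct) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Two-tailed paired t-test
#'
#' Classic paired t statistic `t = mean(d) / (sd(d) / sqrt(n))` on the
#' replicate-paired differences `d = a - b`, with `n - 1` degrees of
#' freedom. Degenerate cases are handled explicitly: identical vectors give
#' `t = 0, p = 1`; constant nonzero differences give an infinite statistic
#' and `p = 0` with a warning.
#'
#' @param a,b Equal-length numeric vectors (>= 2 values), paired by
#'   position (replicate).
#' @return A one-row tibble: `estimate` (mean difference), `t`, `df`, `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("a and b must have equal length")
  if (length(a) < 2) rlang::abort("need at least 2 pairs")
  d <- a - b
  n <- length(d)
  sdd <- stats::sd(d)
  m <- mean(d)
  if (sdd == 0) {
    if (m == 0) {
      return(tibble::tibble(estimate = 0, t = 0, df = n - 1, p = 1))
    }
    rlang::warn("differences are constant and nonzero: t is infinite, p -> 0")
    return(tibble::tibble(estimate = m, t = sign(m) * Inf, df = n - 1, p = 0))
  }
  tval <- m / (sdd / sqrt(n))
  tibble::tibble(estimate = m, t = tval, df = n - 1,
                 p = 2 * stats::pt(-abs(tval), n - 1))
}

#' Read a Ct table from TSV
#'
#' @param path TSV with columns `gene`, `condition`, `bio_rep`, `tech_rep`,
#'   `ct`.
#' @return A tibble.
#' @export
read_ct <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
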