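#' Read gene sets from GMT or two-column TSV
#'
#' GMT: one set per line, tab-separated `set_id`, `description`,
#' members... Two-column TSV: header `set_id`, `gene_id` (a `set_name`
#' column is honored when present).
#'
#' @param path File path; format chosen by the `.gmt` extension.
#' @return A long tibble: `set_id`, `set_name`, `gene_id`.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    purrr::map(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) {
        rlang::abort("malformed GMT line: need id, description and >= 1 member")
      }
      tibble::tibble(set_id = f[1], set_name = f[2], gene_id = f[-(1:2)])
    }) %>%
      dplyr::bind_rows()
  } else {
    tb <- readr::read_tsv(path, show_col_types = FALSE)
    if (!all(c("set_id", "gene_id") %in% names(tb))) {
      rlang::abort("gene-set TSV needs columns set_id and gene_id")
    }
    if (!"set_name" %in% names(tb)) tb$set_name <- tb$set_id
    dplyr::select(tb, "set_id", "set_name", "gene_id")
  }
}

#' Gene-set over-representation by Fisher's exact test
#'
#' One-sided (over-representation) hypergeometric test of a query gene list
#' against each gene set, within a stated universe, with Benjamini-Hochberg
#' correction across sets. Query and set members are validated against the
#' universe first; unmatched query IDs are reported via a warning and an
#' `unmatched` attribute. Sets with no member in the universe are not
#' testable and are dropped.
#'
#' @param query_ids Character vector of query gene IDs.
#' @param sets Long tibble from [read_gene_sets()] (columns `set_id`,
#'   `gene_id`, optional `set_name`).
#' @param universe_ids All genes the query was drawn from (e.g. every gene
#'   surviving the low-count filter).
#' @param q_cutoff BH-adjusted p cutoff applied when `filter = TRUE`.
#' @param filter Keep only sets with `q < q_cutoff` (default TRUE).
#' @return A tibble: `set_id`, `set_name`, `k` (query hits), `n` (query
#'   size), `K` (set size in universe), `N` (universe size), `odds_ratio`,
#'   `fold_enrichment` = `(k/n)/(K/N)`, `p`, `q`; sorted by `p`.
#' @export
fisher_enrich <- function(query_ids, sets, universe_ids, q_cutoff = 0.05,
                          filter = TRUE) {
  universe <- unique(universe_ids)
  if (length(universe) == 0) rlang::abort("empty universe")
  query <- unique(query_ids)
  if (length(query) == 0) rlang::abort("empty query")
  unmatched <- setdiff(query, universe)
  if (length(unmatched) > 0) {
    rlang::warn(paste0(length(unmatched),
                       " query ID(s) absent from the universe were dropped"))
    query <- intersect(query, universe)
    if (length(query) == 0) rlang::abort("no query gene is in the universe")
  }
  N <- length(universe)
  n <- length(query)
  per_set <- sets %>%
    dplyr::filter(.data$gene_id %in% universe) %>%
    dplyr::group_by(.data$set_id) %>%
    dplyr::summarise(
      set_name = dplyr::first(if ("set_name" %in% names(sets)) .data$set_name
                              else .data$set_id),
      K = dplyr::n_distinct(.data$gene_id),
      k = sum(unique(.data$gene_id) %in% query),
      .groups = "drop"
    )
  if (nrow(per_set) == 0) rlang::abort("no gene set overlaps the universe")
  res <- per_set %>%
    dplyr::mutate(
      n = n, N = N,
      odds_ratio = dplyr::case_when(
        .data$k == 0 ~ 0,
        (n - .data$k) * (.data$K - .data$k) == 0 ~ Inf,
        TRUE ~ (.data$k * (N - .data$K - n + .data$k)) /
          ((n - .data$k) * (.data$K - .data$k))
      ),
      fold_enrichment = (.data$k / n) / (.data$K / N),
      p = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                        lower.tail = FALSE)
    ) %>%
    dplyr::mutate(q = bh_adjust(.data$p)) %>%
    dplyr::select("set_id", "set_name", "k", "n", "K", "N", "odds_ratio",
                  "fold_enrichment", "p", "q") %>%
    dplyr::arrange(.data$p)
  attr(res, "unmatched") <- unmatched
  if (filter) res <- dplyr::filter(res, .data$q < q_cutoff)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (a thin,
#' name-stable wrapper around `stats::p.adjust(method = "BH")`).
#'
#' @param pvals Numeric p-values.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}
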