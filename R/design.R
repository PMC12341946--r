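#' Model terms of the time-course regression
#'
#' The per-gene model is a quadratic polynomial in time (minutes) with all
#' interactions of the linear and quadratic terms with two binary factors,
#' memory and strain:
#'
#' \deqn{y = b0 + bM M + bS S + bMS MS + bT t + bTM tM + bTS tS + bTMS tMS
#'       + bT2 t^2 + bT2M t^2 M + bT2S t^2 S + bT2MS t^2 MS + e}
#'
#' `M` and `S` are 0/1 indicators (reference levels: no-memory, wild type),
#' so every coefficient is interpreted relative to the naive wild-type
#' response. Returns the 12 model terms with their factor content and
#' polynomial degree, used to enforce marginality during backward stepwise
#' elimination.
#'
#' @return A tibble with columns `term`, `memory`, `strain` (0/1 factor
#'   involvement) and `degree` (polynomial degree in time).
#' @export
mtc_terms <- function() {
  tibble::tibble(
    term = c("intercept", "memory", "strain", "memory_strain",
             "t", "t_memory", "t_strain", "t_memory_strain",
             "t2", "t2_memory", "t2_strain", "t2_memory_strain"),
    memory = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
    strain = c(0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1, 1),
    degree = c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2)
  )
}

# marginality: term j "marginalizes" term i when i's factor set and degree
# are both contained in j's (i may not be removed while j is retained)
.marginalizers <- function() {
  tm <- mtc_terms()
  k <- nrow(tm)
  out <- matrix(FALSE, k, k, dimnames = list(tm$term, tm$term))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      out[i, j] <- tm$memory[i] <= tm$memory[j] &&
        tm$strain[i] <= tm$strain[j] &&
        tm$degree[i] <= tm$degree[j]
    }
  }
  out
}

.infer_reference <- function(values, preferred) {
  lv <- unique(values)
  hit <- intersect(preferred, lv)
  if (length(hit) > 0) hit[1] else lv[1]
}

#' Build the time-course design matrix
#'
#' Expands a sample design table into the 12-column model matrix of
#' [mtc_terms()]. Memory and strain are coded 0/1 against reference levels;
#' time enters in raw minutes (no centering or scaling), so linear
#' coefficients are log2-expression change per minute and quadratic ones per
#' minute squared. Coefficient signs depend on the reference coding, which
#' is therefore stated explicitly in the returned attributes.
#'
#' @param design A data frame with columns `sample`, `strain`, `memory`,
#'   `time` (minutes).
#' @param ref_strain,ref_memory Reference levels. Defaults: `"WT"` if
#'   present (else the first strain observed), and the first of
#'   `"no_memory"`, `"no-memory"`, `"naive"` present (else the first memory
#'   level observed).
#' @return A numeric matrix (samples x 12) with row names `design$sample`,
#'   column names `mtc_terms()$term`, and attributes `ref_strain`,
#'   `ref_memory`.
#' @export
build_design <- function(design, ref_strain = NULL, ref_memory = NULL) {
  stopifnot(is.data.frame(design))
  need <- c("sample", "strain", "memory", "time")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) {
    rlang::abort(paste0("design table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (length(unique(design$strain)) != 2) {
    rlang::abort("design must contain exactly 2 strain levels")
  }
  if (length(unique(design$memory)) != 2) {
    rlang::abort("design must contain exactly 2 memory levels")
  }
  if (length(unique(design$time)) < 3) {
    rlang::abort("design must contain at least 3 distinct time points")
  }
  if (is.null(ref_strain)) ref_strain <- .infer_reference(design$strain, "WT")
  if (is.null(ref_memory)) {
    ref_memory <- .infer_reference(design$memory,
                                   c("no_memory", "no-memory", "naive"))
  }
  M <- as.numeric(design$memory != ref_memory)
  S <- as.numeric(design$strain != ref_strain)
  t <- as.numeric(design$time)
  X <- cbind(
    intercept = 1, memory = M, strain = S, memory_strain = M * S,
    t = t, t_memory = t * M, t_strain = t * S, t_memory_strain = t * M * S,
    t2 = t^2, t2_memory = t^2 * M, t2_strain = t^2 * S,
    t2_memory_strain = t^2 * M * S
  )
  rownames(X) <- design$sample
  if (qr(X)$rank < ncol(X)) {
    rlang::abort("design matrix is rank deficient; the full factorial model is not estimable")
  }
  attr(X, "ref_strain") <- ref_strain
  attr(X, "ref_memory") <- ref_memory
  X
}

# counts tibble (gene_id + sample columns) -> integer matrix
.as_count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  m
}

.as_value_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
}
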