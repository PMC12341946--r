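#' Configure a factorial memory time-course simulation
#'
#' Builds the parameter set of the negative binomial count simulator. The
#' defaults emulate a bulk yeast heat-shock experiment: two strains (wild
#' type and a mutant) x two prior-exposure conditions (memory / no-memory)
#' x three time points (0, 15, 20 min of heat shock) x three biological
#' replicates, ~6,000 expressed genes.
#'
#' Per-gene expression follows the quadratic time-course model of
#' [mtc_terms()] on the log2 scale. Each gene gets a direction (induced,
#' repressed or flat), a linear time slope `beta_t` (log2 units per minute),
#' and a saturating quadratic tie `beta_t2 = quad_ratio * beta_t` (the
#' default `-1/(2*max(times))` makes the trend level off at the last time
#' point, mimicking the strong linear-quadratic coupling seen in short
#' stress time courses). Memory, strain, and their interaction modulate the
#' linear slope:
#'
#' * `dampened`   — the factor shrinks the slope (same sign, smaller |.|);
#'   slope multiplier drawn so the interaction coefficient is between 50%
#'   and 80% of `|beta_t|` (the response persists at reduced intensity; it
#'   is not abolished).
#' * `enhanced`   — the factor amplifies the slope (50–100% of `|beta_t|`
#'   added with the same sign).
#' * `reversed`   — the factor flips the sign of the trend (interaction
#'   between 150% and 250% of `|beta_t|`, opposite sign).
#' * `no_change`  — interaction coefficient exactly 0.
#'
#' The drawn coefficients always satisfy the classifier's comparison rules,
#' so applying [classify_effect()] to the truth reproduces the declared
#' classes exactly.
#'
#' @param n_genes,n_reps Number of genes and biological replicates.
#' @param times Time points in minutes (>= 3 distinct values).
#' @param strains,memory_levels Two labels each; the first is the reference
#'   level (wild type, naive).
#' @param dispersion NB dispersion phi > 0 (`variance = mu + phi * mu^2`).
#'   Values below `1e-6` are treated as the exact noiseless limit and yield
#'   deterministic rounded means.
#' @param lib_size_mean,lib_size_cv Expected total counts per sample and
#'   their log-normal coefficient of variation.
#' @param class_proportions,strain_proportions,interaction_proportions
#'   Named proportions over `dampened`, `enhanced`, `reversed`, `no_change`
#'   for the memory, strain and interaction effects (each must sum to 1).
#' @param direction_proportions Named proportions over `induced`,
#'   `repressed`, `flat`. Flat genes have every time-family coefficient 0.
#' @param effect_scale Typical `|beta_t|` in log2 units per minute; slopes
#'   are drawn uniformly in `[0.5, 1.5] * effect_scale`.
#' @param quad_ratio Ratio `beta_t2 / beta_t` for the base trend.
#' @param quad_ratio_interaction Ratio tying each quadratic interaction
#'   coefficient to its linear counterpart (default: same as `quad_ratio`,
#'   so every cell's trend saturates in proportion to its own slope; set to
#'   0 for purely linear modulation).
#' @param baseline_range Range of baseline log2 mean expression.
#' @param baseline_sd SD of the additive (time-independent) memory, strain
#'   and memory:strain offsets on the log2 scale.
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 6000,
                       n_reps = 3,
                       times = c(0, 15, 20),
                       strains = c("WT", "mip6d"),
                       memory_levels = c("no_memory", "memory"),
                       dispersion = 0.1,
                       lib_size_mean = 5e6,
                       lib_size_cv = 0.2,
                       class_proportions = c(dampened = 0.4, enhanced = 0.15,
                                             reversed = 0.1, no_change = 0.35),
                       strain_proportions = c(dampened = 0.10, enhanced = 0.05,
                                              reversed = 0.05, no_change = 0.80),
                       interaction_proportions = c(dampened = 0.05,
                                                   enhanced = 0.03,
                                                   reversed = 0.02,
                                                   no_change = 0.90),
                       direction_proportions = c(induced = 0.25,
                                                 repressed = 0.25,
                                                 flat = 0.5),
                       effect_scale = 0.3,
                       quad_ratio = -1 / (2 * max(times)),
                       quad_ratio_interaction = quad_ratio,
                       baseline_range = c(3, 10),
                       baseline_sd = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_reps = n_reps, times = times, strains = strains,
    memory_levels = memory_levels, dispersion = dispersion,
    lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
    class_proportions = class_proportions,
    strain_proportions = strain_proportions,
    interaction_proportions = interaction_proportions,
    direction_proportions = direction_proportions,
    effect_scale = effect_scale, quad_ratio = quad_ratio,
    quad_ratio_interaction = quad_ratio_interaction,
    baseline_range = baseline_range, baseline_sd = baseline_sd,
    seed = as.integer(seed)
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.check_props <- function(p, what) {
  lev <- c("dampened", "enhanced", "reversed", "no_change")
  if (!all(names(p) %in% lev) || is.null(names(p))) {
    rlang::abort(paste0(what, " must be named with ",
                        paste(lev, collapse = ", ")))
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    rlang::abort(paste0(what, " must be non-negative and sum to 1"))
  }
  out <- stats::setNames(rep(0, length(lev)), lev)
  out[names(p)] <- p
  out
}

.validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_reps >= 1)
  if (length(unique(cfg$times)) < 3) {
    rlang::abort("times must contain at least 3 distinct values")
  }
  if (cfg$dispersion <= 0) rlang::abort("dispersion must be > 0")
  if (length(cfg$strains) != 2 || length(cfg$memory_levels) != 2) {
    rlang::abort("exactly 2 strains and 2 memory levels are required")
  }
  if (cfg$lib_size_cv < 0) rlang::abort("lib_size_cv must be >= 0")
  .check_props(cfg$class_proportions, "class_proportions")
  .check_props(cfg$strain_proportions, "strain_proportions")
  .check_props(cfg$interaction_proportions, "interaction_proportions")
  dp <- cfg$direction_proportions
  if (!all(names(dp) %in% c("induced", "repressed", "flat")) ||
      abs(sum(dp) - 1) > 1e-9 || any(dp < 0)) {
    rlang::abort("direction_proportions must be named induced/repressed/flat and sum to 1")
  }
  invisible(cfg)
}

# draw a linear-slope modulation coefficient realizing `class` given beta_t
.draw_modulation <- function(class, beta_t) {
  n <- length(beta_t)
  mult <- numeric(n)
  idx <- class == "dampened"
  mult[idx] <- -stats::runif(sum(idx), 0.5, 0.8)
  idx <- class == "enhanced"
  mult[idx] <- stats::runif(sum(idx), 0.5, 1.0)
  idx <- class == "reversed"
  mult[idx] <- -stats::runif(sum(idx), 1.5, 2.5)
  mult * beta_t
}

# draw the three-way interaction coefficient realizing `class` given the
# net additive slope A = bt + btm + bts in the (memory, mutant) cell
.draw_interaction <- function(class, beta_t, additive) {
  n <- length(beta_t)
  sgn <- sign(beta_t)
  net <- additive
  idx <- class == "reversed"
  net[idx] <- -sgn[idx] * stats::runif(sum(idx), 0.5, 1.5) * abs(beta_t[idx])
  idx <- class == "enhanced"
  net[idx] <- sgn[idx] *
    (abs(additive[idx]) + stats::runif(sum(idx), 0.3, 1.0) * abs(beta_t[idx]))
  idx <- class == "dampened"
  net[idx] <- sgn[idx] * stats::runif(sum(idx), 0.1, 0.7) * abs(additive[idx])
  net - additive
}

#' Simulate a factorial memory time-course count matrix
#'
#' Draws a gene x sample integer count matrix from the generative model
#' described in [sim_config()]: for gene g and sample j,
#' `mu_gj = s_j * 2^(x_j' beta_g)` with `x_j` the model row of
#' [build_design()] and `s_j` a library scaling factor calibrated so the
#' expected sample total equals the drawn library size; counts are
#' `NB(mu, phi)` (all biological and technical noise is realized by this
#' draw). Dispersions below `1e-6` are the noiseless limit: counts are the
#' rounded means.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `memory_sim` with elements `counts` (tibble,
#'   `gene_id` + one column per sample), `design` (tibble: sample, strain,
#'   memory, time, replicate), `truth` (per-gene generating coefficients,
#'   direction and declared classes) and `config`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  dirs <- .check_dir_sample(config$direction_proportions, n)
  flat <- dirs == "flat"
  sgn <- ifelse(dirs == "induced", 1, ifelse(dirs == "repressed", -1, 0))
  beta_t <- sgn * stats::runif(n, 0.5, 1.5) * config$effect_scale
  beta_t2 <- config$quad_ratio * beta_t

  mem_class <- .class_sample(config$class_proportions, n)
  str_class <- .class_sample(config$strain_proportions, n)
  int_class <- .class_sample(config$interaction_proportions, n)
  mem_class[flat] <- "no_change"
  str_class[flat] <- "no_change"
  int_class[flat] <- "no_change"

  beta_tm <- .draw_modulation(mem_class, beta_t)
  beta_ts <- .draw_modulation(str_class, beta_t)
  additive <- beta_t + beta_tm + beta_ts
  beta_tms <- .draw_interaction(int_class, beta_t, additive)

  qri <- config$quad_ratio_interaction
  truth <- tibble::tibble(
    gene_id = gene_id,
    beta_0 = stats::runif(n, config$baseline_range[1], config$baseline_range[2]),
    beta_memory = stats::rnorm(n, 0, config$baseline_sd),
    beta_strain = stats::rnorm(n, 0, config$baseline_sd),
    beta_memory_strain = stats::rnorm(n, 0, config$baseline_sd),
    beta_t = beta_t,
    beta_t_memory = beta_tm,
    beta_t_strain = beta_ts,
    beta_t_memory_strain = beta_tms,
    beta_t2 = beta_t2,
    beta_t2_memory = qri * beta_tm,
    beta_t2_strain = qri * beta_ts,
    beta_t2_memory_strain = qri * beta_tms,
    direction = dirs,
    memory_class = mem_class,
    strain_class = str_class,
    interaction_class = int_class
  )

  design <- tidyr::expand_grid(
    strain = config$strains,
    memory = config$memory_levels,
    time = config$times,
    replicate = seq_len(config$n_reps)
  ) %>%
    dplyr::mutate(sample = sprintf("%s_%s_t%g_r%d", .data$strain,
                                   .data$memory, .data$time, .data$replicate)) %>%
    dplyr::select("sample", "strain", "memory", "time", "replicate")

  X <- build_design(design, ref_strain = config$strains[1],
                    ref_memory = config$memory_levels[1])
  B <- as.matrix(truth[, c("beta_0", "beta_memory", "beta_strain",
                           "beta_memory_strain", "beta_t", "beta_t_memory",
                           "beta_t_strain", "beta_t_memory_strain", "beta_t2",
                           "beta_t2_memory", "beta_t2_strain",
                           "beta_t2_memory_strain")])
  L <- B %*% t(X) # genes x samples, log2 scale
  if (any(!is.finite(L)) || max(abs(L)) > 45) {
    worst <- which.max(apply(abs(L), 1, max))
    rlang::abort(paste0(
      "non-finite expected count for gene of class '",
      truth$memory_class[worst], "' (|log2 mean| too large); ",
      "reduce effect_scale or baseline_range"))
  }
  E <- 2^L
  lib_sizes <- .draw_lib_sizes(ncol(E), config$lib_size_mean, config$lib_size_cv)
  s <- lib_sizes / colSums(E)
  mu <- sweep(E, 2, s, "*")
  if (config$dispersion < 1e-6) {
    cts <- round(mu)
  } else {
    cts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$dispersion),
                  nrow = nrow(mu))
  }
  dimnames(cts) <- list(gene_id, design$sample)
  storage.mode(cts) <- "integer"

  structure(
    list(counts = .as_value_tibble(cts), design = design, truth = truth,
         config = config),
    class = "memory_sim"
  )
}

.class_sample <- function(props, n) {
  sample(names(props), n, replace = TRUE, prob = props)
}

.check_dir_sample <- function(props, n) {
  lev <- c("induced", "repressed", "flat")
  p <- stats::setNames(rep(0, 3), lev)
  p[names(props)] <- props
  sample(lev, n, replace = TRUE, prob = p)
}

.draw_lib_sizes <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Count genes per declared truth class
#'
#' @param truth The `truth` tibble of a [simulate_counts()] result.
#' @param effect Which declared class to tabulate: the memory, strain or
#'   interaction effect.
#' @return A tibble with one row per class label (`dampened`, `enhanced`,
#'   `reversed`, `no_change`, zeros included) and a count `n` summing to the
#'   number of genes.
#' @export
truth_class_counts <- function(truth,
                               effect = c("memory", "strain", "interaction")) {
  effect <- match.arg(effect)
  col <- paste0(effect, "_class")
  lev <- c("dampened", "enhanced", "reversed", "no_change")
  tab <- table(factor(truth[[col]], levels = lev))
  tibble::tibble(class = lev, n = as.integer(tab))
}

#' @export
print.memory_sim <- function(x, ...) {
  cat("Simulated memory time course:",
      nrow(x$truth), "genes x", nrow(x$design), "samples\n")
  cat("  strains:", paste(x$config$strains, collapse = ", "),
      "| memory:", paste(x$config$memory_levels, collapse = ", "),
      "| times (min):", paste(x$config$times, collapse = ", "), "\n")
  cat("  dispersion:", x$config$dispersion,
      "| seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulation to TSV files
#'
#' Writes `counts.tsv` (genes x samples), `design.tsv` and `truth.tsv`.
#'
#' @param sim A `memory_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "memory_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "design.tsv", "truth.tsv"))
  readr::write_tsv(sim$counts, paths[1])
  readr::write_tsv(sim$design, paths[2])
  readr::write_tsv(sim$truth, paths[3])
  invisible(paths)
}

#' Read a count matrix / design table written by [write_sim()]
#'
#' @param path TSV path. The count matrix must have a `gene_id` first column
#'   and one column per sample.
#' @return A tibble.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_counts
#' @export
read_design <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
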