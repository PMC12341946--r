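test_that("identical seeds reproduce the simulation bitwise", {
  a <- simulate_counts(sim_config(n_genes = 60, seed = 1))
  b <- simulate_counts(sim_config(n_genes = 60, seed = 1))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$design, b$design)
  d <- simulate_counts(sim_config(n_genes = 60, seed = 2))
  expect_false(identical(a$counts, d$counts))
})

test_that("zero-effect, zero-noise limit gives constant counts per gene", {
  cfg <- sim_config(
    n_genes = 40, dispersion = 1e-9, lib_size_cv = 0, baseline_sd = 0,
    direction_proportions = c(flat = 1),
    class_proportions = c(no_change = 1),
    strain_proportions = c(no_change = 1),
    interaction_proportions = c(no_change = 1),
    seed = 4
  )
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$counts[-1])
  ranges <- apply(m, 1, function(x) diff(range(x)))
  expect_lte(max(ranges), 1) # integer rounding only
  expect_true(all(sim$truth$beta_t == 0 & sim$truth$beta_t2 == 0))
})

test_that("empirical fold change matches the generative closed form", {
  cfg <- sim_config(n_genes = 2000, n_reps = 3, seed = 8, lib_size_cv = 0)
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$counts[-1])
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  d <- sim$design
  ref0 <- d$sample[d$strain == "WT" & d$memory == "no_memory" & d$time == 0]
  ref20 <- d$sample[d$strain == "WT" & d$memory == "no_memory" & d$time == 20]
  pick <- sim$truth$direction == "induced" &
    sim$truth$memory_class == "no_change" &
    sim$truth$strain_class == "no_change" &
    sim$truth$interaction_class == "no_change"
  expect_gt(sum(pick), 50)
  emp <- log2(rowMeans(cpm[pick, ref20]) / rowMeans(cpm[pick, ref0]))
  # closed form of the generative model on the CPM scale: the per-gene
  # trend plus the shared composition shift of the expression totals
  X <- build_design(sim$design)
  B <- as.matrix(sim$truth[, paste0("beta_", c(
    "0", "memory", "strain", "memory_strain", "t", "t_memory", "t_strain",
    "t_memory_strain", "t2", "t2_memory", "t2_strain", "t2_memory_strain"))])
  totals <- colSums(2^(B %*% t(X)))
  comp <- log2(mean(totals[match(ref0, sim$design$sample)]) /
                 mean(totals[match(ref20, sim$design$sample)]))
  expected <- 20 * sim$truth$beta_t[pick] + 400 * sim$truth$beta_t2[pick] + comp
  expect_lt(abs(mean(emp) - mean(expected)) / abs(mean(expected)), 0.1)
})

test_that("counts have negative binomial mean-variance across replicates", {
  phi <- 0.2
  cfg <- sim_config(
    n_genes = 3000, n_reps = 3, dispersion = phi, lib_size_cv = 0,
    direction_proportions = c(flat = 1), class_proportions = c(no_change = 1),
    strain_proportions = c(no_change = 1),
    interaction_proportions = c(no_change = 1), seed = 12
  )
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$counts[-1]) # flat genes: constant mean over 36 samples
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu > 50
  ratio <- sum(v[keep]) / sum(mu[keep] + phi * mu[keep]^2)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("declared truth classes obey the classifier rules exactly", {
  sim <- simulate_counts(sim_config(n_genes = 800, seed = 5))
  tr <- sim$truth
  nf <- tr$direction != "flat"
  mem <- classify_effect(tr$beta_t[nf], tr$beta_t_memory[nf], TRUE)
  stn <- classify_strain(tr$beta_t[nf], tr$beta_t_strain[nf], TRUE)
  int <- classify_interaction(tr$beta_t[nf], tr$beta_t_memory[nf],
                              tr$beta_t_strain[nf],
                              tr$beta_t_memory_strain[nf],
                              tr$interaction_class[nf] != "no_change")
  expect_identical(mem, tr$memory_class[nf])
  expect_identical(stn, tr$strain_class[nf])
  expect_identical(int, tr$interaction_class[nf])
  expect_true(all(tr$beta_t[!nf] == 0 & tr$beta_t2[!nf] == 0 &
                    tr$beta_t_memory[!nf] == 0))
})

test_that("truth class counts conserve genes and match proportions", {
  cfg <- sim_config(n_genes = 300, seed = 9,
                    class_proportions = c(dampened = 1),
                    direction_proportions = c(induced = 1))
  sim <- simulate_counts(cfg)
  tab <- truth_class_counts(sim$truth)
  expect_equal(sum(tab$n), 300)
  expect_equal(tab$n[tab$class == "dampened"], 300)

  cfg2 <- sim_config(n_genes = 4000, seed = 10,
                     class_proportions = c(enhanced = 0.25, dampened = 0.5,
                                           no_change = 0.25),
                     direction_proportions = c(induced = 1))
  tab2 <- truth_class_counts(simulate_counts(cfg2)$truth)
  expect_equal(sum(tab2$n), 4000)
  for (cl in c("enhanced", "dampened", "no_change")) {
    p <- c(enhanced = 0.25, dampened = 0.5, no_change = 0.25)[[cl]]
    sigma <- sqrt(4000 * p * (1 - p))
    expect_lt(abs(tab2$n[tab2$class == cl] - 4000 * p), 3 * sigma)
  }
})

test_that("unrepresentable configurations are rejected with clear errors", {
  expect_error(sim_config(class_proportions = c(dampened = 0.6)), "sum to 1")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(times = c(0, 15)), "3 distinct")
  cfg <- sim_config(n_genes = 20, effect_scale = 3,
                    baseline_range = c(30, 40), seed = 1)
  expect_error(simulate_counts(cfg), "class")
})

test_that("simulation round-trips through TSV files", {
  sim <- simulate_counts(sim_config(n_genes = 25, seed = 3))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  cts <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(as.data.frame(cts), as.data.frame(sim$counts))
  des <- read_design(file.path(dir, "design.tsv"))
  expect_equal(as.data.frame(des), as.data.frame(sim$design))
})
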