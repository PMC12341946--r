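test_that("effect classification follows the comparison rules", {
  expect_equal(classify_effect(2, -1, TRUE), "dampened")
  expect_equal(classify_effect(2, -5, TRUE), "reversed")
  expect_equal(classify_effect(1, 0.5, TRUE), "enhanced")
  expect_equal(classify_effect(-1, -0.5, TRUE), "enhanced")
  expect_equal(classify_effect(-2, 1.2, TRUE), "dampened")
  expect_equal(classify_effect(-2, 4, TRUE), "reversed")
  # significance gate dominates magnitudes
  expect_equal(classify_effect(2, -5, FALSE), "no_change")
  # exact tie within tolerance
  expect_equal(classify_effect(2, 0, TRUE), "no_change")
  expect_equal(classify_effect(2, 1e-12, TRUE), "no_change")
  # total suppression is dampening, not reversal
  expect_equal(classify_effect(2, -2, TRUE), "dampened")
  # no linear trend
  expect_equal(classify_effect(0, 1, TRUE), "not_applicable")
  # strain rule is the same comparison
  expect_equal(classify_strain(2, -1, TRUE), "dampened")
  expect_equal(classify_strain(1, 0.5, TRUE), "enhanced")
  expect_equal(classify_strain(2, -5, TRUE), "reversed")
})

test_that("interaction classification compares net against additive slope", {
  expect_equal(classify_interaction(2, -0.5, -0.5, 0, FALSE), "no_change")
  expect_equal(classify_interaction(2, -0.5, -0.5, -0.5, TRUE), "dampened")
  expect_equal(classify_interaction(2, -0.5, -0.5, 0.5, TRUE), "enhanced")
  expect_equal(classify_interaction(2, -0.5, -0.5, -1.5, TRUE), "reversed")
})

test_that("classification agrees with a literal rule-table oracle on random draws", {
  set.seed(40)
  n <- 1000
  bt <- runif(n, -2, 2)
  bt[sample(n, 50)] <- 0
  bi <- runif(n, -3, 3)
  bts <- runif(n, -1, 1)
  btms <- runif(n, -1, 1)
  sig <- runif(n) > 0.3
  got_e <- classify_effect(bt, bi, sig)
  got_i <- classify_interaction(bt, bi, bts, btms, sig)
  exp_e <- exp_i <- character(n)
  for (k in seq_len(n)) {
    exp_e[k] <- oracle_effect(bt[k], bi[k], sig[k])
    exp_i[k] <- oracle_interaction(bt[k], bi[k], bts[k], btms[k], sig[k])
  }
  expect_identical(got_e, exp_e)
  expect_identical(got_i, exp_i)
})

test_that("labels are scale-equivariant in the time coefficients", {
  set.seed(41)
  bt <- runif(200, -1, 1)
  bi <- runif(200, -2, 2)
  for (cc in c(0.01, 3, 1000)) {
    expect_identical(classify_effect(cc * bt, cc * bi, TRUE),
                     classify_effect(bt, bi, TRUE))
  }
})

test_that("direction comes from the linear slope, else the fitted net change", {
  expect_equal(assign_direction(1, 0), "induced")
  expect_equal(assign_direction(-1, 0), "repressed")
  # quadratic-only: net change over [0, 20] decides
  expect_equal(assign_direction(0, 0.01, t_min = 0, t_max = 20), "induced")
  expect_equal(assign_direction(0, -0.01, t_min = 0, t_max = 20), "repressed")
  expect_true(is.na(assign_direction(0, 0)))
})

test_that("overlap summary counts every intersection and conserves genes", {
  mk <- function(m, s, i) {
    tibble::tibble(gene_id = sprintf("g%02d", seq_along(m)),
                   direction = "induced",
                   memory_effect = m, strain_effect = s,
                   interaction_effect = i)
  }
  only_mem <- mk(rep("dampened", 5), rep("no_change", 5), rep("no_change", 5))
  os <- overlap_summary(only_mem)
  expect_equal(sum(os$n), 5)
  expect_equal(os$n[os$memory & !os$strain & !os$interaction], 5L)

  set.seed(42)
  lv <- c("dampened", "enhanced", "reversed", "no_change")
  m <- sample(lv, 30, replace = TRUE)
  s <- sample(lv, 30, replace = TRUE)
  i <- sample(lv, 30, replace = TRUE)
  os2 <- overlap_summary(mk(m, s, i))
  expect_equal(sum(os2$n), 30)
  hand <- table(memory = m != "no_change", strain = s != "no_change",
                interaction = i != "no_change")
  for (r in seq_len(nrow(os2))) {
    expect_equal(
      os2$n[r],
      as.integer(hand[as.character(os2$memory[r]),
                      as.character(os2$strain[r]),
                      as.character(os2$interaction[r])])
    )
  }
})

test_that("proportion test matches the textbook two-proportion z statistic", {
  classes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    direction = "induced",
    memory_effect = "no_change", strain_effect = "no_change",
    interaction_effect = rep(c("dampened", "no_change"), c(30, 70))
  )
  subset_ids <- sprintf("g%03d", 1:20) # 20 dampened of 20
  pt <- proportion_test(subset_ids, classes)
  row <- pt[pt$category == "dampened", ]
  p1 <- 1; p0 <- 0.3
  pp <- (20 + 30) / (20 + 100)
  z_hand <- (p1 - p0) / sqrt(pp * (1 - pp) * (1 / 20 + 1 / 100))
  expect_equal(row$z, z_hand)
  expect_equal(row$p, 2 * pnorm(-abs(z_hand)))
  expect_equal(row$p,
               prop.test(c(20, 30), c(20, 100), correct = FALSE)$p.value)
  # subset = everything: zero difference, p = 1
  pt_all <- proportion_test(classes$gene_id, classes)
  expect_true(all(pt_all$diff == 0))
  expect_true(all(pt_all$p == 1))
})

test_that("random subsets of the background are rarely called significant", {
  set.seed(43)
  lv <- c("dampened", "enhanced", "reversed", "no_change")
  classes <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:500),
    direction = "induced",
    memory_effect = "no_change", strain_effect = "no_change",
    interaction_effect = sample(lv, 500, replace = TRUE,
                                prob = c(0.3, 0.1, 0.05, 0.55))
  )
  rejections <- replicate(200, {
    pt <- proportion_test(sample(classes$gene_id, 80), classes)
    any(pt$p < 0.05)
  })
  # the overlapping-samples z-test is conservative; bound the rate from above
  n_cat <- 4
  bound <- 0.05 * n_cat + 3 * sqrt(0.05 * n_cat * (1 - 0.05 * n_cat) / 200)
  expect_lte(mean(rejections), bound)
})

test_that("pipeline classification is exhaustive and exclusive per gene", {
  sim <- simulate_counts(sim_config(n_genes = 300, seed = 16))
  norm <- normalize_counts(filter_low_counts(sim$counts))
  fits <- backward_stepwise(filter_time_significant(fit_timecourse(norm, sim$design)))
  cl <- classify_genes(fits)
  lv <- c("enhanced", "dampened", "reversed", "no_change", "not_applicable")
  expect_equal(nrow(cl), nrow(fits$genes))
  expect_equal(anyDuplicated(cl$gene_id), 0L)
  for (col in c("memory_effect", "strain_effect", "interaction_effect")) {
    expect_true(all(cl[[col]] %in% lv))
  }
  expect_true(all(is.na(cl$direction) |
                    cl$direction %in% c("induced", "repressed")))
})
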