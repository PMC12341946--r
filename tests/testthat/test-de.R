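test_that("identical conditions give M = 0, D = 0, prob = 0", {
  set.seed(3)
  rep_a <- matrix(rpois(40, 100) + 1, 20, 2)
  m <- cbind(rep_a, rep_a) # condition B identical to condition A
  colnames(m) <- c("A_r1", "A_r2", "B_r1", "B_r2")
  norm <- norm_from_matrix(m)
  de <- noiseq_probability(norm, two_group_design(), list(group = "A"),
                           list(group = "B"))
  expect_equal(de$M, rep(0, 20))
  expect_equal(de$D, rep(0, 20))
  expect_equal(de$prob, rep(0, 20))
  expect_equal(de$signed_fc, rep(1, 20))
})

test_that("probability equals an exhaustive double-loop recount", {
  set.seed(7)
  m <- matrix(rpois(80, 60) + 1, 20, 4)
  m[1:5, 3:4] <- m[1:5, 3:4] * 4L
  colnames(m) <- c("A_r1", "A_r2", "B_r1", "B_r2")
  norm <- norm_from_matrix(m)
  de <- noiseq_probability(norm, two_group_design(), list(group = "A"),
                           list(group = "B"))
  cpm <- as.matrix(norm$cpm[-1])
  expected <- oracle_noiseq_prob(cpm[, 1:2], cpm[, 3:4])
  expect_identical(de$prob, expected)
})

test_that("a single strong shift among tight replicates is called with prob > 0.99", {
  set.seed(8)
  base <- rpois(200, 500)
  m <- cbind(A_r1 = base, A_r2 = base + rpois(200, 2),
             B_r1 = base + rpois(200, 2), B_r2 = base + rpois(200, 2))
  m[1, 3:4] <- m[1, 3:4] * 100L
  norm <- norm_from_matrix(m)
  de <- noiseq_probability(norm, two_group_design(), list(group = "B"),
                           list(group = "A"))
  expect_gt(de$prob[1], 0.99)
})

test_that("swapping conditions negates M and mirrors the labels", {
  set.seed(9)
  m <- matrix(rpois(120, 80) + 1, 30, 4)
  m[1:10, 1:2] <- m[1:10, 1:2] * 5L
  colnames(m) <- c("A_r1", "A_r2", "B_r1", "B_r2")
  norm <- norm_from_matrix(m)
  ab <- noiseq_probability(norm, two_group_design(), list(group = "A"),
                           list(group = "B"))
  ba <- noiseq_probability(norm, two_group_design(), list(group = "B"),
                           list(group = "A"))
  expect_equal(ba$M, -ab$M)
  expect_equal(ba$prob, ab$prob)
  expect_equal(abs(ba$signed_fc), abs(ab$signed_fc))
  lab_ab <- categorize_fc(ab)$label
  lab_ba <- categorize_fc(ba)$label
  flip <- c(strong_down = "strong_up", down = "up", unchanged = "unchanged",
            up = "down", strong_up = "strong_down")
  expect_equal(as.character(lab_ba), unname(flip[as.character(lab_ab)]))
})

test_that("fold-change categories follow the cutoff rules", {
  de <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6),
    M = 0, D = 1,
    prob = c(0.9, 0.9, 0.5, 0.9, 0.95, 0.9),
    signed_fc = c(2.5, -1.5, 3.0, 1.19, -2.01, 1.2)
  )
  lab <- as.character(categorize_fc(de, prob_threshold = 0.8)$label)
  expect_equal(lab, c("strong_up", "down", "unchanged", "unchanged",
                      "strong_down", "up"))
  # invariant: unchanged iff |fc| < fc_lo or prob below threshold
  cat <- categorize_fc(de, prob_threshold = 0.8)
  expect_equal(cat$label == "unchanged",
               abs(de$signed_fc) < 1.2 | de$prob < 0.8)
})

test_that("missing conditions and missing replication are rejected", {
  m <- matrix(rpois(40, 50) + 1, 10, 4)
  colnames(m) <- c("A_r1", "A_r2", "B_r1", "B_r2")
  norm <- norm_from_matrix(m)
  expect_error(noiseq_probability(norm, two_group_design(),
                                  list(group = "C"), list(group = "A")),
               "no sample")
  d1 <- tibble::tibble(sample = colnames(m),
                       group = c("A", "A", "A", "B"))
  expect_error(noiseq_probability(norm, d1, list(group = "A"),
                                  list(group = "B")), "2 replicates")
})

test_that("transition tables conserve genes and match a hand count", {
  lev <- c("strong_down", "down", "unchanged", "up", "strong_up")
  mk <- function(labels) {
    tibble::tibble(gene_id = sprintf("g%02d", seq_along(labels)),
                   label = factor(labels, levels = lev))
  }
  same <- mk(rep(c("up", "down", "unchanged"), each = 4))
  tt <- transition_table(same, same)
  expect_equal(sum(tt$n), 12)
  expect_equal(sum(tt$n[as.character(tt$from) == as.character(tt$to)]), 12)

  a <- mk(c("up", "up", "up", "down", "down", "unchanged", "unchanged",
            "strong_up", "strong_up", "strong_down", "up", "unchanged"))
  b <- mk(c("strong_up", "up", "unchanged", "down", "up", "unchanged",
            "down", "strong_up", "up", "strong_down", "up", "unchanged"))
  tt2 <- transition_table(a, b)
  expect_equal(sum(tt2$n), 12)
  expect_equal(tt2$n[tt2$from == "up" & tt2$to == "up"], 2L)
  expect_equal(tt2$n[tt2$from == "up" & tt2$to == "strong_up"], 1L)
  expect_equal(tt2$n[tt2$from == "unchanged" & tt2$to == "unchanged"], 2L)
  expect_equal(tt2$n[tt2$from == "strong_down" & tt2$to == "strong_down"], 1L)
  expect_equal(nrow(tt2), 25)
})

test_that("baseline comparisons cover every condition and later time", {
  sim <- simulate_counts(sim_config(n_genes = 120, seed = 13))
  norm <- normalize_counts(filter_low_counts(sim$counts))
  de <- de_vs_baseline(norm, sim$design)
  combos <- dplyr::distinct(de, strain, memory, time)
  expect_equal(nrow(combos), 8) # 2 strains x 2 memory x 2 later times
  expect_true(all(de$prob >= 0 & de$prob <= 1))
  expect_true(all(abs(de$signed_fc) >= 1))
  expect_true(all(sign(de$signed_fc)[de$M != 0] == sign(de$M)[de$M != 0]))
})
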