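toy_spatial <- function() {
  # 3 query cells and 4 target cells (2 subtypes) at hand-set coordinates
  tibble::tibble(
    cell_id = c("q1", "q2", "q3", "t1", "t2", "t3", "t4"),
    sample_id = "s1",
    condition = "c1",
    sx = c(0, 10, 5, 1, 9, 5, 20),
    sy = c(0, 0, 5, 0, 1, 4, 20),
    true_label = c("Q", "Q", "Q", "venous", "capillary", "venous", "capillary")
  )
}

test_that("a single query-target pair is assigned with its distance", {
  sp <- tibble::tibble(
    cell_id = c("q1", "t1"), sample_id = "s1", condition = "c1",
    sx = c(0, 3), sy = c(0, 4), true_label = c("Q", "venous")
  )
  asg <- nearest_target(sp, "Q", "venous", label_column = "true_label")
  expect_equal(asg$target_subtype, "venous")
  expect_equal(asg$distance, 5)
})

test_that("nearest_target matches the brute-force all-pairs minimum", {
  sp <- toy_spatial()
  asg <- nearest_target(sp, "Q", c("venous", "capillary"),
                        label_column = "true_label")
  tg <- sp[4:7, ]
  q <- sp[1:3, ]
  j <- oracle_nearest_target(q$sx, q$sy, tg$sx, tg$sy)
  expect_equal(asg$target_cell_id, tg$cell_id[j])
  expect_equal(asg$target_subtype, tg$true_label[j])

  set.seed(202)
  n <- 200L
  sp2 <- tibble::tibble(
    cell_id = sprintf("c%d", 1:(2 * n)), sample_id = "s1",
    sx = runif(2 * n, 0, 100), sy = runif(2 * n, 0, 100),
    true_label = c(rep("Q", n), sample(c("A", "B"), n, TRUE))
  )
  asg2 <- nearest_target(sp2, "Q", c("A", "B"), label_column = "true_label")
  tg2 <- sp2[sp2$true_label != "Q", ]
  j2 <- oracle_nearest_target(sp2$sx[1:n], sp2$sy[1:n], tg2$sx, tg2$sy)
  expect_equal(asg2$target_cell_id, tg2$cell_id[j2])
})

test_that("equidistant targets resolve to the earlier table row", {
  sp <- tibble::tibble(
    cell_id = c("q1", "t1", "t2"), sample_id = "s1",
    sx = c(0, 1, -1), sy = c(0, 0, 0), true_label = c("Q", "B", "A")
  )
  asg <- nearest_target(sp, "Q", c("A", "B"), label_column = "true_label")
  expect_equal(asg$target_cell_id, "t1")
})

test_that("a sample with query cells but no targets raises a named analysis error", {
  sp <- tibble::tibble(
    cell_id = c("q1", "x1"), sample_id = "bad_sample",
    sx = c(0, 1), sy = c(0, 1), true_label = c("Q", "other")
  )
  expect_error(nearest_target(sp, "Q", "venous", label_column = "true_label"),
               "bad_sample", class = "proxiscore_analysis_error")
})

test_that("nearest targets never cross sample boundaries", {
  sp <- tibble::tibble(
    cell_id = c("q1", "t_far", "t_near_other_sample"),
    sample_id = c("s1", "s1", "s2"),
    sx = c(0, 100, 0.1), sy = c(0, 0, 0),
    true_label = c("Q", "A", "A")
  )
  sp <- rbind(sp, tibble::tibble(cell_id = "q2", sample_id = "s2",
                                 sx = 0, sy = 0, true_label = "Q"))
  asg <- nearest_target(sp, "Q", "A", label_column = "true_label")
  expect_equal(asg$target_cell_id[asg$sample_id == "s1"], "t_far")
  expect_equal(asg$target_cell_id[asg$sample_id == "s2"],
               "t_near_other_sample")
})

test_that("expected proportions are the subtype shares and sum to one", {
  sp <- toy_spatial()
  p0 <- expected_proportions(sp, c("venous", "capillary"),
                             label_column = "true_label")
  expect_equal(sum(p0$p0), 1)
  expect_equal(p0$p0[p0$target_subtype == "venous"], 0.5)

  counts <- tibble::tibble(
    cell_id = sprintf("t%d", 1:10), sample_id = "s1",
    sx = 1:10, sy = 1:10,
    true_label = c(rep("A", 4), rep("B", 6))
  )
  p0b <- expected_proportions(counts, c("A", "B"), label_column = "true_label")
  expect_equal(p0b$p0, c(0.4, 0.6))

  one <- expected_proportions(counts[1:4, ], "A", label_column = "true_label")
  expect_equal(one$p0, 1)
})

test_that("binomial_upper_tail is exact and matches independent oracles", {
  expect_equal(binomial_upper_tail(5, 10, 0.5), 0.623046875)
  expect_equal(binomial_upper_tail(10, 10, 0.5), 2^-10)
  expect_equal(binomial_upper_tail(0, 25, 0.3), 1)
  # direct pmf summation oracle on a grid of cases
  for (case in list(c(3, 12, 0.2), c(7, 40, 0.1), c(19, 20, 0.9),
                    c(1, 5, 0.5), c(250, 500, 0.45))) {
    expect_equal(binomial_upper_tail(case[1], case[2], case[3]),
                 oracle_binom_upper(case[1], case[2], case[3]),
                 tolerance = 1e-12)
  }
  # cross-check against stats::binom.test
  bt <- binom.test(17, 60, p = 0.2, alternative = "greater")
  expect_equal(binomial_upper_tail(17, 60, 0.2), bt$p.value, tolerance = 1e-12)
  expect_error(binomial_upper_tail(11, 10, 0.5),
               class = "proxiscore_value_error")
  expect_error(binomial_upper_tail(5, 10, 1.5),
               class = "proxiscore_value_error")
})

test_that("proximity scores reproduce hand-computed observed/expected ratios", {
  # n_query = 10, p0(A) = 0.4, observed(A) = 7 -> score 1.75
  asg <- tibble::tibble(
    cell_id = sprintf("q%d", 1:10), sample_id = "s1", condition = "c1",
    target_cell_id = "t", distance = 1,
    target_subtype = c(rep("A", 7), rep("B", 3))
  )
  p0 <- tibble::tibble(sample_id = "s1", target_subtype = c("A", "B"),
                       n_targets = c(4L, 6L), p0 = c(0.4, 0.6))
  res <- proximity_scores(asg, p0)
  ps <- res$per_sample
  expect_equal(ps$score[ps$target_subtype == "A"], 7 / (10 * 0.4))
  expect_equal(ps$score[ps$target_subtype == "B"], 3 / (10 * 0.6))
  expect_equal(sum(ps$observed), 10)
  pc <- res$per_condition
  expect_equal(pc$pooled_score[pc$target_subtype == "A"], 1.75)
  expect_equal(pc$p_value[pc$target_subtype == "A"],
               oracle_binom_upper(7, 10, 0.4), tolerance = 1e-12)
})

test_that("a single target subtype always scores exactly 1", {
  asg <- tibble::tibble(
    cell_id = sprintf("q%d", 1:6), sample_id = "s1", condition = "c1",
    target_cell_id = "t", distance = 1, target_subtype = "A"
  )
  p0 <- tibble::tibble(sample_id = "s1", target_subtype = "A",
                       n_targets = 5L, p0 = 1)
  res <- proximity_scores(asg, p0)
  expect_equal(res$per_sample$score, 1)
  expect_equal(res$per_condition$pooled_score, 1)
})

test_that("pooling weights p0 by sample sizes and sem follows the sd formula", {
  asg <- dplyr::bind_rows(
    tibble::tibble(cell_id = sprintf("a%d", 1:10), sample_id = "s1",
                   condition = "c1", target_cell_id = "t", distance = 1,
                   target_subtype = c(rep("A", 6), rep("B", 4))),
    tibble::tibble(cell_id = sprintf("b%d", 1:20), sample_id = "s2",
                   condition = "c1", target_cell_id = "t", distance = 1,
                   target_subtype = c(rep("A", 8), rep("B", 12)))
  )
  p0 <- tibble::tibble(sample_id = c("s1", "s1", "s2", "s2"),
                       target_subtype = c("A", "B", "A", "B"),
                       p0 = c(0.5, 0.5, 0.25, 0.75))
  res <- proximity_scores(asg, p0)
  pc <- res$per_condition
  a <- pc[pc$target_subtype == "A", ]
  expect_equal(a$pooled_n, 30)
  expect_equal(a$pooled_observed, 14)
  expect_equal(a$pooled_p0, (10 * 0.5 + 20 * 0.25) / 30)
  expect_equal(a$pooled_score, 14 / (30 * a$pooled_p0))
  scores <- c(6 / (10 * 0.5), 8 / (20 * 0.25))
  expect_equal(a$condition_mean_score, mean(scores))
  expect_equal(a$condition_sem_score, sd(scores) / sqrt(2))
})

test_that("per-sample test scope and depletion direction are available", {
  asg <- tibble::tibble(
    cell_id = sprintf("q%d", 1:10), sample_id = "s1", condition = "c1",
    target_cell_id = "t", distance = 1,
    target_subtype = c(rep("A", 7), rep("B", 3))
  )
  p0 <- tibble::tibble(sample_id = "s1", target_subtype = c("A", "B"),
                       p0 = c(0.4, 0.6))
  res <- proximity_scores(asg, p0, test_scope = "per-sample")
  ps <- res$per_sample
  expect_equal(ps$p_value[ps$target_subtype == "A"],
               oracle_binom_upper(7, 10, 0.4), tolerance = 1e-12)
  dep <- proximity_scores(asg, p0, alternative = "depletion")
  expect_equal(dep$per_condition$p_value[dep$per_condition$target_subtype == "B"],
               pbinom(3, 10, 0.6), tolerance = 1e-12)
})

test_that("a distance cap drops far assignments before counting", {
  asg <- tibble::tibble(
    cell_id = sprintf("q%d", 1:4), sample_id = "s1", condition = "c1",
    target_cell_id = "t", distance = c(1, 2, 50, 60),
    target_subtype = c("A", "A", "B", "B")
  )
  p0 <- tibble::tibble(sample_id = "s1", target_subtype = c("A", "B"),
                       p0 = c(0.5, 0.5))
  res <- proximity_scores(asg, p0, max_distance = 10)
  expect_equal(unique(res$per_sample$n_query), 2)
  expect_equal(sum(res$per_sample$observed), 2)
})

test_that("null synthetic data give scores near 1 with conserved counts", {
  cfg <- null_config(n = 4000L, seed = 31L,
                     freqs = c(A = 0.25, B = 0.25, Q = 0.5))
  sp <- generate_spatial(cfg, "ctrl", "s1")
  asg <- nearest_target(sp, "Q", c("A", "B"), label_column = "true_label")
  p0 <- expected_proportions(sp, c("A", "B"), label_column = "true_label")
  res <- proximity_scores(asg, p0)
  expect_equal(sum(res$per_sample$observed), nrow(asg))
  expect_true(all(res$per_sample$score >= 0.9 & res$per_sample$score <= 1.1))
})

test_that("rejection rate increases with the planted attraction strength", {
  reps <- 200L
  rates <- vapply(c(0, 0.1, 0.3, 0.6), function(rho) {
    cfg <- enriched_config(n = 400L, rho = rho, attraction_sd = 5, seed = 77L)
    rej <- vapply(seq_len(reps), function(r) {
      sp <- generate_spatial(cfg, "case", sprintf("rep%d", r))
      sample_pvalue(sp, "A")$p < 0.05
    }, logical(1))
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[4], rates[1])
})
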