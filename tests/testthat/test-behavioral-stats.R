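# Zero-safe log transform, Welch tests, split-plot ANOVA, post-hocs.

test_that("zero-safe log adds sqrt(Q1/Q3) only when zeros are present", {
  r <- zero_safe_log(c(1, 2, 3, 4))
  expect_equal(r$constant, 0)
  expect_equal(r$transformed, log(c(1, 2, 3, 4)))

  # sorted {0,1,2,4,4}: Q1 = 1, Q3 = 4 by linear interpolation -> c = 0.5
  r2 <- zero_safe_log(c(4, 0, 2, 4, 1))
  expect_equal(r2$constant, 0.5)
  expect_equal(exp(r2$transformed) - r2$constant, c(4, 0, 2, 4, 1))

  expect_warning(r3 <- zero_safe_log(c(0, 0, 0, 0, 0, 8)), "first quartile")
  expect_equal(r3$constant, 4)
  expect_error(zero_safe_log(c(-1, 2)), "non-negative")
  expect_error(zero_safe_log(c(0, 0)), "all values are zero")
})

test_that("Welch t-test matches the reference implementation", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  mine <- welch_t(a, b)
  ref <- stats::t.test(a, b)  # Welch is t.test's default
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p, ref$p.value)

  set.seed(8)
  for (r in 1:5) {
    x <- rnorm(sample(4:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(4:12, 1), 1, sd = runif(1, 0.5, 3))
    mine <- welch_t(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic))
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p, ref$p.value)
  }
})

test_that("Welch test is antisymmetric and agrees with its summary form", {
  set.seed(10)
  a <- rnorm(9); b <- rnorm(7, 0.5)
  fwd <- welch_t(a, b); rev <- welch_t(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$df, rev$df)
  expect_equal(fwd$p, rev$p)

  summ <- welch_t_from_summary(mean(a), sd(a), length(a),
                               mean(b), sd(b), length(b))
  expect_equal(summ$t, fwd$t)
  expect_equal(summ$df, fwd$df)
  expect_equal(summ$p, fwd$p)

  eq <- welch_t_from_summary(5, 1, 10, 5, 3, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_error(welch_t_from_summary(1, 0, 5, 1, 0, 5), "variances")
  expect_error(welch_t(c(1, 1), c(1, 1)), "variances")
})

test_that("split-plot ANOVA matches aov across random unbalanced designs", {
  set.seed(21)
  for (r in 1:4) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    subj <- c(sprintf("a%d", 1:n1), sprintf("b%d", 1:n2))
    geno <- rep(c("G1", "G2"), c(n1, n2))
    df <- expand.grid(animal_id = subj, treatment = c("t1", "t2"),
                      stringsAsFactors = FALSE)
    df$genotype <- geno[match(df$animal_id, subj)]
    df$attack_duration_s <- rnorm(nrow(df), 10, 2) +
      rnorm(length(subj), 0, 1.5)[match(df$animal_id, subj)]
    mine <- mixed_rm_anova(df)
    ref <- summary(stats::aov(
      attack_duration_s ~ genotype * treatment + Error(animal_id / treatment),
      data = df))
    btw <- ref[["Error: animal_id"]][[1]]
    wth <- ref[["Error: animal_id:treatment"]][[1]]
    expect_equal(mine$effects$F[1], btw[["F value"]][1])
    expect_equal(mine$effects$F[2], wth[["F value"]][1])
    expect_equal(mine$effects$F[3], wth[["F value"]][2])
    expect_equal(mine$effects$SS, c(btw$`Sum Sq`[1], wth$`Sum Sq`[1:2]))
    expect_equal(mine$errors$SS, c(btw$`Sum Sq`[2], wth$`Sum Sq`[3]))
    expect_equal(mine$effects$p[1], btw[["Pr(>F)"]][1])
    expect_equal(mine$effects$p[2:3], wth[["Pr(>F)"]][1:2])
  }
})

test_that("ANOVA is location invariant and collapses a null within factor", {
  co <- simulate_cohort(sim_cohort_params(n_per_genotype = 8L,
                                          ages_months = 7L,
                                          zero_prob = 0, seed = 14L))
  a1 <- mixed_rm_anova(co)
  co2 <- co; co2$attack_duration_s <- co2$attack_duration_s + 100
  a2 <- mixed_rm_anova(co2)
  expect_equal(a1$effects$F, a2$effects$F)
  expect_equal(a1$effects$SS, a2$effects$SS)

  # duplicating each subject's value across both treatments kills SS_within
  co3 <- co
  first <- co3[co3$treatment == "vehicle", ]
  co3$attack_duration_s <- first$attack_duration_s[
    match(co3$animal_id, first$animal_id)]
  a3 <- mixed_rm_anova(co3)
  expect_lt(a3$effects$SS[2], 1e-18)
  expect_lt(a3$effects$SS[3], 1e-18)
})

test_that("incomplete subjects are dropped and counted", {
  co <- simulate_cohort(sim_cohort_params(n_per_genotype = 5L,
                                          ages_months = 7L,
                                          zero_prob = 0, seed = 6L))
  co_m <- co[!(co$animal_id == "SAMR1_01" & co$treatment == "drug"), ]
  a <- mixed_rm_anova(co_m)
  expect_equal(a$n_dropped, 1L)
  expect_equal(a$n_subjects, 9L)
  expect_error(mixed_rm_anova(co[co$genotype == "SAMP8", ]), "between factor")
})

test_that("Tukey HSD uses the right error strata and reduces at k = 2", {
  co <- read_cohort(toy_cohort_path())
  a <- mixed_rm_anova(co)
  tk <- tukey_hsd(a)
  expect_equal(nrow(tk), 6L)
  # hand-computed q statistics for the toy data (MS_w = 0.5, MS_b = 23/6)
  row_wd <- tk[tk$cell1 == "SAMP8:drug" & tk$cell2 == "SAMP8:vehicle", ]
  expect_equal(row_wd$q, 3.5 / sqrt(0.5 / 2 * (1 / 4 + 1 / 4)))
  expect_equal(row_wd$df, 6L)
  row_gv <- tk[tk$cell1 == "SAMP8:vehicle" & tk$cell2 == "SAMR1:vehicle", ]
  expect_equal(row_gv$q, 4 / sqrt((23 / 6) / 2 * (1 / 4 + 1 / 4)))
  expect_equal(row_gv$p_adj,
               stats::ptukey(row_gv$q, 4, 6, lower.tail = FALSE))

  # equal cell means (permuted within-cell values) give adjusted p = 1
  co_eq <- co
  co_eq$attack_duration_s[co_eq$genotype == "SAMP8" &
                            co_eq$treatment == "drug"] <- c(13, 10, 12, 11)
  tk_eq <- tukey_hsd(mixed_rm_anova(co_eq))
  same <- tk_eq[tk_eq$cell1 == "SAMP8:drug" & tk_eq$cell2 == "SAMP8:vehicle", ]
  expect_equal(same$q, 0)
  expect_equal(same$p_adj, 1)
})

test_that("Sidak adjustment is exact and monotone", {
  expect_equal(sidak_adjust(0, m = 5), 0)
  expect_equal(sidak_adjust(c(0.2, 0.7), m = 2), 1 - (1 - c(0.2, 0.7))^2)
  expect_equal(round(sidak_adjust(0.0253, m = 2), 4), 0.0500)
  expect_equal(sidak_adjust(0.3, m = 1), 0.3)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_adjust(p, m = length(p))) >= 0))
  expect_true(all(sidak_adjust(p, m = length(p) + 4) >=
                    sidak_adjust(p, m = length(p))))
  expect_error(sidak_adjust(1.2), "0, 1")
  expect_error(sidak_adjust(c(0.1, 0.2), m = 1), "m")
})

test_that("Welch power on simulated cohorts tracks the normal approximation", {
  # genotype shift of one within-group SD, n = 18/group, alpha = 0.05
  sd_tot <- sqrt(0.6^2 + 0.5^2)
  nrep <- 2000L
  hits <- 0L
  for (r in seq_len(nrep)) {
    co <- simulate_cohort(sim_cohort_params(
      n_per_genotype = 18L, ages_months = 5L, genotype_effect = sd_tot,
      onset_age_months = 5L, zero_prob = 0, crossover_age_months = 0L,
      seed = 5000L + r))
    lv <- log(co$attack_duration_s)
    w <- welch_t(lv[co$genotype == "SAMP8"], lv[co$genotype == "SAMR1"])
    if (w$p < 0.05) hits <- hits + 1L
  }
  power_hat <- hits / nrep
  power_ref <- stats::pnorm(sqrt(18 / 2) - stats::qnorm(0.975)) +
    stats::pnorm(-sqrt(18 / 2) - stats::qnorm(0.975))
  expect_lt(abs(power_hat - power_ref), 0.05)
})
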