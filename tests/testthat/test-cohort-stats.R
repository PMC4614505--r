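test_that("balanced one-factor lsmeans are geometric means", {
  rec <- data.frame(genotype = rep(c("a", "b"), each = 3),
                    modulus_Pa = c(2, 4, 8, 16, 16, 16))
  fit <- fit_log_model(rec, "genotype")
  ls <- lsmeans_log(fit)
  expect_equal(ls$lsmean[ls$group == "a"], 4)        # geometric mean
  expect_equal(ls$lsmean[ls$group == "b"], 16)
  expect_equal(ls$lsmean_log[ls$group == "a"], mean(log(c(2, 4, 8))))
})

test_that("unbalanced two-factor lsmeans match the emmeans oracle", {
  library(emmeans)
  set.seed(21)
  rec <- data.frame(
    genotype = sample(c("WT", "OIM"), 37, TRUE),
    medium = sample(c("air", "PBS"), 37, TRUE),
    modulus_Pa = rlnorm(37, 15, 0.6))
  fit <- fit_log_model(rec, c("genotype", "medium"))
  for (f in c("genotype", "medium")) {
    mine <- lsmeans_log(fit, f)
    em <- as.data.frame(emmeans::emmeans(fit$lm, f))
    o1 <- order(mine$group); o2 <- order(as.character(em[[f]]))
    expect_equal(mine$lsmean_log[o1], em$emmean[o2], tolerance = 1e-8)
    expect_equal(mine$se_log[o1], em$SE[o2], tolerance = 1e-8)
  }
  # cell lsmeans match the interaction grid predictions too
  cells <- lsmeans_log(fit)
  emc <- as.data.frame(emmeans::emmeans(fit$lm, c("genotype", "medium")))
  expect_equal(sort(cells$lsmean_log), sort(emc$emmean), tolerance = 1e-8)
})

test_that("model fitting validates inputs and degenerate designs", {
  expect_error(fit_log_model(data.frame(genotype = "a", modulus_Pa = 1),
                             "genotype"), "2 groups")
  rec <- data.frame(genotype = c("a", "a", "b"),
                    modulus_Pa = c(1e6, 2e6, 3e6))
  expect_error(fit_log_model(rec, "genotype"), "n >= 2")
  rec2 <- data.frame(genotype = rep(c("a", "b"), each = 3),
                     modulus_Pa = c(1, 2, 3, -1, 2, 3))
  expect_error(fit_log_model(rec2, "genotype"), "positive")
})

test_that("Tukey at two groups equals the pooled t-test", {
  set.seed(22)
  rec <- data.frame(genotype = rep(c("WT", "OIM"), c(10, 8)),
                    modulus_Pa = rlnorm(18, 15, 0.4))
  cmp <- tukey_pairwise(fit_log_model(rec, "genotype"))
  tt <- t.test(log(modulus_Pa) ~ genotype, data = rec, var.equal = TRUE)
  expect_equal(cmp$p_tukey, tt$p.value, tolerance = 1e-6)
  expect_equal(abs(cmp$t), abs(unname(tt$statistic)), tolerance = 1e-9)
})

test_that("identical groups give p near 1 and unit ratio", {
  rec <- data.frame(genotype = rep(c("a", "b"), each = 5),
                    modulus_Pa = rep(c(1e6, 2e6, 3e6, 2e6, 1.5e6), 2))
  cmp <- tukey_pairwise(fit_log_model(rec, "genotype"))
  expect_equal(cmp$ratio, 1, tolerance = 1e-12)
  expect_gt(cmp$p_tukey, 0.99)
  expect_false(cmp$significant)
})

test_that("Tukey adjustment never reports below the unadjusted p at k > 2", {
  set.seed(23)
  rec <- data.frame(genotype = rep(c("a", "b", "c"), each = 6),
                    modulus_Pa = rlnorm(18, 15, 0.5))
  fit <- fit_log_model(rec, "genotype")
  cmp <- tukey_pairwise(fit)
  p_unadj <- 2 * pt(abs(cmp$t), cmp$df, lower.tail = FALSE)
  expect_true(all(cmp$p_tukey >= p_unadj - 1e-12))
})

test_that("fold ratios reproduce the printed prose folds", {
  f <- fold_ratio(14.2, 2.8)
  expect_equal(f$ratio, 5.07, tolerance = 0.001)
  expect_equal(f$fold, 5)
  f9 <- fold_ratio(10.8, 1.2)
  expect_equal(f9$ratio, 9, tolerance = 1e-12)
  expect_equal(f9$fold, 9)
  expect_equal(fold_ratio(3, 3)$ratio, 1)
  # orientation-free integer fold
  expect_equal(fold_ratio(2.8, 14.2)$fold, 5)
})

test_that("the printed PBS design is overwhelmingly powered", {
  # groups at the printed means/SDs and n: rejection at alpha = 0.001
  # should be near-certain
  rej <- vapply(1:300, function(s) {
    coh <- generate_cohort(cohort_sim_spec(groups_tbl(
      list("WT", "PBS", 3.3e6, 0.5e6, 10),
      list("OIM", "PBS", 16.2e6, 3.0e6, 8)), seed = 5000 + s))
    tukey_pairwise(fit_log_model(coh, "genotype"))$p_tukey < 0.001
  }, logical(1))
  expect_gt(mean(rej), 0.97)
})
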