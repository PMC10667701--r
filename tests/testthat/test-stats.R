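test_that("significance tiers map p-values to the reporting convention", {
  expect_equal(p_tier(c(0.005, 0.03, 0.07, 0.2)), c("***", "**", "*", "ns"))
  # boundaries are strict
  expect_equal(p_tier(c(0.01, 0.05, 0.1)), c("**", "*", "ns"))
})

test_that("the Shapiro/Bartlett gate routes to Dunnett or Steel", {
  set.seed(102)
  normals <- lapply(1:4, function(i) rnorm(50))
  expect_equal(gate_test_choice(normals)$test, "Dunnett")
  # verify the gate's premise directly: nothing rejected
  expect_true(all(vapply(normals, function(g) shapiro.test(g)$p.value,
                         numeric(1)) > 0.05))
  skewed <- c(normals[1:3], list(rlnorm(50, 0, 1.5)))
  expect_true(shapiro.test(skewed[[4]])$p.value < 0.05)
  expect_equal(gate_test_choice(skewed)$test, "Steel")
  # unequal variances alone also push to Steel
  het <- list(rnorm(60, 0, 1), rnorm(60, 0, 1), rnorm(60, 0, 6))
  expect_true(bartlett.test(het, rep(1:3, each = 60))$p.value < 0.05 ||
                gate_test_choice(het)$test == "Steel")
  expect_error(gate_test_choice(list(c(1, 2), rnorm(5))), "at least 3")
})

test_that("Dunnett contrasts detect a large shift and ignore identical data", {
  same <- list(ref = rep(3, 10), a = rep(3, 10), b = rep(3, 10))
  res0 <- dunnett_many_to_one(same)
  expect_true(all(res0$p > 0.99))
  set.seed(11)
  g <- list(ref = rnorm(30), a = rnorm(30), b = rnorm(30, 3))
  res <- dunnett_many_to_one(g)
  expect_equal(res$tier[res$contrast == "b vs ref"], "***")
  expect_equal(res$tier[res$contrast == "a vs ref"], "ns")
  expect_error(dunnett_many_to_one(list(ref = numeric(0), a = rnorm(5))),
               "reference")
})

test_that("a single Steel comparison reduces to the rank-sum test", {
  set.seed(13)
  a <- rnorm(20); b <- rnorm(20, 0.8)
  ps <- steel_many_to_one(list(a, b), 1)$p
  pw <- wilcox.test(b, a, exact = FALSE, correct = FALSE)$p.value
  expect_lt(abs(ps - pw) / pw, 0.1)
  # one-sided variant agrees too
  ps1 <- steel_many_to_one(list(a, b), 1, alternative = "greater")$p
  pw1 <- wilcox.test(b, a, alternative = "greater", exact = FALSE,
                     correct = FALSE)$p.value
  expect_lt(abs(ps1 - pw1) / pw1, 0.1)
})

test_that("Steel detects a stochastically larger group with good power", {
  set.seed(17)
  hits <- mean(vapply(1:100, function(i) {
    ref <- rnorm(20)
    shift <- 1.5 * IQR(ref)
    g <- list(ref = ref, a = rnorm(20), b = rnorm(20) + shift)
    res <- steel_many_to_one(g, 1, alternative = "greater")
    res$p[res$contrast == "b vs ref"] < 0.05
  }, logical(1)))
  expect_gte(hits, 0.8)
})

test_that("Steel adjusted p-values are never smaller than unadjusted ones", {
  set.seed(19)
  for (i in 1:20) {
    g <- list(rnorm(12), rnorm(12, 0.5), rnorm(12, 1), rnorm(12, -0.5))
    adj <- steel_many_to_one(g, 1)$p
    unadj <- vapply(2:4, function(j) {
      wilcox.test(g[[j]], g[[1]], exact = FALSE, correct = FALSE)$p.value
    }, numeric(1))
    expect_true(all(adj >= unadj - 1e-10))
  }
})

test_that("the small-sample Steel fallback is Bonferroni-conservative", {
  set.seed(23)
  g <- list(ref = rnorm(4), a = rnorm(4), b = rnorm(4))
  res <- steel_many_to_one(g, 1)   # auto: groups of 4 use the fallback
  raw <- vapply(c("a", "b"), function(nm) {
    wilcox.test(g[[nm]], g$ref)$p.value
  }, numeric(1))
  expect_equal(res$p, unname(pmin(1, raw * 2)))
})

test_that("Mann-Whitney p-values match exact rank enumeration", {
  # all 3 ranks of b above a: one-sided p = 1 / C(6,3) = 0.05
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  expect_equal(mann_whitney_two_group(a, b, "less")$p, 0.05)
  # the reversed alternative has no support at all: p = 1
  expect_equal(mann_whitney_two_group(a, b, "greater")$p, 1)
  # identical singletons carry no evidence
  expect_equal(mann_whitney_two_group(1, 1)$p, 1)
  expect_error(mann_whitney_two_group(numeric(0), 1), "nonempty")
})

test_that("study contrasts run the gated day-wise scheme end to end", {
  tab <- make_study_table(study_table_spec(
    n_per_cell = 15,
    day_effects = list(quinine = list(area = c(0, 2.5, 5, 7.5))),
    dispersion = list(area = 5, speed = 0.03, omega = 0.008), seed = 31))
  res <- run_study_contrasts(tab, "area")
  expect_setequal(unique(res$condition), c("control", "quinine"))
  expect_equal(nrow(res), 6)   # 3 day contrasts per condition
  q4 <- res[res$condition == "quinine" & res$contrast == "Day 4 vs Day 1", ]
  expect_equal(q4$tier, "***")   # 1.5-SD drift by Day 4 at n = 15
  # missing reference day errors out
  expect_error(run_study_contrasts(tab[tab$day != 1, ], "area"),
               "reference day")
  expect_error(run_study_contrasts(tab, "no_such_index"), "not found")
})

test_that("the Day-5 scheme compares manipulations against intact", {
  set.seed(37)
  conds <- c("day5_intact", "day5_cutoff", "day5_horizontal", "day5_reverse")
  tab <- do.call(rbind, lapply(conds, function(cn) {
    shift <- if (cn == "day5_intact") 0 else -10
    data.frame(condition = cn, day = 5, area = rnorm(12, 30 + shift, 4))
  }))
  res <- run_study_contrasts(tab, "area", scheme = "day5")
  expect_equal(nrow(res), 3)
  expect_true(all(grepl("vs day5_intact", res$contrast)))
  expect_true(all(res$p < 0.01))
  expect_error(run_study_contrasts(tab[tab$condition != "day5_intact", ],
                                   "area", scheme = "day5"),
               "reference condition")
})

test_that("rank correlation wrapper returns Spearman's rho", {
  set.seed(41)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)
  rc <- rank_correlation(x, y)
  expect_equal(rc$rho, cor(x, y, method = "spearman"))
  expect_lt(rc$p, 0.01)
})
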