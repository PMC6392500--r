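test_that("Wilson intervals match the hand formula; boundaries behave", {
  ci <- binomial_ci(8, 10)
  expect_equal(c(ci$ci_low, ci$ci_high), wilson_oracle(8, 10),
               tolerance = 1e-12)
  expect_equal(round(ci$ci_low, 3), 0.490)
  expect_equal(round(ci$ci_high, 3), 0.943)
  expect_identical(ci$method, "wilson")

  all_s <- binomial_ci(10, 10)
  expect_equal(all_s$proportion, 1)
  expect_equal(all_s$ci_high, 1)
  none <- binomial_ci(0, 50)
  expect_equal(none$proportion, 0)
  expect_equal(none$ci_low, 0)
  expect_error(binomial_ci(1, 0), "n")
  expect_error(binomial_ci(5, 3), "k <= n")
})

test_that("Clopper-Pearson option reproduces binom.test exactly", {
  for (kn in list(c(8, 10), c(0, 12), c(12, 12), c(30, 100))) {
    ci <- binomial_ci(kn[1], kn[2], method = "clopper-pearson")
    ref <- binom.test(kn[1], kn[2])$conf.int
    expect_equal(c(ci$ci_low, ci$ci_high), as.numeric(ref),
                 tolerance = 1e-9)
  }
})

test_that("habituation curves use tracked worms only and flag gaps", {
  ev <- data.frame(
    worm_id = rep(sprintf("w%d", 1:4), 3),
    strain = "N2", plate_id = "p1", day = 1,
    tap_index = rep(1:3, each = 4),
    tracked = c(TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE, FALSE, FALSE,
                FALSE, FALSE, FALSE, FALSE),
    reversed = c(TRUE, TRUE, FALSE, TRUE,
                 TRUE, FALSE, NA, NA,
                 NA, NA, NA, NA))
  expect_warning(hc <- habituation_curve(ev), "gaps")
  expect_equal(hc$denominator, c(4L, 2L, 0L))
  expect_equal(hc$numerator[1:2], c(3L, 1L))
  expect_equal(hc$proportion[1:2], c(0.75, 0.5))
  expect_true(is.na(hc$proportion[3]))
})

test_that("a generated curve stays within 4 binomial SEs of truth at every tap", {
  m <- hab_model(0.9, 0.3, 0.2, dropout = 0.05)
  ex <- gen_tap_experiment(list(N2 = m), 5000, seed = 13)
  hc <- habituation_curve(ex)
  p_t <- tap_probabilities(m, 30)
  se <- sqrt(p_t * (1 - p_t) / hc$denominator)
  expect_true(all(abs(hc$proportion - p_t) < 4 * se))
  expect_true(all(hc$ci_low <= hc$proportion & hc$proportion <= hc$ci_high))
})

test_that("the day QC gate is inclusive at exactly 80%", {
  mk <- function(k, n, day = 1) data.frame(
    worm_id = sprintf("d%d_w%d", day, 1:n), strain = "N2", plate_id = "p1",
    day = day, tap_index = 1L, tracked = TRUE,
    reversed = c(rep(TRUE, k), rep(FALSE, n - k)))
  ev <- rbind(mk(79, 100, 1), mk(80, 100, 2), mk(100, 100, 3))
  qc <- qc_day(ev, "N2")
  expect_equal(qc$pass, c(FALSE, TRUE, TRUE))
  expect_equal(qc$proportion, c(0.79, 0.80, 1.00))
  expect_error(qc_day(ev, "CB1112"), "reference strain absent")
})

test_that("strongly different strains give a significant, correctly signed contrast", {
  out <- c(rep(TRUE, 50), rep(FALSE, 50), rep(TRUE, 10), rep(FALSE, 90))
  st <- rep(c("N2", "mut"), each = 100)
  cmp <- compare_strains(out, st, endpoint = "reversal-at-tap-30")
  expect_lt(cmp$contrasts$p_adj, 0.001)
  # direction: N2 (50%) has higher log-odds than mut (10%)
  lab <- cmp$contrasts$contrast
  expect_true((grepl("^N2", lab) && cmp$contrasts$estimate > 0) ||
                (grepl("^mut", lab) && cmp$contrasts$estimate < 0))
  # independent oracle: the exact 2x2 test agrees on significance
  expect_lt(fisher.test(matrix(c(50, 50, 10, 90), 2, byrow = TRUE))$p.value,
            0.001)
})

test_that("adjusted p-values never fall below raw ones", {
  set.seed(17)
  for (i in 1:20) {
    S <- sample(2:5, 1)
    n <- sample(20:60, 1)
    st <- rep(sprintf("s%d", 1:S), each = n)
    out <- rbinom(S * n, 1, runif(S, 0.2, 0.8)[rep(1:S, each = n)])
    cmp <- compare_strains(out, st)
    expect_true(all(cmp$contrasts$p_adj >= cmp$contrasts$p_raw - 1e-12))
    expect_equal(nrow(cmp$contrasts), S * (S - 1) / 2)
  }
})

test_that("single-step adjustment matches multcomp's Tukey contrasts", {
  skip_if_not_installed("multcomp")
  set.seed(23)
  st <- factor(rep(c("a", "b", "c", "d"), each = 80))
  out <- rbinom(320, 1, c(0.3, 0.45, 0.5, 0.7)[as.integer(st)])
  cmp <- compare_strains(out, st)
  fit <- glm(out ~ st, family = binomial())
  gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(st = "Tukey")))
  expect_equal(unname(cmp$contrasts$estimate),
               unname(as.numeric(gl$test$coefficients)), tolerance = 1e-6)
  expect_equal(unname(cmp$contrasts$p_adj),
               unname(as.numeric(gl$test$pvalues)), tolerance = 0.002)
})

test_that("complete separation switches to the flagged penalized fit", {
  out <- c(rep(TRUE, 40), rep(FALSE, 0), rep(FALSE, 40))
  st <- rep(c("all", "none"), each = 40)
  cmp <- compare_strains(out, st)
  expect_true(cmp$separated)
  expect_true(all(is.finite(cmp$contrasts$se)))
  expect_lt(cmp$contrasts$p_adj, 0.001)
})

test_that("compare_habituated_level works at the endpoint tap and guards sizes", {
  ms <- list(N2 = hab_model(0.9, 0.45, 0.2), mut = hab_model(0.9, 0.45, 0.2))
  ex <- gen_tap_experiment(ms, 80, seed = 19)
  cmp <- compare_habituated_level(ex)
  expect_s3_class(cmp, "strain_comparison")
  expect_identical(cmp$endpoint, "reversal-at-tap-30")
  sub <- ex$events[ex$events$tap_index == 30 & ex$events$tracked, ]
  expect_equal(sum(cmp$counts$n), nrow(sub))
  expect_error(compare_habituated_level(ex, endpoint_tap = 99),
               "endpoint tap")
  one <- ex$events[ex$events$strain == "N2", ]
  expect_error(compare_habituated_level(one), "2 strains")
})

test_that("proportion endpoints wrap CIs and the strain comparison", {
  out <- c(rep(TRUE, 96), rep(FALSE, 64), rep(TRUE, 60), rep(FALSE, 100))
  st <- rep(c("N2", "dat-1"), c(160, 160))
  pe <- proportion_endpoint(out, st, endpoint = "swimming-at-10-min")
  expect_equal(pe$per_strain$n, c(160L, 160L))
  expect_equal(sort(pe$per_strain$proportion), c(0.375, 0.6))
  expect_s3_class(pe$comparison, "strain_comparison")
  w <- binomial_ci(96, 160)
  row <- pe$per_strain[pe$per_strain$strain == "N2", ]
  expect_equal(row$ci_low, w$ci_low)
  expect_equal(row$ci_high, w$ci_high)
})

test_that("estimated SWIP proportions cover the truth at the nominal rate", {
  covered <- sapply(1:40, function(s) {
    set.seed(1000 + s)
    k <- rbinom(1, 160, 0.6)
    ci <- binomial_ci(k, 160)
    ci$ci_low <= 0.6 && 0.6 <= ci$ci_high
  })
  expect_gte(mean(covered), 0.90)
})

test_that("slowing index is 1 - on/off ratio with seeded bootstrap intervals", {
  set.seed(7)
  bends <- data.frame(
    strain = rep(c("N2", "cat-2"), each = 40),
    condition = rep(rep(c("off_food", "on_food"), each = 20), 2),
    bends = c(rpois(20, 20), rpois(20, 10), rpois(20, 20), rpois(20, 20)))
  s1 <- basal_slowing_summary(bends, n_boot = 500, seed = 4)
  s2 <- basal_slowing_summary(bends, n_boot = 500, seed = 4)
  expect_identical(s1, s2)
  n2 <- s1$per_strain[s1$per_strain$strain == "N2", ]
  expect_lt(abs(n2$slowing_index - 0.5), 0.15)
  expect_true(n2$ci_low <= n2$slowing_index &&
                n2$slowing_index <= n2$ci_high)
  expect_equal(nrow(s1$pairwise), 1L)

  same <- bends
  same$bends[same$strain == "N2" & same$condition == "on_food"] <-
    same$bends[same$strain == "N2" & same$condition == "off_food"]
  s3 <- basal_slowing_summary(same, n_boot = 200, seed = 1)
  expect_equal(s3$per_strain$slowing_index[s3$per_strain$strain == "N2"], 0)

  bad <- bends[bends$condition == "on_food", ]
  expect_error(basal_slowing_summary(bad), "lacks one condition")
})

test_that("random strain relabeling destroys a real difference at the nominal rate", {
  ms <- list(a = hab_model(0.9, 0.25, 0.3), b = hab_model(0.9, 0.55, 0.3))
  ex <- gen_tap_experiment(ms, 150, seed = 29)
  expect_lt(compare_habituated_level(ex)$contrasts$p_adj, 0.01)
  sub <- ex$events[ex$events$tap_index == 30 & ex$events$tracked, ]
  set.seed(31)
  hits <- sapply(1:60, function(i) {
    compare_strains(sub$reversed, sample(sub$strain))$contrasts$p_adj < 0.05
  })
  expect_lt(mean(hits), 0.15)
})
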