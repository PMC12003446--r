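# Tier filters, RPM normalization, differential abundance and summaries.

test_that("tier filters reproduce the rule definitions on fixed cases", {
  m <- rbind(a = c(5, 0, 0, 0),    # deep in one sample only
             b = c(1, 1, 1, 1),    # shallow but ubiquitous; sum 4 < 5
             c = c(0, 0, 0, 0),    # absent
             d = c(2, 3, 0, 1))    # present in 3 of 4, sum 6
  tiers <- apply_tier_filters(m)
  expect_equal(tiers$tier1, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(tiers$tier2, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(tiers$tier3, c(FALSE, TRUE, FALSE, TRUE))

  # single-sample matrix with count 2: tier1 and tier3 (present in all)
  t1 <- apply_tier_filters(matrix(2, 1, 1))
  expect_true(t1$tier1 && t1$tier3)
  expect_false(t1$tier2)

  # empty matrix -> empty assignment
  expect_equal(nrow(apply_tier_filters(matrix(0, 0, 3))), 0)

  # per-sample tier-2 variant: >= 5 reads in >= 2 samples
  m2 <- rbind(x = c(5, 5, 0), y = c(5, 4, 4))
  t2 <- apply_tier_filters(m2, tier2_rule = "per_sample")
  expect_equal(t2$tier2, c(TRUE, FALSE))
})

test_that("tier filters agree with the brute-force evaluator on random matrices", {
  set.seed(404)
  for (rep in 1:200) {
    ns <- sample(1:10, 1)
    nc <- sample(1:50, 1)
    m <- matrix(rpois(ns * nc, lambda = sample(c(0.3, 1, 3), 1)), nc, ns)
    got <- apply_tier_filters(m)
    for (i in seq_len(nc)) {
      want <- brute_tiers(m[i, ], ns)
      expect_equal(got$tier1[i], want$tier1)
      expect_equal(got$tier2[i], want$tier2)
      expect_equal(got$tier3[i], want$tier3)
    }
  }
})

test_that("RPM normalization is exact and invertible", {
  m <- matrix(c(0, 10, 7, 123), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  mr <- c(s1 = 2e6, s2 = 5e6)
  rpm <- rpm_normalize(m, mr)
  expect_equal(rpm["a", "s2"], 7 * 1e6 / 5e6)
  expect_equal(rpm["b", "s1"], 5.0)
  expect_equal(rpm["a", "s1"], 0.0)
  # inverse identity
  back <- sweep(rpm, 2, mr, function(x, s) x * s / 1e6)
  expect_true(all(abs(back - m) < 1e-9))
  expect_error(rpm_normalize(m, c(s1 = 0, s2 = 1e6)))
})

test_that("differential abundance matches the closed-form Welch oracle", {
  x <- c(3.1, 2.8, 3.5, 3.0)
  y <- c(1.0, 1.3, 0.9, 1.1)
  rpm <- rbind(k1 = c(x, y))
  sheet <- tibble::tibble(sample_id = paste0("s", 1:8),
                          group = rep(c("case", "control"), each = 4),
                          mappable_reads = 1e6)
  colnames(rpm) <- sheet$sample_id
  d <- differential_abundance(rpm, sheet)
  expect_equal(d$p_value, welch_p(x, y), tolerance = 1e-12)
  expect_equal(d$mean_rpm_case, mean(x))
  expect_equal(d$log2fc, log2((mean(x) + 0.01) / (mean(y) + 0.01)))
  expect_equal(d$direction, "up")

  # pooled-variance variant against its own closed form
  dp <- differential_abundance(rpm, sheet, var_equal = TRUE)
  expect_equal(dp$p_value, pooled_t_p(x, y), tolerance = 1e-12)

  # identical groups: log2fc 0, direction none, p = 1 (zero-variance guard)
  rpm2 <- rbind(k1 = rep(2.5, 8)); colnames(rpm2) <- sheet$sample_id
  d2 <- differential_abundance(rpm2, sheet)
  expect_equal(d2$log2fc, 0)
  expect_equal(d2$p_value, 1)
  expect_equal(d2$direction, "none")

  # constant unequal groups: 4 vs 1 with eps 0 -> log2fc exactly 2
  rpm3 <- rbind(k1 = rep(c(4, 1), each = 4)); colnames(rpm3) <- sheet$sample_id
  d3 <- differential_abundance(rpm3, sheet, epsilon = 0)
  expect_equal(d3$log2fc, 2)

  # a group with < 2 samples errors, naming the group
  bad_sheet <- sheet[c(1, 5:8), ]
  expect_error(differential_abundance(rpm[, bad_sheet$sample_id,
                                          drop = FALSE], bad_sheet), "case")
})

test_that("direction summaries and chi-squared match hand computation", {
  mk <- function(up, down) tibble::tibble(
    direction = c(rep("up", up), rep("down", down), rep("none", 3)))
  s <- direction_summary(mk(18, 6))
  expect_equal(s$n_up, 18)
  expect_equal(s$pct_up, 75.0)

  # two-collection Pearson chi-squared, no continuity correction
  s2 <- direction_summary(mk(18, 6), mk(10, 10))
  expect_equal(s2$chisq,
               pearson_chisq_2x2(rbind(c(18, 6), c(10, 10))),
               tolerance = 1e-12)
  expect_equal(s2$chisq, 2.947, tolerance = 1e-3)

  # identical proportions -> chi-squared 0, p 1
  s3 <- direction_summary(mk(12, 4), mk(6, 2))
  expect_equal(s3$chisq, 0, tolerance = 1e-12)
  expect_equal(s3$p_value, 1)

  # nothing significant -> pct missing, no test
  s4 <- direction_summary(mk(0, 0))
  expect_true(is.na(s4$pct_up))
  expect_null(s4$chisq)
})

test_that("circ-linear correlation equals the definition-formula R^2", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  r <- circ_linear_correlation(x, y)
  expect_equal(r$r_squared, def_r2(x, y), tolerance = 1e-12)
  expect_equal(circ_linear_correlation(x, 2 * x)$r_squared, 1)
  expect_true(is.na(circ_linear_correlation(x, rep(1, 4))$r_squared))
  expect_error(circ_linear_correlation(x, y[1:3]))
})

test_that("RPM, log2FC and p are invariant under joint count/library scaling", {
  set.seed(77)
  counts <- matrix(rpois(80, 20), 10, 8)
  rownames(counts) <- paste0("k", 1:10)
  sheet <- tibble::tibble(sample_id = paste0("s", 1:8),
                          group = rep(c("case", "control"), each = 4),
                          mappable_reads = round(runif(8, 1e6, 2e6)))
  colnames(counts) <- sheet$sample_id
  mr <- setNames(sheet$mappable_reads, sheet$sample_id)
  d1 <- differential_abundance(rpm_normalize(counts, mr), sheet)
  sheet2 <- sheet; sheet2$mappable_reads <- sheet$mappable_reads * 7
  d2 <- differential_abundance(rpm_normalize(counts * 7,
                                             mr * 7), sheet2)
  expect_equal(d1$log2fc, d2$log2fc, tolerance = 1e-9)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-9)
  expect_equal(rpm_normalize(counts, mr), rpm_normalize(counts * 7, mr * 7),
               tolerance = 1e-9)
})
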