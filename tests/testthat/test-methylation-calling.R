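# Conversion counting, rate estimation, site calling, dependency and
# pairwise comparisons.

test_that("count_conversions applies the C/T counting rules per read base", {
  fx <- pileup_fixture(c(rep("T", 10)))
  cc <- count_conversions(fx$sam, fx$ref)
  row <- cc[cc$pos0 == fx$pos0, ]
  expect_equal(c(row$coverage, row$unconverted), c(10L, 0L))

  fx2 <- pileup_fixture(c(rep("C", 10), rep("T", 10)))
  cc2 <- count_conversions(fx2$sam, fx2$ref)
  row2 <- cc2[cc2$pos0 == fx2$pos0, ]
  expect_equal(c(row2$coverage, row2$unconverted), c(20L, 10L))
  expect_equal(row2$level, 0.5)

  # G at a C position is excluded from both counts
  fx3 <- pileup_fixture(c(rep("C", 5), rep("T", 5), rep("G", 3)))
  cc3 <- count_conversions(fx3$sam, fx3$ref)
  row3 <- cc3[cc3$pos0 == fx3$pos0, ]
  expect_equal(c(row3$coverage, row3$unconverted), c(10L, 5L))
})

test_that("alignment targets missing from the reference raise a named error", {
  fx <- pileup_fixture(rep("T", 3))
  wrong <- c(OTHER = fx$ref[["TX"]])
  expect_error(count_conversions(fx$sam, wrong), "TX")
})

test_that("conversion-rate estimation is trimmed and accurate", {
  all_t <- pileup_fixture(rep("T", 30))
  cc <- count_conversions(all_t$sam, all_t$ref)
  expect_equal(estimate_conversion_rate(cc), 1)
  expect_error(estimate_conversion_rate(cc[0, ]), "coverage")

  # recovery on synthetic data with methylated sites present
  tg <- small_world()
  sim <- simulate_bs_reads(tg$sequences, tg$truth, depth = 60, seed = 41,
                           conversion = 0.995)
  ccs <- count_conversions(sim$sam, tg$sequences)
  expect_lt(abs(estimate_conversion_rate(ccs) - 0.995), 0.002)
})

test_that("call_sites applies coverage, level, count and BH-binomial filters", {
  counts <- data.frame(
    ref = "TX", pos0 = 1:4 * 10L, strand = "+",
    coverage = c(20L, 19L, 100L, 20L),
    unconverted = c(2L, 10L, 0L, 4L))
  counts$level <- counts$unconverted / counts$coverage
  cs <- call_sites(counts, conversion_rate = 0.995, min_unconverted = 2L)
  # coverage 19 fails the filter even at level 0.53; zero unconverted never calls
  expect_false(20L %in% cs$calls$pos0)
  expect_false(30L %in% cs$calls$pos0)
  expect_true(40L %in% cs$calls$pos0)
  # exact binomial tail: coverage 20, unconverted 2, c = 0.995
  p_row <- cs$tested$p[cs$tested$pos0 == 10L]
  expect_equal(p_row, bf_binom_tail(2, 20, 0.005), tolerance = 1e-12)
  expect_lt(abs(p_row - 4.6e-3), 2e-4)
})

test_that("binomial p-values match the exact tail-sum oracle", {
  set.seed(99)
  n <- sample(5:50, 30, TRUE)
  k <- vapply(n, function(x) sample.int(x, 1), integer(1))
  counts <- data.frame(ref = "TX", pos0 = seq_along(n), strand = "+",
                       coverage = n, unconverted = k, level = k / n)
  cs <- call_sites(counts, 0.99, min_cov = 1L)
  oracle <- mapply(bf_binom_tail, k, n, MoreArgs = list(p = 0.01))
  expect_equal(cs$tested$p[order(cs$tested$pos0)], unname(oracle),
               tolerance = 1e-12)
})

test_that("calling is monotone in unconverted count at fixed coverage", {
  base <- data.frame(ref = "TX", pos0 = 0L, strand = "+", coverage = 50L,
                     unconverted = 0L, level = 0)
  called <- vapply(0:50, function(u) {
    base$unconverted <- u; base$level <- u / 50
    nrow(call_sites(base, 0.995)$calls) == 1L
  }, logical(1))
  # once called, raising the unconverted count never un-calls
  first <- which(called)[1]
  expect_true(all(called[first:length(called)]))
})

test_that("dependency classification follows the knockout/rescue thresholds", {
  mk <- function(levels, cov = 100L, id = "s") {
    tested <- data.frame(ref = "TX", pos0 = seq_along(levels) * 10L,
                         strand = "+", coverage = cov,
                         unconverted = round(levels * cov))
    tested$level <- tested$unconverted / tested$coverage
    tested$p <- 0; tested$q <- 0
    structure(list(sample = id, conversion_rate = 0.995,
                   calls = tested[tested$level >= 0.1, ], tested = tested),
              class = "SampleCallSet")
  }
  wt <- mk(c(0.4, 0.4, 0.4))
  ko <- mk(c(0.01, 0.2, 0.01))
  ko$tested$coverage[3] <- 5L                       # site 3 undercovered in KO
  dep <- classify_dependency(wt, ko)
  expect_equal(dep$status, c("dependent", "independent", "unresolved"))
  rescue <- mk(c(0.2, 0.2, 0.2))
  dep2 <- classify_dependency(wt, ko, rescue)
  expect_equal(dep2$status[1], "rescued")
})

test_that("pairwise comparison keeps sites by joint coverage and either-level", {
  mk <- function(levels, cov) {
    tested <- data.frame(ref = "TX", pos0 = seq_along(levels) * 10L,
                         strand = "+", coverage = cov,
                         unconverted = round(levels * cov))
    tested$level <- tested$unconverted / tested$coverage
    tested$p <- tested$q <- 0
    structure(list(sample = "x", conversion_rate = 1,
                   calls = tested[0, ], tested = tested),
              class = "SampleCallSet")
  }
  a <- mk(c(0.3, 0.05, 0.3), cov = c(100L, 100L, 100L))
  b <- mk(c(0.05, 0.05, 0.3), cov = c(100L, 100L, 10L))
  pw <- compare_pairwise(a, b)
  expect_equal(pw$pos0, 10L)        # 0.3/0.05 in; 0.05/0.05 out; low-cov out
  expect_equal(pw$level_a, 0.3)
  expect_equal(pw$level_b, 0.05)
})

test_that("site-level recovery on synthetic data meets the accuracy envelope", {
  tg <- small_world()
  sim <- simulate_bs_reads(tg$sequences, tg$truth, depth = 50, seed = 43)
  cc <- count_conversions(sim$sam, tg$sequences)
  cs <- call_sites(cc, estimate_conversion_rate(cc))
  m <- match(site_key(cs$calls), site_key(tg$truth$sites))
  expect_gt(mean(!is.na(m)), 0.95)                     # precision
  mae <- mean(abs(cs$calls$level[!is.na(m)] -
                    tg$truth$sites$level[m[!is.na(m)]]))
  expect_lt(mae, 0.06)
})
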