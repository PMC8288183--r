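# Generators: planted ground truth, determinism, emitted-format validity.

test_that("planted Type II sites carry UCCA and sit in foldable hairpin loops", {
  tg <- make_transcriptome(n_transcripts = 10, sites_per_type = 5, seed = 1,
                           hairpin_spec = list(loop = c(7, 7), stem = c(11, 11)))
  s2 <- tg$truth$sites[tg$truth$sites$type == "TypeII", ]
  expect_equal(nrow(s2), 5)
  ctx <- extract_context(s2, tg$sequences, k = 10)
  expect_true(all(substr(ctx, 12, 15) == "UCCA"))
  # folding the planted window recovers at least stem - 2 pairs around the loop
  gm <- stem_loop_table(s2, tg$sequences)
  expect_true(all(gm$stem_len >= 11 - 2))
  expect_true(all(gm$site_in_loop))
  expect_true(all(gm$loop_len == 7))
  # Type I sites carry the downstream G-rich triplet
  s1 <- tg$truth$sites[tg$truth$sites$type == "TypeI", ]
  ctx1 <- extract_context(s1, tg$sequences, k = 10)
  expect_true(all(grepl("GGG", substr(ctx1, 13, 17), fixed = TRUE)))
  # truth invariants
  expect_true(all(tg$truth$sites$level >= 0 & tg$truth$sites$level <= 1))
  expect_true(tg$truth$conversion > 0.9 && tg$truth$conversion <= 1)
})

test_that("generation is seed-deterministic down to the emitted bytes", {
  d1 <- tempfile(); d2 <- tempfile()
  make_transcriptome(n_transcripts = 3, sites_per_type = 4, seed = 9, outdir = d1)
  make_transcriptome(n_transcripts = 3, sites_per_type = 4, seed = 9, outdir = d2)
  for (f in c("transcriptome.fa", "annotation.gtf", "truth_sites.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  t1 <- make_transcriptome(n_transcripts = 3, sites_per_type = 4, seed = 10)
  expect_false(identical(readLines(file.path(d1, "transcriptome.fa")),
                         as.character(Biostrings::DNAStringSet(t1$sequences))))
})

test_that("truth tables round-trip through disk", {
  d <- tempfile()
  tg <- make_transcriptome(n_transcripts = 3, sites_per_type = 4, seed = 2,
                           outdir = d)
  tr <- read_truth_table(d)
  expect_equal(tr$sites, tg$truth$sites)
  expect_equal(tr$background, tg$truth$background)
  expect_identical(tr$conversion, tg$truth$conversion)
})

test_that("invalid hairpin specs and conversion rates are rejected", {
  expect_error(make_transcriptome(2, 2, hairpin_spec = list(loop = c(3, 3),
                                                            stem = c(11, 11))),
               "loop")
  expect_error(make_transcriptome(2, 2, hairpin_spec = list(loop = c(7, 7),
                                                            stem = c(2, 2))),
               "stem")
  expect_error(make_transcriptome(2, 2, seed = 1, conversion = 0.8), "conversion")
  expect_error(make_transcriptome(2, 2, seed = 1,
                                  hairpin_spec = list(loop = c(40, 40),
                                                      stem = c(30, 30)),
                                  transcript_length = 80),
               "cannot embed")
})

test_that("simulated bisulfite reads follow the conversion model and emit valid SAM", {
  tg <- small_world()
  # deep coverage at one site, perfect conversion
  truth1 <- tg$truth
  truth1$sites$level[] <- 0.5
  sim <- simulate_bs_reads(tg$sequences, truth1, depth = 120, seed = 3,
                           conversion = 1)
  cc <- count_conversions(sim$sam, tg$sequences)
  at <- cc[match(site_key(truth1$sites), site_key(cc)), ]
  # pooled across sites: binomial error far below 0.015 at this depth
  expect_lt(abs(weighted.mean(at$level, at$coverage) - 0.5), 0.025)
  # zero methylation at perfect conversion leaves no unconverted C anywhere
  truth0 <- tg$truth; truth0$sites$level[] <- 0
  sim0 <- simulate_bs_reads(tg$sequences, truth0, depth = 30, seed = 4,
                            conversion = 1)
  cc0 <- count_conversions(sim0$sam, tg$sequences)
  expect_equal(sum(cc0$unconverted), 0)
  # non-conversion floor visible at c = 0.99
  sim99 <- simulate_bs_reads(tg$sequences, truth0, depth = 60, seed = 5,
                             conversion = 0.99)
  cc99 <- count_conversions(sim99$sam, tg$sequences)
  expect_lt(abs(sum(cc99$unconverted) / sum(cc99$coverage) - 0.01), 0.003)
  # SAM records validate against the emitted reference
  bam <- m5Ctools:::.as_bam(sim$sam)
  a <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth")))[[1]]
  lens <- nchar(tg$sequences)[as.character(a$rname)]
  expect_true(all(a$pos >= 1 & a$pos + a$qwidth - 1 <= lens))
})

test_that("expression simulator plants exactly one writer at the requested strength", {
  se <- simulate_expression(n_enzymes = 125, n_samples = 9, writer_corr = 1,
                            seed = 11)
  expect_equal(nrow(se$expression), 125)
  expect_equal(order(se$expression[se$writer, ]), order(se$type2_counts))
  se9 <- simulate_expression(n_samples = 9, writer_corr = 0.9, seed = 12)
  expect_lt(abs(se9$achieved_spearman - 0.9), 0.02)
  expect_error(simulate_expression(writer_corr = 1.2, seed = 1), "writer_corr")
  expect_error(simulate_expression(n_samples = 2, seed = 1), "3 samples")
})

test_that("reporter read simulator respects depth, rules and barcodes", {
  des <- design_variant_library("GGCGGCGCGACCTCCAGAAGCGCGCCGCC", 11,
                                scheme = "original", seed = 31)
  des <- rbind(des, des); des$variant_id <- c("V1", "V2")
  des$barcode <- c("AGTAGTAGTA", "TGATGATGAT")
  rules <- data.frame(variant_id = c("V1", "V2"), true_level = c(0.8, 0))
  rr <- simulate_reporter_reads(des, rules, depth_per_variant = c(100L, 0L),
                                seed = 32)
  reads <- Biostrings::readDNAStringSet(rr$fastq, format = "fastq")
  expect_equal(length(reads), 100)                       # depth 0 -> absent
  expect_true(all(substr(as.character(reads), 1, 10) == "AGTAGTAGTA"))
  dup <- des; dup$barcode <- rep("AGTAGTAGTA", 2)
  expect_error(simulate_reporter_reads(dup, rules, 10, seed = 1), "barcode")
})

test_that("translation simulator plants the TE shift and monotone fraction trends", {
  td <- simulate_translation_data(genes = 100, planted_te_shift = 0.7, seed = 21)
  expect_equal(length(td$mrna_counts), 200)
  expect_setequal(unique(td$truth$te_multiplier), c(0.7, 1))
  # each polysome site's level follows its planted direction exactly
  for (s in unique(td$polysome$site)[1:10]) {
    sub <- td$polysome[td$polysome$site == s, ]
    rho <- cor(sub$level, sub$fraction, method = "spearman")
    expect_equal(unname(sign(rho)),
                 if (td$truth$fraction_trend[s] == "down") -1 else 1)
  }
  expect_error(simulate_translation_data(genes = 10, planted_te_shift = 0),
               "planted_te_shift")
})
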