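# Reporter library design, demultiplexing and quantification.

reporter_insert <- "AAGGCGGCGCGACCTCCAGAAGCGCGCCGCCTAA"
reporter_site <- 13L     # 0-based target C (followed by TCCA)
reporter_loop <- c(11L, 18L)
reporter_pairs <- data.frame(pos5 = c(10L, 9L, 8L, 7L, 6L),
                             pos3 = c(19L, 20L, 21L, 22L, 23L))

full_design <- function(seed = 7)
  design_variant_library(reporter_insert, reporter_site, scheme = "all",
                         loop = reporter_loop, stem_pairs = reporter_pairs,
                         seed = seed)

test_that("core-motif scheme enumerates all 256 substitutions including the original", {
  des <- design_variant_library(reporter_insert, reporter_site,
                                scheme = "core_motif", seed = 1)
  expect_equal(nrow(des), 256L)
  expect_true("core:UCCA" %in% des$descriptor)
  expect_equal(length(unique(des$sequence)), 256L)
  # every design keeps the target C at its recorded offset
  expect_true(all(substr(des$sequence, des$target_offset + 1,
                         des$target_offset + 1) == "C"))
})

test_that("loop and stem schemes perturb the intended bases", {
  des <- full_design()
  tr <- des[des$category == "loop_trunc", ]
  expect_equal(nchar(tr$sequence), nchar(reporter_insert) - 2L)
  ext <- des[des$category == "loop_ext", ]
  expect_equal(sort(nchar(ext$sequence) - nchar(reporter_insert)),
               c(2L, 4L, 6L, 8L))                     # A_n adds n up + n down
  expect_true(all(substr(ext$sequence, ext$target_offset + 1,
                         ext$target_offset + 1) == "C"))
  sd <- des[des$category == "stem_disrupt", ]
  expect_equal(nrow(sd), 5L)
  # first disruption set replaces the 5' base of pair 1 with A
  v1 <- strsplit(sd$sequence[1], "")[[1]]
  expect_equal(v1[reporter_pairs$pos5[1] + 1L], "A")
})

test_that("barcodes are C-free, unique and Hamming-separated", {
  des <- full_design()
  expect_false(any(grepl("C", des$barcode)))
  expect_equal(anyDuplicated(des$barcode), 0L)
  bc <- do.call(rbind, strsplit(des$barcode[1:40], ""))
  hd <- outer(seq_len(40), seq_len(40), Vectorize(function(i, j)
    sum(bc[i, ] != bc[j, ])))
  diag(hd) <- 99L
  expect_gte(min(hd), 3L)
})

test_that("demultiplexing assigns exactly and partitions reads", {
  des <- full_design()[1:20, ]
  rules <- data.frame(variant_id = des$variant_id,
                      true_level = rep(0.5, nrow(des)))
  rr <- simulate_reporter_reads(des, rules, depth_per_variant = 30, seed = 3)
  dm <- demultiplex(rr$fastq, des)
  expect_equal(dm$n_assigned, 600L)
  expect_equal(dm$n_unassigned, 0L)
  expect_equal(sum(lengths(dm$groups)), dm$n_assigned)
  # one corrupted barcode: unassigned at 0 mismatches, rescued at 1
  reads <- as.character(Biostrings::readDNAStringSet(rr$fastq, format = "fastq"))
  substr(reads[1], 1, 1) <- ifelse(substr(reads[1], 1, 1) == "A", "G", "A")
  dm0 <- demultiplex(reads, des, max_mismatch = 0)
  expect_equal(dm0$n_unassigned, 1L)
  dm1 <- demultiplex(reads, des, max_mismatch = 1)
  expect_equal(dm1$n_unassigned, 0L)
  dup <- des; dup$barcode[2] <- dup$barcode[1]
  expect_error(demultiplex(reads, dup), "ambiguous")
})

test_that("quantification recovers rule levels, suppresses thin variants, flags contamination", {
  des <- full_design()[c(1, 30, 60, 90, 120, 150, 180, 210, 240, 260:285), ]
  rules <- default_reporter_rules(des, original_level = 0.8)
  depths <- rep(200L, nrow(des)); depths[2] <- 19L
  rr <- simulate_reporter_reads(des, rules, depth_per_variant = depths, seed = 5)
  qv <- quantify_variants(demultiplex(rr$fastq, des)$groups, des)
  expect_false(qv$reported[qv$variant_id == des$variant_id[2]])
  expect_true(is.na(qv$level[qv$variant_id == des$variant_id[2]]))
  mrg <- merge(qv[qv$reported, ], rules)
  expected_obs <- mrg$true_level + (1 - mrg$true_level) * 0.005
  tol <- 3 * sqrt(expected_obs * (1 - expected_obs) / mrg$n_reads) + 0.5 / mrg$n_reads
  expect_true(all(abs(mrg$level - expected_obs) <= tol))
  # contamination: reads that are not the designed insert
  groups <- demultiplex(rr$fastq, des)$groups
  v <- des$variant_id[3]
  groups[[v]] <- vapply(groups[[v]], function(r) {
    s <- strsplit(r, "")[[1]]
    s[c(2, 4, 6, 8, 20, 22, 24, 26)] <- "T"        # corrupt non-C positions
    paste(s, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  qv2 <- quantify_variants(groups, des)
  expect_true(qv2$contaminated[qv2$variant_id == v])
})

test_that("position-max profile summarises the core motif by position and base", {
  des <- design_variant_library(reporter_insert, reporter_site,
                                scheme = "core_motif", seed = 9)
  rules <- default_reporter_rules(des, original_level = 0.8)
  rr <- simulate_reporter_reads(des, rules, depth_per_variant = 60, seed = 10)
  qv <- quantify_variants(demultiplex(rr$fastq, des)$groups, des)
  pm <- position_max_profile(qv, des)
  expect_equal(nrow(pm), 16L)
  # the original base at each position attains at least the original's level
  orig_lvl <- qv$level[qv$descriptor == "core:UCCA"]
  for (k in 1:4) {
    b <- substr("UCCA", k, k)
    expect_gte(pm$max_level[pm$position == k & pm$base == b], orig_lvl)
  }
  # +3 purines are abolished to the non-conversion floor
  expect_lt(pm$max_level[pm$position == 3 & pm$base == "A"], 0.1)
  expect_lt(pm$max_level[pm$position == 3 & pm$base == "G"], 0.1)
  expect_gt(pm$max_level[pm$position == 3 & pm$base == "C"], 0.5)
})
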