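test_that("simulators are bit-identical under a fixed seed", {
  g1 <- random_genome(5000, seed = 5)
  g2 <- random_genome(5000, seed = 5)
  expect_identical(g1$sequences, g2$sequences)

  p <- error_profile(snp_rate = 0.02, indel_rate = 0.001, gap_events = 2L)
  expect_identical(mutate_assembly(g1, p, seed = 9)$assembly$sequences,
                   mutate_assembly(g2, p, seed = 9)$assembly$sequences)

  rp <- read_profile(coverage = 5)
  r1 <- simulate_reads(g1, rp, seed = 3)
  r2 <- simulate_reads(g1, rp, seed = 3)
  expect_identical(r1$read1, r2$read1)
  expect_identical(r1$read2, r2$read2)
})

test_that("all-zero profile is the identity and rates are validated", {
  g <- random_genome(3000, seed = 6)
  out <- mutate_assembly(g, error_profile(), seed = 1)
  expect_identical(out$assembly$sequences, g$sequences)
  expect_equal(nrow(out$truth), 0)
  expect_error(error_profile(snp_rate = 1.5), "snp_rate")
})

test_that("SNP-only mutation conserves length and matches the binomial count", {
  g <- random_genome(1e5, seed = 8)
  out <- mutate_assembly(g, error_profile(snp_rate = 0.05), seed = 2)
  expect_equal(out$assembly$total_length, g$total_length)
  n_snp <- sum(out$truth$type == "snp")
  # 3 sigma around Binomial(1e5, 0.05)
  expect_lt(abs(n_snp - 5000), 3 * sqrt(1e5 * 0.05 * 0.95))
  # every recorded SNP position really differs
  a <- strsplit(g$sequences[[1]], "")[[1]]
  b <- strsplit(out$assembly$sequences[[1]], "")[[1]]
  pos <- out$truth$start[out$truth$type == "snp"] + 1L
  expect_true(all(a[pos] != b[pos]))
  expect_true(all(a[-pos] == b[-pos]))
})

test_that("injected SNP truth count pins down the alignment diff count", {
  # match-maximising alignment may pair an occasional substituted base with
  # a nearby identical base through a compensating gap pair, so the diff
  # count is bounded above by the truth count and sits within ~2% of it
  g <- random_genome(2e4, seed = 15)
  out <- mutate_assembly(g, error_profile(snp_rate = 0.03), seed = 4)
  d <- count_differences(out$assembly, g)
  truth <- sum(out$truth$type == "snp")
  expect_lte(d$total_differences, truth)
  expect_gte(d$total_differences, 0.98 * truth)
  # and it still equals the independent alignment oracle exactly
  expect_equal(d$total_differences,
               oracle_differences(g$sequences[[1]],
                                  out$assembly$sequences[[1]]))
})

test_that("gap conversion raises gap_perc and leaves other bases intact", {
  g <- random_genome(5000, seed = 16)
  out <- mutate_assembly(g, error_profile(gap_events = 2L), seed = 5)
  expect_gt(contiguity_metrics(out$assembly)$gap_perc,
            contiguity_metrics(g)$gap_perc)
  a <- strsplit(g$sequences[[1]], "")[[1]]
  b <- strsplit(out$assembly$sequences[[1]], "")[[1]]
  expect_true(all(a[b != "N"] == b[b != "N"]))
})

test_that("fragmentation conserves content and degrades normN50 monotonically", {
  g <- random_genome(10000, seed = 17)
  expect_identical(fragment_assembly(g, 1L)$sequences, g$sequences)
  f10 <- fragment_assembly(g, 10L, seed = 1)
  expect_equal(length(f10$sequences), 10L)
  expect_equal(paste(f10$sequences, collapse = ""), g$sequences[[1]])
  nn50 <- vapply(c(1L, 2L, 5L, 10L, 20L), function(n)
    contiguity_metrics(fragment_assembly(g, n, seed = 1))$normN50, 0)
  expect_true(all(diff(nn50) <= 0))
  expect_error(fragment_assembly(g, 0L), "n_pieces")
})

test_that("read simulation has the right count, exactness and depth", {
  g <- random_genome(1e5, seed = 18)
  rp <- read_profile(coverage = 20, read_length = 150L, base_error_rate = 0)
  rd <- simulate_reads(g, rp, seed = 19)
  expect_equal(length(rd$read1), round(20 * 1e5 / (2 * 150)))  # 6667 pairs

  # with zero error rate every read is an exact (possibly rc) substring
  src <- g$sequences[[1]]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(src)))
  idx <- sample(length(rd$read1), 50)
  expect_true(all(vapply(rd$read1[idx], function(r)
    grepl(r, src, fixed = TRUE), TRUE)))
  expect_true(all(vapply(rd$read2[idx], function(r)
    grepl(r, src, fixed = TRUE) || grepl(r, rc, fixed = TRUE), TRUE)))

  # mapped-back mean depth within 10% of nominal coverage
  pas <- map_reads(g, rd)
  expect_lt(abs(mean(pas$read_depth[[1]]) - 20) / 20, 0.1)

  tiny <- random_genome(100, seed = 1)
  expect_error(simulate_reads(tiny, rp), "insert_mean")
})

test_that("fastq round trip preserves reads", {
  g <- random_genome(3000, seed = 20)
  rd <- simulate_reads(g, read_profile(coverage = 3), seed = 21)
  paths <- write_fastq_pair(rd, tempfile(), compress = TRUE)
  back <- read_fastq_pair(paths[1], paths[2])
  expect_identical(unname(back$read1), unname(rd$read1))
  expect_identical(unname(back$read2), unname(rd$read2))
})

test_that("translocation preserves content and reports four junctions", {
  g <- random_genome(3e4, seed = 22)
  tl <- translocate_assembly(g, seg_len = 1000L, min_separation = 8000L, seed = 23)
  expect_equal(nrow(tl$breakpoints), 4)
  expect_equal(sort(strsplit(tl$assembly$sequences[[1]], "")[[1]]),
               sort(strsplit(g$sequences[[1]], "")[[1]]))
  expect_false(identical(tl$assembly$sequences, g$sequences))
})

test_that("training-set generator produces scored, seeded, coherent tables", {
  ladder <- lapply(c(0, 0.05, 0.15), function(r) error_profile(snp_rate = r))
  t1 <- generate_training_set(n_genomes = 2, gradient = ladder,
                              ref_length = 8000, reads = read_profile(coverage = 12),
                              seed = 3)
  t2 <- generate_training_set(n_genomes = 2, gradient = ladder,
                              ref_length = 8000, reads = read_profile(coverage = 12),
                              seed = 3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 6)
  expect_true(all(METRIC_NAMES %in% colnames(t1)))
  # identity level scores pmb 100; pmb strictly decreasing along the ladder
  for (g in unique(t1$organism)) {
    pmb <- t1$pmb[t1$organism == g]
    expect_equal(pmb[1], 100)
    expect_true(all(diff(pmb) < 0))
  }
  expect_error(generate_training_set(n_genomes = 1), "at least 2")
})
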