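test_that("perfect reads from a gapless sequence all map as proper pairs", {
  pas <- fx_pas()
  expect_equal(pas$mapped_read_count, pas$n_reads)
  expect_gt(pas$proper_pair_count / pas$mapped_read_count, 0.99)
  expect_lt(abs(pas$insert_stats[["mean"]] - 450), 25)
})

test_that("low-identity alignments are discarded", {
  set.seed(31)
  tgt <- assembly_record(c(t = random_seq(2000)))
  r <- substr(tgt$sequences[[1]], 501, 650)
  noisy <- mutate_seq(r, 0.40)
  reads <- list(read1 = c(x = noisy), read2 = c(x = random_seq(150)))
  expect_error(map_reads(tgt, reads, min_identity = 0.75), "no alignments")
})

test_that("reads from an unrelated sequence mostly fail to map", {
  a <- random_genome(10000, seed = 32)
  b <- random_genome(10000, seed = 33)
  rd <- simulate_reads(a, read_profile(coverage = 5, base_error_rate = 0), seed = 34)
  res <- tryCatch(map_reads(b, rd, insert_stats = c(450, 50)),
                  error = function(e) NULL)
  frac <- if (is.null(res)) 0 else res$mapped_read_count / res$n_reads
  expect_lt(frac, 0.02)
})

test_that("fragment depth covers exactly the proper-pair fragment intervals", {
  g <- fx_genome()
  pas <- fx_pas()
  fd <- fragment_depth(pas, g)[[1]]
  p <- pas$pairs[pas$pairs$proper, ]
  expect_equal(sum(as.numeric(fd)),
               sum(pmax(p$end1, p$end2) - pmin(p$start1, p$start2)))
  # single synthetic pair: flat depth 1 on the fragment, 0 outside
  one <- structure(list(pairs = data.frame(
    pair = 1L, tid1 = 1L, start1 = 10, end1 = 60, strand1 = 1L,
    tid2 = 1L, start2 = 70, end2 = 110, strand2 = -1L,
    insert = 100, proper = TRUE)), class = "PairedAlignmentSet")
  asm <- assembly_record(c(s = random_seq(200)))
  d <- fragment_depth(one, asm)[[1]]
  expect_equal(d[11:110], rep(1L, 100))
  expect_equal(sum(d), 100)
  # no proper pairs -> all-zero track
  one$pairs$proper <- FALSE
  expect_equal(sum(fragment_depth(one, asm)[[1]]), 0)
})

test_that("perfect uniform coverage yields error-free interior, no flags", {
  g <- fx_genome()
  pas <- fx_pas()
  tr <- flag_errors(pas, g)
  am <- accuracy_metrics(tr, pas)
  W <- round(pas$insert_stats[["mean"]])
  interior <- (W + 1):(g$total_length - W)
  expect_gt(mean(tr$tracks[[1]]$error_free[interior]), 0.95)
  for (fl in c("clip", "low_fc_in_contig", "low_fc_over_gap",
               "fcd_err_in_contig", "fcd_err_over_gap", "links", "coll_repeat")) {
    expect_lt(100 * mean(tr$tracks[[1]][[fl]]), 1)
  }
  expect_gt(am$prop_pair_perc, 99)
})

test_that("error_free never overlaps an error flag; over_gap/in_contig exclusive", {
  g <- fx_genome()
  tr <- flag_errors(fx_pas(), g)
  t1 <- tr$tracks[[1]]
  any_err <- t1$clip | t1$low_read_cov | t1$low_fc_in_contig |
    t1$low_fc_over_gap | t1$fcd_err_in_contig | t1$fcd_err_over_gap |
    t1$links | t1$coll_repeat
  expect_false(any(t1$error_free & any_err))
  expect_false(any(t1$low_fc_in_contig & t1$low_fc_over_gap))
  expect_false(any(t1$fcd_err_in_contig & t1$fcd_err_over_gap))
})

test_that("accuracy percents are plain base ratios", {
  g <- fx_genome()
  pas <- fx_pas()
  tr <- flag_errors(pas, g)
  am <- accuracy_metrics(tr, pas)
  expect_equal(am$prop_pair_perc, 100 * pas$proper_pair_count / pas$mapped_read_count)
  expect_equal(am$error_free_bases,
               100 * sum(tr$tracks[[1]]$error_free) / g$total_length)
})

test_that("metric percents are invariant to scaffold order in the input", {
  g2 <- random_genome(16000, n_seqs = 2, seed = 35)
  rd <- simulate_reads(g2, read_profile(coverage = 15, base_error_rate = 0),
                       seed = 36)
  pas <- map_reads(g2, rd)
  m <- compute_metrics(g2, pas)
  rev_asm <- assembly_record(g2$sequences[c(2, 1)])
  pas_r <- map_reads(rev_asm, rd)
  m_r <- compute_metrics(rev_asm, pas_r)
  for (col in METRIC_NAMES) expect_equal(m[[col]], m_r[[col]], tolerance = 1e-12)
})

test_that("doubling coverage of perfect data barely moves error_free (saturation)", {
  g <- fx_genome()
  rd40 <- simulate_reads(g, read_profile(coverage = 40, base_error_rate = 0),
                         seed = 103)
  m20 <- compute_metrics(g, fx_pas())
  m40 <- compute_metrics(g, map_reads(g, rd40))
  expect_lt(abs(m40$error_free_bases - m20$error_free_bases), 2)
})

test_that("flag medians rise with the structural-error rate", {
  rates <- c(0, 0.01, 0.05, 0.10)
  L <- 15000
  med <- matrix(NA_real_, length(rates), 3,
                dimnames = list(NULL, c("clip", "fcd", "links")))
  for (ri in seq_along(rates)) {
    vals <- matrix(NA_real_, 20, 3)
    for (rep in 1:20) {
      g <- random_genome(L, seed = 4000 + 100 * ri + rep)
      asm <- if (rates[ri] == 0) g else
        translocate_assembly(g, seg_len = max(200L, as.integer(rates[ri] * L / 2)),
                             min_separation = 4000L, seed = 5000 + rep)$assembly
      rd <- simulate_reads(g, read_profile(coverage = 15, base_error_rate = 0),
                           seed = 6000 + 100 * ri + rep)
      pas <- map_reads(asm, rd, insert_stats = c(450, 50))
      am <- accuracy_metrics(flag_errors(pas, asm), pas)
      vals[rep, ] <- c(am$clip, am$fcd_err_in_contig + am$fcd_err_over_gap,
                       am$links)
    }
    med[ri, ] <- apply(vals, 2, median)
  }
  total <- rowSums(med)
  expect_gt(suppressWarnings(cor(total, rates, method = "spearman")), 0)
  # links evidence grows with the amount of rearranged sequence; clip
  # evidence appears as soon as junctions exist (it tracks junction count,
  # which is constant here, so it steps up and stays)
  expect_true(all(diff(med[, "links"]) > 0))
  expect_true(all(med[-1, "clip"] > 0))
})

test_that("zero coverage raises an informative error", {
  g <- fx_genome()
  pas <- fx_pas()
  empty <- pas
  empty$read_depth <- lapply(empty$read_depth, function(x) integer(length(x)))
  expect_error(flag_errors(empty, g), "insufficient coverage")
})

test_that("SAM round trip reproduces the metric row", {
  g2 <- random_genome(16000, n_seqs = 2, seed = 37)
  rd <- simulate_reads(g2, read_profile(coverage = 12, base_error_rate = 0),
                       seed = 38)
  pas <- map_reads(g2, rd)
  sam <- tempfile(fileext = ".sam")
  write_sam(pas, g2, sam)
  pas2 <- read_alignments(sam, g2)
  m1 <- compute_metrics(g2, pas)
  m2 <- compute_metrics(g2, pas2)
  for (col in METRIC_NAMES) expect_equal(m1[[col]], m2[[col]], tolerance = 1e-9)
})

test_that("flag tracks export as BED runs", {
  g <- fx_genome()
  tr <- flag_errors(fx_pas(), g)
  bed <- tempfile(fileext = ".bed")
  write_flag_bed(tr, bed)
  b <- utils::read.table(bed, sep = "\t",
                         col.names = c("chrom", "start", "end", "name"))
  expect_true(all(b$end > b$start))
  ef <- b[b$name == "error_free", ]
  expect_equal(sum(ef$end - ef$start), sum(tr$tracks[[1]]$error_free))
})
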