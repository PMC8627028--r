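#' Default thresholds for per-base error flagging
#'
#' All coverage thresholds are relative to the global mean depth so that
#' 10-30x libraries behave alike. See [flag_errors()] for the meaning of
#' each flag.
#'
#' @param low_cov_frac read-depth fraction of the global mean below which a
#'   base is `low_read_cov`.
#' @param low_fc_frac fragment-depth fraction of the global mean below which
#'   a base is `low_fc_*`.
#' @param fcd_cutoff_frac fragment-coverage-distribution deviation cutoff,
#'   as a fraction of mean fragment depth.
#' @param min_clip_support number of clipped alignments whose clip anchors
#'   must cover a base to flag it `clip`.
#' @param clip_window half-width (bp) of the window around a clip anchor.
#' @param min_clip_len minimum soft-clip length for an alignment to
#'   contribute a clip anchor.
#' @param min_link_support number of distant/cross-sequence pairs covering a
#'   base to flag it `links`.
#' @param link_dist_mult mates further apart than this multiple of the
#'   insert mean count as link evidence.
#' @param coll_mult fragment-depth multiple of the global mean above which a
#'   sustained run is a collapsed repeat.
#' @param min_perfect minimum depth of perfectly matching, unclipped reads
#'   for an `error_free` base.
#' @return named list of thresholds.
#' @export
flag_params <- function(low_cov_frac = 0.25, low_fc_frac = 0.25,
                        fcd_cutoff_frac = 0.3, min_clip_support = 2L,
                        clip_window = 10L, min_clip_len = 5L,
                        min_link_support = 2L, link_dist_mult = 10,
                        coll_mult = 2.0, min_perfect = 5L) {
  as.list(environment())
}

# +1 over each 0-based half-open [start, end) interval on a length-L track
interval_accumulate <- function(L, starts, ends) {
  if (length(starts) == 0L) return(integer(L))
  starts <- pmax(pmin(starts, L), 0L)
  ends <- pmax(pmin(ends, L), 0L)
  d <- tabulate(starts + 1L, nbins = L + 1L) - tabulate(ends + 1L, nbins = L + 1L)
  cumsum(d)[seq_len(L)]
}

# centered running mean, window W (edges use shrinking windows)
running_mean <- function(x, W) {
  n <- length(x)
  h <- W %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Map paired-end reads to an assembly
#'
#' Deterministic k-mer seed-and-extend mapper: exact k-mer seeds taken every
#' `stride` bases vote for (target, diagonal) placements; the best ungapped
#' extension defines the aligned segment, with unaligned read ends recorded
#' as soft clips. Alignments whose matching bases fall below `min_identity`
#' of the read length are discarded. Ties break deterministically by
#' (matches, mismatches, target order, position, strand). The recommended
#' identity floor is 0.5 for chromosome/whole-assembly scoring and 0.75 for
#' scaffolds, where spurious mapping is more likely.
#'
#' @param asm an [assembly_record()].
#' @param reads list with `read1`/`read2` character vectors in matched
#'   order (as from [simulate_reads()] or [read_fastq_pair()]).
#' @param min_identity minimum fraction of read bases matching.
#' @param k seed k-mer size.
#' @param stride spacing between seed start positions within a read.
#' @param mismatch_penalty ungapped extension mismatch penalty (match = +1).
#' @param insert_stats optional c(mean, sd) of the library insert size; if
#'   `NULL`, estimated robustly (median/MAD) from same-target FR pairs.
#' @return a `PairedAlignmentSet`: list with `alignments` (data.frame),
#'   `read_depth`/`perfect_depth` (per-target integer tracks),
#'   `insert_stats`, `mapped_read_count`, `proper_pair_count`, `n_reads`.
#' @export
map_reads <- function(asm, reads, min_identity = 0.5, k = 17L, stride = 8L,
                      mismatch_penalty = 3L, insert_stats = NULL) {
  stopifnot(inherits(asm, "AssemblyRecord"))
  if (length(reads$read1) != length(reads$read2)) stop("mismatched pair files")
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0, 1]")
  res <- .map_reads_cpp(unname(asm$sequences), unname(toupper(reads$read1)),
                        unname(toupper(reads$read2)), k = as.integer(k),
                        stride = as.integer(stride),
                        min_identity = min_identity,
                        mismatch_penalty = as.integer(mismatch_penalty))
  aln <- res$alignments
  if (nrow(aln) == 0L) stop("no alignments")
  aln$seq_id <- names(asm$sequences)[aln$tid]
  names(res$read_depth) <- names(res$perfect_depth) <- names(asm$sequences)
  build_alignment_set(asm, aln, res$read_depth, res$perfect_depth,
                      n_reads = 2L * length(reads$read1),
                      insert_stats = insert_stats)
}

# shared pairing/insert logic for native and external alignments
build_alignment_set <- function(asm, aln, read_depth, perfect_depth, n_reads,
                                insert_stats = NULL) {
  m1 <- aln[aln$mate == 1L, ]
  m2 <- aln[aln$mate == 2L, ]
  i <- match(m1$pair, m2$pair)
  both <- !is.na(i)
  a <- m1[both, ]
  b <- m2[i[both], ]

  same_tid <- a$tid == b$tid
  opp <- a$strand != b$strand
  insert <- pmax(a$end, b$end) - pmin(a$start, b$start)
  # FR orientation: the forward-strand mate starts no later than the reverse one
  fwd_first <- ifelse(a$strand == 1L, a$start <= b$start, b$start <= a$start)
  fr <- same_tid & opp & fwd_first

  if (is.null(insert_stats)) {
    ins <- insert[fr]
    if (length(ins) < 10L) {
      insert_stats <- c(mean = if (length(ins)) stats::median(ins) else NA_real_,
                        sd = if (length(ins)) max(stats::mad(ins), 1) else NA_real_)
    } else {
      insert_stats <- c(mean = stats::median(ins),
                        sd = max(stats::mad(ins), 1))
    }
  } else {
    insert_stats <- c(mean = insert_stats[[1]], sd = insert_stats[[2]])
  }
  if (!is.finite(insert_stats[["mean"]]) || insert_stats[["mean"]] <= 0) {
    stop("could not establish a positive insert size")
  }

  proper <- fr & abs(insert - insert_stats[["mean"]]) <= 3 * insert_stats[["sd"]]

  pairs <- data.frame(pair = a$pair,
                      tid1 = a$tid, start1 = a$start, end1 = a$end,
                      strand1 = a$strand,
                      tid2 = b$tid, start2 = b$start, end2 = b$end,
                      strand2 = b$strand,
                      insert = insert, proper = proper)

  structure(list(
    alignments = aln,
    pairs = pairs,
    read_depth = read_depth,
    perfect_depth = perfect_depth,
    insert_stats = insert_stats,
    mapped_read_count = nrow(aln),
    proper_pair_count = 2L * sum(proper),
    n_reads = n_reads,
    seq_ids = names(asm$sequences),
    seq_lengths = asm$lengths
  ), class = "PairedAlignmentSet")
}

#' @exportS3Method base::print
print.PairedAlignmentSet <- function(x, ...) {
  cat(sprintf(paste0("PairedAlignmentSet: %d alignments, %d/%d reads mapped ",
                     "(%.1f%%), %d reads in proper pairs, insert %.0f +/- %.0f\n"),
              nrow(x$alignments), x$mapped_read_count, x$n_reads,
              100 * x$mapped_read_count / x$n_reads, x$proper_pair_count,
              x$insert_stats[["mean"]], x$insert_stats[["sd"]]))
  invisible(x)
}

#' Import alignments from SAM/BAM
#'
#' External alignments can replace the built-in mapper; the per-base flag
#' engine then runs on them unchanged. Soft/hard clips are taken from the
#' CIGAR and mismatch counts from the NM tag when present (alignments
#' lacking NM are treated as mismatch-free). SAM input is converted with
#' Rsamtools; unsorted input is handled by the import itself.
#'
#' @param path SAM or BAM file of paired-end alignments against `asm`.
#' @param asm the [assembly_record()] the reads were mapped to.
#' @param insert_stats optional c(mean, sd) library insert size.
#' @return a `PairedAlignmentSet`.
#' @export
read_alignments <- function(path, asm, insert_stats = NULL) {
  stopifnot(inherits(asm, "AssemblyRecord"))
  if (!file.exists(path)) stop("file not found: ", path)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  if (length(ga) == 0L) stop("no alignments")
  md <- S4Vectors::mcols(ga)
  flag <- md$flag
  qname <- md$qname
  nm <- md$NM
  if (is.null(nm)) nm <- rep(0L, length(ga))
  nm[is.na(nm)] <- 0L

  tid <- match(as.character(GenomicAlignments::seqnames(ga)), names(asm$sequences))
  if (anyNA(tid)) stop("alignment targets not present in the assembly: ",
                       paste(unique(as.character(
                         GenomicAlignments::seqnames(ga))[is.na(tid)]), collapse = ", "))
  cig <- GenomicAlignments::cigar(ga)
  clip_left <- integer(length(cig))
  has_l <- grepl("^[0-9]+[SH]", cig)
  clip_left[has_l] <- as.integer(sub("^([0-9]+)[SH].*$", "\\1", cig[has_l]))
  clip_right <- integer(length(cig))
  has_r <- grepl("[0-9]+[SH]$", cig)
  clip_right[has_r] <- as.integer(sub("^.*?([0-9]+)[SH]$", "\\1", cig[has_r]))

  qlen <- GenomicAlignments::qwidth(ga) + clip_left + clip_right
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)
  aln <- data.frame(
    pair = match(qname, unique(qname)),
    mate = mate,
    tid = tid,
    start = GenomicAlignments::start(ga) - 1,
    end = GenomicAlignments::end(ga),
    strand = ifelse(as.character(GenomicAlignments::strand(ga)) == "-", -1L, 1L),
    clip_left = clip_left, clip_right = clip_right,
    matches = pmax(GenomicAlignments::qwidth(ga) - nm, 0L),
    mismatches = nm,
    identity = pmax(GenomicAlignments::qwidth(ga) - nm, 0L) / pmax(qlen, 1L))
  aln$seq_id <- names(asm$sequences)[aln$tid]

  L <- asm$lengths
  read_depth <- lapply(names(L), function(id) {
    w <- aln$tid == match(id, names(asm$sequences))
    interval_accumulate(L[[id]], aln$start[w], aln$end[w])
  })
  perf <- aln$clip_left == 0L & aln$clip_right == 0L & aln$mismatches == 0L
  perfect_depth <- lapply(names(L), function(id) {
    w <- perf & aln$tid == match(id, names(asm$sequences))
    interval_accumulate(L[[id]], aln$start[w], aln$end[w])
  })
  names(read_depth) <- names(perfect_depth) <- names(L)

  build_alignment_set(asm, aln, read_depth, perfect_depth,
                      n_reads = length(unique(qname)) * 2L,
                      insert_stats = insert_stats)
}

#' Per-base fragment (physical) depth
#'
#' Each proper pair contributes +1 over the full fragment interval
#' (leftmost alignment start to rightmost alignment end). Pairs spanning
#' two sequences contribute nothing here; they feed the `links` flag.
#'
#' @param pas a `PairedAlignmentSet`.
#' @param asm the matching [assembly_record()].
#' @return named list of integer tracks, one per sequence.
#' @export
fragment_depth <- function(pas, asm) {
  stopifnot(inherits(pas, "PairedAlignmentSet"))
  p <- pas$pairs[pas$pairs$proper, ]
  lapply(stats::setNames(seq_along(asm$lengths), names(asm$lengths)), function(ti) {
    w <- p$tid1 == ti
    interval_accumulate(asm$lengths[[ti]],
                        pmin(p$start1[w], p$start2[w]),
                        pmax(p$end1[w], p$end2[w]))
  })
}

#' Per-base error-evidence flags
#'
#' Scans every base of the assembly for read-mapping error evidence,
#' producing boolean tracks:
#' \describe{
#'   \item{clip}{covered by the anchor windows of at least
#'     `min_clip_support` soft-clipped alignments (clustered clipping marks
#'     breakpoints).}
#'   \item{low_read_cov}{read depth below `low_cov_frac` x global mean.}
#'   \item{low_fc_in_contig / low_fc_over_gap}{fragment depth below
#'     `low_fc_frac` x global mean; a flagged run overlapping a gap run is
#'     `over_gap`, otherwise `in_contig` (mutually exclusive).}
#'   \item{fcd_err_in_contig / fcd_err_over_gap}{mean absolute deviation of
#'     the fragment-depth profile from its local flat fit (running median),
#'     averaged over an insert-length window, exceeds `fcd_cutoff_frac` x
#'     mean fragment depth; split over gaps as above.}
#'   \item{links}{covered by `min_link_support`+ pairs whose mates map to a
#'     different sequence or more than `link_dist_mult` x insert mean away.}
#'   \item{coll_repeat}{fragment depth above `coll_mult` x global mean over
#'     a run at least one insert length long.}
#'   \item{error_free}{depth of perfectly matching, unclipped alignments at
#'     least `min_perfect`, and no other flag set.}
#' }
#' The first and last insert-mean bases of each sequence are excluded from
#' fcd/low_fc flagging: fragments cannot fully cover sequence ends, so
#' physical coverage there is depressed by construction.
#'
#' @param pas a `PairedAlignmentSet`.
#' @param asm the matching [assembly_record()].
#' @param params thresholds from [flag_params()].
#' @return object of class `FlagTracks`: per-sequence list of logical
#'   tracks plus `fragment_depth`/`read_depth`, and the global means.
#' @export
flag_errors <- function(pas, asm, params = flag_params()) {
  stopifnot(inherits(pas, "PairedAlignmentSet"), inherits(asm, "AssemblyRecord"))
  ids <- names(asm$sequences)
  total_len <- asm$total_length
  mean_rd <- sum(vapply(pas$read_depth, function(x) sum(as.numeric(x)), 0)) / total_len
  if (mean_rd == 0) stop("insufficient coverage: mean read depth is 0")
  fd <- fragment_depth(pas, asm)
  mean_fd <- sum(vapply(fd, function(x) sum(as.numeric(x)), 0)) / total_len
  W <- as.integer(round(pas$insert_stats[["mean"]]))
  if (W %% 2L == 0L) W <- W + 1L

  aln <- pas$alignments
  prs <- pas$pairs

  tracks <- lapply(stats::setNames(seq_along(ids), ids), function(ti) {
    id <- ids[ti]
    L <- asm$lengths[[id]]
    rd <- pas$read_depth[[id]]
    f <- fd[[id]]
    gap <- logical(L)
    g <- asm$gap_runs[asm$gap_runs$seq_id == id, , drop = FALSE]
    for (r in seq_len(nrow(g))) gap[(g$start[r] + 1L):g$end[r]] <- TRUE
    edge <- rep(TRUE, L)
    if (L > 2L * W) edge[(W + 1L):(L - W)] <- FALSE

    # clip: clustered clip anchors
    w_aln <- aln$tid == ti
    anchors <- c(aln$start[w_aln & aln$clip_left >= params$min_clip_len],
                 aln$end[w_aln & aln$clip_right >= params$min_clip_len])
    clip_support <- interval_accumulate(L, pmax(anchors - params$clip_window, 0),
                                        pmin(anchors + params$clip_window, L))
    clip <- clip_support >= params$min_clip_support

    # low read coverage
    low_read_cov <- rd < params$low_cov_frac * mean_rd

    # low fragment coverage, split over gaps, edges excluded
    low_fc_raw <- (f < params$low_fc_frac * mean_fd) & !edge
    low_fc <- split_over_gap(low_fc_raw, gap)

    # fragment coverage distribution error: windowed deviation from flat fit
    if (L >= W) {
      med <- stats::runmed(f, W, endrule = "constant")
      dev <- running_mean(abs(f - med), W)
    } else {
      dev <- rep(abs(stats::median(f) - f), length.out = L)
    }
    fcd_raw <- (dev > params$fcd_cutoff_frac * mean_fd) & !edge
    fcd <- split_over_gap(fcd_raw, gap)

    # links: distant or cross-sequence mates
    far <- !is.na(prs$insert) &
      (prs$tid1 != prs$tid2 | prs$insert > params$link_dist_mult * pas$insert_stats[["mean"]])
    lp <- prs[far, , drop = FALSE]
    link_support <- interval_accumulate(L, c(lp$start1[lp$tid1 == ti], lp$start2[lp$tid2 == ti]),
                                        c(lp$end1[lp$tid1 == ti], lp$end2[lp$tid2 == ti]))
    links <- link_support >= params$min_link_support

    # collapsed repeats: sustained high fragment depth
    high <- f > params$coll_mult * mean_fd
    coll_repeat <- runs_at_least(high, W)

    any_err <- clip | low_read_cov | low_fc$in_contig | low_fc$over_gap |
      fcd$in_contig | fcd$over_gap | links | coll_repeat
    error_free <- (pas$perfect_depth[[id]] >= params$min_perfect) & !any_err

    list(clip = clip, low_read_cov = low_read_cov,
         low_fc_in_contig = low_fc$in_contig, low_fc_over_gap = low_fc$over_gap,
         fcd_err_in_contig = fcd$in_contig, fcd_err_over_gap = fcd$over_gap,
         links = links, coll_repeat = coll_repeat, error_free = error_free,
         fragment_depth = f, read_depth = rd)
  })

  structure(list(tracks = tracks, mean_read_depth = mean_rd,
                 mean_fragment_depth = mean_fd, insert_stats = pas$insert_stats,
                 params = params, total_length = total_len),
            class = "FlagTracks")
}

# split a flagged logical track into over_gap / in_contig by run overlap
split_over_gap <- function(flag, gap) {
  if (!any(flag)) return(list(in_contig = flag, over_gap = flag))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  over <- logical(length(flag))
  gcs <- cumsum(gap)
  for (i in which(r$values)) {
    n_gap <- gcs[ends[i]] - if (starts[i] > 1L) gcs[starts[i] - 1L] else 0L
    if (n_gap > 0L) over[starts[i]:ends[i]] <- TRUE
  }
  list(in_contig = flag & !over, over_gap = flag & over)
}

# TRUE only within runs of TRUE of length >= minlen
runs_at_least <- function(x, minlen) {
  if (!any(x)) return(x)
  r <- rle(x)
  r$values <- r$values & r$lengths >= minlen
  inverse.rle(r)
}

#' Accuracy metrics from flag tracks
#'
#' Converts each per-base flag into a percent of total assembly bases, and
#' computes the proper-pair percent (reads in proper pairs / mapped reads).
#'
#' @param tracks a `FlagTracks` object from [flag_errors()].
#' @param pas the `PairedAlignmentSet` the tracks came from.
#' @return one-row data.frame with columns `prop_pair_perc`, `clip`,
#'   `low_read_cov`, `low_fc_in_contig`, `low_fc_over_gap`,
#'   `fcd_err_in_contig`, `fcd_err_over_gap`, `links`, `coll_repeat`,
#'   `error_free_bases`.
#' @export
accuracy_metrics <- function(tracks, pas) {
  stopifnot(inherits(tracks, "FlagTracks"))
  if (pas$mapped_read_count == 0L) stop("no mapped reads")
  total <- tracks$total_length
  pct <- function(flag) {
    100 * sum(vapply(tracks$tracks, function(t) sum(t[[flag]]), 0)) / total
  }
  data.frame(
    prop_pair_perc = 100 * pas$proper_pair_count / pas$mapped_read_count,
    clip = pct("clip"),
    low_read_cov = pct("low_read_cov"),
    low_fc_in_contig = pct("low_fc_in_contig"),
    low_fc_over_gap = pct("low_fc_over_gap"),
    fcd_err_in_contig = pct("fcd_err_in_contig"),
    fcd_err_over_gap = pct("fcd_err_over_gap"),
    links = pct("links"),
    coll_repeat = pct("coll_repeat"),
    error_free_bases = pct("error_free")
  )
}

#' Canonical metric column order
#'
#' The 13 model-facing quality metrics, in fixed order.
#' @export
METRIC_NAMES <- c("normN50", "gap_perc", "prop_pair_perc", "FCD_err_in_contig",
                  "FCD_err_over_gap", "low_fc_in_contig", "low_fc_over_gap",
                  "links", "clip", "coll_repeat", "low_read_cov",
                  "error_free_bases", "norm_contig_number")

#' Full metrics vector for one assembly
#'
#' Combines [contiguity_metrics()] and [accuracy_metrics()] into the
#' 13-metric row consumed by the scoring model (fixed column order,
#' [METRIC_NAMES]), plus auxiliary columns.
#'
#' @param asm an [assembly_record()].
#' @param pas a `PairedAlignmentSet` for `asm`.
#' @param params flag thresholds, see [flag_params()].
#' @param id row identifier.
#' @return one-row data.frame: `id`, the 13 metrics, then auxiliary columns
#'   (`n50`, `n90`, `scaffold_number`, `avg_scaffold_length`, `total_length`).
#' @export
compute_metrics <- function(asm, pas, params = flag_params(), id = "assembly") {
  cm <- contiguity_metrics(asm)
  tr <- flag_errors(pas, asm, params)
  am <- accuracy_metrics(tr, pas)
  row <- data.frame(
    id = id,
    normN50 = cm$normN50,
    gap_perc = cm$gap_perc,
    prop_pair_perc = am$prop_pair_perc,
    FCD_err_in_contig = am$fcd_err_in_contig,
    FCD_err_over_gap = am$fcd_err_over_gap,
    low_fc_in_contig = am$low_fc_in_contig,
    low_fc_over_gap = am$low_fc_over_gap,
    links = am$links,
    clip = am$clip,
    coll_repeat = am$coll_repeat,
    low_read_cov = am$low_read_cov,
    error_free_bases = am$error_free_bases,
    norm_contig_number = cm$norm_contig_number,
    n50 = cm$n50, n90 = cm$n90,
    scaffold_number = cm$scaffold_number,
    avg_scaffold_length = cm$avg_scaffold_length,
    total_length = cm$total_length,
    stringsAsFactors = FALSE)
  row
}

#' Export flag tracks as BED
#'
#' Writes one BED line per maximal flagged run, per flag type (the `name`
#' column carries the flag).
#'
#' @param tracks `FlagTracks` from [flag_errors()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_flag_bed <- function(tracks, path) {
  stopifnot(inherits(tracks, "FlagTracks"))
  flags <- c("clip", "low_read_cov", "low_fc_in_contig", "low_fc_over_gap",
             "fcd_err_in_contig", "fcd_err_over_gap", "links", "coll_repeat",
             "error_free")
  rows <- list()
  for (id in names(tracks$tracks)) {
    for (fl in flags) {
      x <- tracks$tracks[[id]][[fl]]
      if (!any(x)) next
      r <- rle(x)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values
      rows[[length(rows) + 1L]] <- data.frame(chrom = id, start = starts[keep],
                                              end = ends[keep], name = fl)
    }
  }
  bed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character())
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export alignments as SAM
#'
#' Writes the mapper's alignments in SAM (soft clips in the CIGAR, mismatch
#' count in the NM tag; sequence and quality columns are omitted as `*`).
#' A file written here and re-imported with [read_alignments()] yields the
#' same metric row, which is also the supported hand-off to external
#' SAM/BAM tooling.
#'
#' @param pas a `PairedAlignmentSet` from [map_reads()].
#' @param asm the matching [assembly_record()].
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pas, asm, path) {
  stopifnot(inherits(pas, "PairedAlignmentSet"), inherits(asm, "AssemblyRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(asm$lengths),
                     as.integer(asm$lengths)), con)
  a <- pas$alignments
  # mate lookup for RNEXT/PNEXT
  key <- paste(a$pair, a$mate)
  other <- paste(a$pair, 3L - a$mate)
  mi <- match(other, key)
  flag <- 1L +
    ifelse(a$strand == -1L, 16L, 0L) +
    ifelse(a$mate == 1L, 64L, 128L) +
    ifelse(!is.na(mi) & a$strand[pmax(mi, 1L)] == -1L & !is.na(mi), 32L, 0L)
  rnext <- ifelse(is.na(mi), "*",
                  ifelse(a$seq_id[pmax(mi, 1L)] == a$seq_id, "=",
                         a$seq_id[pmax(mi, 1L)]))
  pnext <- ifelse(is.na(mi), 0L, a$start[pmax(mi, 1L)] + 1L)
  flag <- flag + ifelse(is.na(mi), 8L, 0L)
  seg <- a$end - a$start
  cigar <- paste0(ifelse(a$clip_left > 0, paste0(a$clip_left, "S"), ""),
                  seg, "M",
                  ifelse(a$clip_right > 0, paste0(a$clip_right, "S"), ""))
  lines <- sprintf("read%d\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t*\t*\tNM:i:%d",
                   a$pair, flag, a$seq_id, as.integer(a$start) + 1L, cigar,
                   rnext, as.integer(pnext), a$mismatches)
  writeLines(lines, con)
  invisible(path)
}
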