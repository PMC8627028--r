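#' Generate a random genome sequence
#'
#' Uniform i.i.d. bases at a given GC content; a deliberately structure-free
#' null genome for exercising the metric and scoring machinery.
#'
#' @param length sequence length in bp.
#' @param n_seqs number of sequences (length is split equally).
#' @param gc GC content in (0, 1).
#' @param seed integer seed; the generator is fully reproducible.
#' @return an [assembly_record()].
#' @export
random_genome <- function(length = 1e5, n_seqs = 1L, gc = 0.41, seed = 1L) {
  stopifnot(length >= n_seqs, gc > 0, gc < 1)
  withr_seed(seed, {
    per <- diff(round(seq(0, length, length.out = n_seqs + 1)))
    seqs <- vapply(per, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
    names(seqs) <- sprintf("seq%d", seq_len(n_seqs))
    assembly_record(seqs)
  })
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Error profile for assembly degradation
#'
#' Bundles the per-base SNP and indel rates, copy-number and gap event
#' counts, and the fragmentation target used by [mutate_assembly()] /
#' [fragment_assembly()]. Rates are probabilities per base; indel sizes are
#' geometric(`indel_p`) capped at `indel_cap` bp; CNV segment lengths and
#' inserted-gap lengths are sampled uniformly from the given ranges.
#'
#' @param snp_rate substitutions per base.
#' @param indel_rate indel events per base.
#' @param indel_p geometric size parameter for indel lengths.
#' @param indel_cap maximum indel length (bp).
#' @param cnv_events number of copy-number events (tandem duplication or
#'   deletion, equal probability).
#' @param cnv_len_range CNV segment length range (bp).
#' @param gap_events number of N-gap conversions.
#' @param gap_len_range gap length range (bp).
#' @param fragmentation target number of pieces for [fragment_assembly()]
#'   (1 = leave intact).
#' @return a list of class `ErrorProfile`.
#' @export
error_profile <- function(snp_rate = 0, indel_rate = 0, indel_p = 0.5,
                          indel_cap = 50L, cnv_events = 0L,
                          cnv_len_range = c(500L, 5000L), gap_events = 0L,
                          gap_len_range = c(100L, 1000L), fragmentation = 1L) {
  if (snp_rate < 0 || snp_rate > 1) stop("snp_rate must be in [0, 1]")
  if (indel_rate < 0 || indel_rate > 1) stop("indel_rate must be in [0, 1]")
  structure(list(snp_rate = snp_rate, indel_rate = indel_rate,
                 indel_p = indel_p, indel_cap = as.integer(indel_cap),
                 cnv_events = as.integer(cnv_events),
                 cnv_len_range = as.integer(cnv_len_range),
                 gap_events = as.integer(gap_events),
                 gap_len_range = as.integer(gap_len_range),
                 fragmentation = as.integer(fragmentation)),
            class = "ErrorProfile")
}

BASES <- c("A", "C", "G", "T")

#' Inject errors into an assembly
#'
#' Applies, in order, copy-number events, indels, SNPs and N-gap
#' conversions to every sequence. SNPs and indels are never placed inside
#' existing gap runs. Every event is recorded in a truth log with 0-based
#' half-open coordinates on the output sequence where possible.
#'
#' @param asm an [assembly_record()].
#' @param profile an [error_profile()].
#' @param seed integer seed.
#' @return list with `assembly` (the degraded [assembly_record()]) and
#'   `truth` (data.frame: `seq_id`, `type`, `start`, `end`, `detail`).
#' @export
mutate_assembly <- function(asm, profile, seed = 1L) {
  stopifnot(inherits(asm, "AssemblyRecord"), inherits(profile, "ErrorProfile"))
  withr_seed(seed, {
    truth <- list()
    out <- lapply(names(asm$sequences), function(id) {
      s <- charToRaw(asm$sequences[[id]])
      is_gap <- s %in% charToRaw("Nn")

      # CNV events on the original coordinate frame
      for (i in seq_len(profile$cnv_events)) {
        L <- length(s)
        len <- sample(profile$cnv_len_range[1]:profile$cnv_len_range[2], 1L)
        if (L <= len + 1L) next
        st <- sample.int(L - len, 1L)
        if (stats::runif(1) < 0.5) {
          s <- c(s[seq_len(st + len - 1L)], s[st:(st + len - 1L)],
                 if (st + len <= L) s[(st + len):L] else raw(0))
          truth[[length(truth) + 1L]] <<- data.frame(
            seq_id = id, type = "cnv_dup", start = st - 1L, end = st + len - 1L,
            detail = sprintf("len=%d", len))
        } else {
          s <- s[-(st:(st + len - 1L))]
          truth[[length(truth) + 1L]] <<- data.frame(
            seq_id = id, type = "cnv_del", start = st - 1L, end = st + len - 1L,
            detail = sprintf("len=%d", len))
        }
        is_gap <- s %in% charToRaw("Nn")
      }

      # indels (applied right-to-left so positions stay valid)
      if (profile$indel_rate > 0) {
        cand <- which(!is_gap)
        n_ind <- stats::rbinom(1L, length(cand), profile$indel_rate)
        if (n_ind > 0) {
          pos <- sort(sample(cand, n_ind), decreasing = TRUE)
          sizes <- pmin(stats::rgeom(n_ind, profile$indel_p) + 1L, profile$indel_cap)
          ins <- stats::runif(n_ind) < 0.5
          for (i in seq_len(n_ind)) {
            p <- pos[i]; sz <- sizes[i]
            if (ins[i]) {
              piece <- charToRaw(paste(sample(BASES, sz, replace = TRUE), collapse = ""))
              s <- c(s[seq_len(p)], piece, if (p < length(s)) s[(p + 1L):length(s)] else raw(0))
              truth[[length(truth) + 1L]] <<- data.frame(
                seq_id = id, type = "ins", start = p, end = p + sz,
                detail = sprintf("len=%d", sz))
            } else {
              e <- min(p + sz - 1L, length(s))
              s <- s[-(p:e)]
              truth[[length(truth) + 1L]] <<- data.frame(
                seq_id = id, type = "del", start = p - 1L, end = e,
                detail = sprintf("len=%d", e - p + 1L))
            }
          }
          is_gap <- s %in% charToRaw("Nn")
        }
      }

      # SNPs
      if (profile$snp_rate > 0) {
        cand <- which(!is_gap)
        n_snp <- stats::rbinom(1L, length(cand), profile$snp_rate)
        if (n_snp > 0) {
          pos <- sample(cand, n_snp)
          orig <- toupper(rawToChar(s[pos], multiple = TRUE))
          repl <- vapply(orig, function(b) sample(setdiff(BASES, b), 1L), character(1))
          s[pos] <- charToRaw(paste(repl, collapse = ""))
          truth[[length(truth) + 1L]] <<- data.frame(
            seq_id = id, type = "snp", start = sort(pos) - 1L, end = sort(pos),
            detail = "sub")
        }
      }

      # gap conversions: replace a stretch with N
      for (i in seq_len(profile$gap_events)) {
        L <- length(s)
        len <- sample(profile$gap_len_range[1]:profile$gap_len_range[2], 1L)
        if (L <= len + 1L) next
        st <- sample.int(L - len, 1L)
        s[st:(st + len - 1L)] <- charToRaw("N")
        truth[[length(truth) + 1L]] <<- data.frame(
          seq_id = id, type = "gap", start = st - 1L, end = st + len - 1L,
          detail = sprintf("len=%d", len))
      }

      rawToChar(s)
    })
    names(out) <- names(asm$sequences)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seq_id = character(), type = character(), start = integer(),
                 end = integer(), detail = character())
    list(assembly = assembly_record(unlist(out)), truth = truth)
  })
}

#' Fragment an assembly into pieces
#'
#' Cuts sequences at uniformly random positions until the assembly consists
#' of `n_pieces` sequences. Total sequence content is conserved.
#'
#' @param asm an [assembly_record()].
#' @param n_pieces target number of pieces (>= current sequence count).
#' @param seed integer seed.
#' @return an [assembly_record()].
#' @export
fragment_assembly <- function(asm, n_pieces, seed = 1L) {
  stopifnot(inherits(asm, "AssemblyRecord"))
  if (n_pieces < 1L) stop("n_pieces must be >= 1")
  n_cuts <- n_pieces - length(asm$sequences)
  if (n_cuts <= 0L) return(asm)
  withr_seed(seed, {
    pieces <- asm$sequences
    for (i in seq_len(n_cuts)) {
      lens <- nchar(pieces)
      cut_ok <- lens >= 2L
      if (!any(cut_ok)) break
      # cut the longest piece; deterministic and keeps pieces balanced
      j <- which.max(ifelse(cut_ok, lens, -Inf))
      L <- lens[j]
      at <- sample.int(L - 1L, 1L)
      left <- substr(pieces[[j]], 1L, at)
      right <- substr(pieces[[j]], at + 1L, L)
      nm <- names(pieces)[j]
      # halves replace the parent in place so assembly order is conserved
      pieces <- append(pieces[-j], stats::setNames(c(left, right),
                                                   paste0(nm, c(".a", ".b"))),
                       after = j - 1L)
    }
    names(pieces) <- sprintf("piece%d", seq_along(pieces))
    assembly_record(pieces)
  })
}

#' Read-simulation profile
#'
#' @param coverage fold sequence coverage of the assembly.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment (insert) size distribution, bp.
#' @param base_error_rate per-base substitution error probability.
#' @return a list of class `ReadProfile`.
#' @export
read_profile <- function(coverage = 20, read_length = 150L, insert_mean = 450,
                         insert_sd = 50, base_error_rate = 0.001) {
  if (coverage <= 0) stop("coverage must be positive")
  if (insert_mean <= 2 * read_length) {
    warning("insert_mean <= 2 * read_length: mates will overlap")
  }
  structure(list(coverage = coverage, read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 base_error_rate = base_error_rate),
            class = "ReadProfile")
}

#' Simulate paired-end reads
#'
#' Fragments are drawn with normal(insert_mean, insert_sd) lengths at
#' uniform positions on each sequence (proportionally to length); fragments
#' overlapping N runs are resampled up to 10 times. Read 1 is the fragment's
#' left end; read 2 is the reverse complement of its right end (FR
#' orientation). Per-base errors are Bernoulli substitutions.
#'
#' @param asm an [assembly_record()]; every sequence must be at least one
#'   insert length long.
#' @param profile a [read_profile()].
#' @param seed integer seed.
#' @return list with `read1`, `read2` (named character vectors) and `truth`
#'   (data.frame of originating `seq_id`, fragment `start`, `end`).
#' @export
simulate_reads <- function(asm, profile, seed = 1L) {
  stopifnot(inherits(asm, "AssemblyRecord"), inherits(profile, "ReadProfile"))
  rl <- profile$read_length
  usable <- asm$lengths >= profile$insert_mean
  if (!any(usable)) stop("insert_mean larger than every sequence")
  withr_seed(seed, {
    lens <- as.numeric(asm$lengths[usable])
    ids <- names(asm$lengths)[usable]
    n_pairs <- round(profile$coverage * sum(lens) / (2 * rl))
    sid <- sample(seq_along(ids), n_pairs, replace = TRUE, prob = lens)

    frag_len <- pmax(rl, pmin(round(stats::rnorm(n_pairs, profile$insert_mean,
                                                 profile$insert_sd)),
                              as.integer(lens[sid])))
    start <- floor(stats::runif(n_pairs) * (lens[sid] - frag_len + 1)) + 1

    # resample fragments touching N runs (up to 10 rounds)
    has_gap <- nrow(asm$gap_runs) > 0L
    if (has_gap) {
      raws <- lapply(asm$sequences[usable], charToRaw)
      gapmask <- lapply(raws, function(r) cumsum(r %in% charToRaw("Nn")))
      overlaps_gap <- function(sid, start, fl) {
        mapply(function(i, st, f) {
          g <- gapmask[[i]]
          hi <- min(st + f - 1, length(g))
          (g[hi] - if (st > 1) g[st - 1] else 0L) > 0L
        }, sid, start, fl)
      }
      for (round in 1:10) {
        bad <- overlaps_gap(sid, start, frag_len)
        if (!any(bad)) break
        nb <- sum(bad)
        start[bad] <- floor(stats::runif(nb) * (lens[sid[bad]] - frag_len[bad] + 1)) + 1
      }
    }

    frag <- substring(asm$sequences[usable][sid], start, start + frag_len - 1)
    r1 <- toupper(substr(frag, 1L, rl))
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      toupper(substr(frag, frag_len - rl + 1L, frag_len)))))

    if (profile$base_error_rate > 0) {
      r1 <- inject_read_errors(r1, profile$base_error_rate)
      r2 <- inject_read_errors(r2, profile$base_error_rate)
    }
    nm <- sprintf("read%d", seq_len(n_pairs))
    names(r1) <- names(r2) <- nm
    list(read1 = r1, read2 = r2,
         truth = data.frame(read_id = nm, seq_id = ids[sid],
                            start = start - 1L, end = start - 1L + frag_len))
  })
}

inject_read_errors <- function(reads, rate) {
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    p <- sample.int(nchar(reads[i]), n_err[i])
    for (q in p) {
      b <- substr(reads[i], q, q)
      if (!b %in% BASES) next
      substr(reads[i], q, q) <- sample(setdiff(BASES, b), 1L)
    }
  }
  reads
}

#' Write simulated reads as paired FASTQ
#'
#' @param reads result of [simulate_reads()].
#' @param prefix output prefix; files `<prefix>_1.fastq` / `_2.fastq` (add
#'   `.gz` via `compress = TRUE`).
#' @param compress gzip the output.
#' @return character vector of the two paths.
#' @export
write_fastq_pair <- function(reads, prefix, compress = FALSE) {
  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_1", "_2"), ext)
  for (i in 1:2) {
    x <- Biostrings::DNAStringSet(reads[[i]])
    q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
      paste(rep("I", w), collapse = ""), character(1)))
    Biostrings::writeXStringSet(x, paths[i], format = "fastq", qualities = q,
                                compress = compress)
  }
  paths
}

#' Read paired FASTQ files
#'
#' @param path1,path2 mate FASTQ paths (optionally gzipped).
#' @return list with `read1`, `read2` named character vectors.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(r1) != length(r2)) stop("mismatched pair files: ",
                                     length(r1), " vs ", length(r2), " reads")
  names(r1) <- sub("\\s.*$", "", names(r1))
  names(r2) <- sub("\\s.*$", "", names(r2))
  list(read1 = as.character(r1), read2 = as.character(r2))
}

#' Swap two distant segments (simulated translocation)
#'
#' Exchanges two equal-length, non-overlapping segments of one sequence,
#' creating four breakpoint junctions whose coordinates are returned as
#' truth. Reads simulated from the original sequence and mapped to the
#' rearranged one produce clip/fcd/links evidence at these junctions.
#'
#' @param asm an [assembly_record()] (the first sequence is rearranged).
#' @param seg_len segment length in bp.
#' @param min_separation minimum distance between the two segments.
#' @param seed integer seed.
#' @return list with `assembly` and `breakpoints` (data.frame `seq_id`,
#'   `pos` of the four junctions, 0-based).
#' @export
translocate_assembly <- function(asm, seg_len = 2000L, min_separation = 10000L,
                                 seed = 1L) {
  stopifnot(inherits(asm, "AssemblyRecord"))
  id <- names(asm$sequences)[1]
  s <- asm$sequences[[id]]
  L <- nchar(s)
  if (L < 2L * seg_len + min_separation + 2L) stop("sequence too short")
  withr_seed(seed, {
    a <- sample.int(L - (2L * seg_len + min_separation), 1L)
    b <- a + seg_len + min_separation +
      sample.int(L - (a + 2L * seg_len + min_separation), 1L) - 1L
    seg_a <- substr(s, a, a + seg_len - 1L)
    seg_b <- substr(s, b, b + seg_len - 1L)
    out <- paste0(substr(s, 1L, a - 1L), seg_b,
                  substr(s, a + seg_len, b - 1L), seg_a,
                  substr(s, b + seg_len, L))
    seqs <- asm$sequences
    seqs[[id]] <- out
    list(assembly = assembly_record(seqs),
         breakpoints = data.frame(
           seq_id = id,
           pos = c(a - 1L, a + seg_len - 1L, b - 1L, b + seg_len - 1L)))
  })
}
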