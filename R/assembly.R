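#' @useDynLib asmqual, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

VALID_BASES <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")

#' Construct an assembly record
#'
#' An `AssemblyRecord` holds the ordered scaffolds/contigs of one assembly
#' together with the coordinates of its gap (N) runs. Coordinates are
#' 0-based, half-open throughout the package (BED convention when written
#' to file). Lowercase (soft-masked) bases are kept as given but treated as
#' their uppercase equivalents by every metric.
#'
#' @param sequences named character vector of DNA sequences (A/C/G/T/N,
#'   either case), or a [Biostrings::DNAStringSet].
#' @return An object of class `AssemblyRecord`: a list with elements
#'   `sequences` (named character vector), `lengths`, `total_length`, and
#'   `gap_runs` (data.frame with `seq_id`, `start`, `end` of maximal N runs).
#' @examples
#' asm <- assembly_record(c(s1 = "ACNNNGT"))
#' asm$gap_runs
#' @export
assembly_record <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (length(sequences) == 0L) stop("empty assembly")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) stop("every sequence needs a non-empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- vapply(sequences, function(s) {
    m <- regexpr("[^ACGTNacgtn]", s)
    as.integer(m)
  }, integer(1))
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character in sequence '%s' at position %d",
                 ids[i], bad[i]))
  }
  lens <- nchar(sequences)
  if (sum(lens) == 0L) stop("empty assembly")
  obj <- structure(list(
    sequences = sequences,
    lengths = stats::setNames(as.integer(lens), ids),
    total_length = sum(as.numeric(lens)),
    gap_runs = find_gap_runs(sequences)
  ), class = "AssemblyRecord")
  obj
}

# maximal runs of N/n per sequence, 0-based half-open
find_gap_runs <- function(sequences) {
  out <- lapply(names(sequences), function(id) {
    m <- gregexpr("[Nn]+", sequences[[id]])[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(seq_id = id,
               start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + attr(m, "match.length"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' @exportS3Method base::print
print.AssemblyRecord <- function(x, ...) {
  cat(sprintf("AssemblyRecord: %d sequence(s), %s bp total, %d gap run(s)\n",
              length(x$sequences), format(x$total_length, big.mark = ","),
              nrow(x$gap_runs)))
  invisible(x)
}

#' Read an assembly from FASTA
#'
#' @param path path to a (possibly wrapped) multi-record FASTA file.
#' @return An [assembly_record()] preserving the input sequence order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("failed to parse FASTA: ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("empty assembly")
  # keep first whitespace-delimited token of the header as the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  assembly_record(as.character(seqs))
}

#' Write an assembly to FASTA
#'
#' @param asm an [assembly_record()].
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(asm, path, width = 70L) {
  x <- Biostrings::DNAStringSet(asm$sequences)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' N50/N90-style length statistic
#'
#' Smallest length L such that sequences of length >= L together cover at
#' least `x` of the total length. `nxx(lengths, 0.5)` is the N50,
#' `nxx(lengths, 0.9)` the N90.
#'
#' @param lengths positive sequence lengths (any order).
#' @param x fraction in (0, 1].
#' @return length in bp.
#' @examples
#' nxx(c(30, 20, 10), 0.5)  # 30
#' nxx(c(30, 20, 10), 0.9)  # 10
#' @export
nxx <- function(lengths, x = 0.5) {
  if (length(lengths) == 0L) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (x <= 0 || x > 1) stop("x must be in (0, 1]")
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(l)
  l[which(cum >= x * sum(l))[1L]]
}

# split scaffolds into contigs at N runs of >= min_gap bases
contig_lengths <- function(asm, min_gap = 1L) {
  unlist(lapply(names(asm$sequences), function(id) {
    L <- asm$lengths[[id]]
    g <- asm$gap_runs[asm$gap_runs$seq_id == id &
                      (asm$gap_runs$end - asm$gap_runs$start) >= min_gap, ,
                      drop = FALSE]
    if (nrow(g) == 0L) return(L)
    starts <- c(0L, g$end)
    ends <- c(g$start, L)
    lens <- ends - starts
    lens[lens > 0L]
  }), use.names = FALSE)
}

#' Contiguity and completeness metrics
#'
#' Computes the sequence-derived metric block: gap percent, N50/N90 and
#' their length-normalised forms, scaffold and contig counts, and average
#' scaffold length. `normN50` is the scaffold N50 expressed as a percent of
#' total assembled length, so a single-piece assembly scores 100.
#'
#' @param asm an [assembly_record()].
#' @param min_gap minimum N-run length that breaks a scaffold into contigs.
#' @return a one-row data.frame with columns `gap_perc`, `n50`, `n90`,
#'   `normN50`, `normN90`, `scaffold_number`, `contig_number`,
#'   `norm_contig_number` (contigs per Mbp), `avg_scaffold_length`,
#'   `contig_n50`, `total_length`.
#' @export
contiguity_metrics <- function(asm, min_gap = 1L) {
  stopifnot(inherits(asm, "AssemblyRecord"))
  lens <- as.numeric(asm$lengths)
  total <- asm$total_length
  n_gap_bases <- sum(asm$gap_runs$end - asm$gap_runs$start)
  clens <- contig_lengths(asm, min_gap = min_gap)
  n50 <- nxx(lens, 0.5)
  n90 <- nxx(lens, 0.9)
  data.frame(
    gap_perc = 100 * n_gap_bases / total,
    n50 = n50,
    n90 = n90,
    normN50 = 100 * n50 / total,
    normN90 = 100 * n90 / total,
    scaffold_number = length(lens),
    contig_number = length(clens),
    norm_contig_number = length(clens) / (total / 1e6),
    avg_scaffold_length = mean(lens),
    contig_n50 = if (length(clens)) nxx(clens, 0.5) else NA_real_,
    total_length = total
  )
}
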