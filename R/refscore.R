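#' Count reference bases not matched by a query assembly
#'
#' Aligns query to reference with an exact, deterministic anchor-chaining
#' algorithm (unique k-mer matches chained by a weighted
#' longest-increasing-subsequence DP, inter-anchor regions closed by a
#' match-maximising dynamic program) and reports the number of reference
#' bases that no 1-to-1 alignment column pairs with an identical query base:
#' substituted bases, deleted blocks and unaligned reference sequence all
#' count. When query and reference carry identical sequence ids they are
#' compared per id; otherwise both sides are concatenated in their given
#' order (the layout a fragmented copy of a reference produces) and
#' compared as single sequences.
#'
#' @param query the assembly being scored ([assembly_record()]).
#' @param ref the trusted reference ([assembly_record()]).
#' @param k anchor k-mer size.
#' @param max_dp_area inter-anchor regions with more DP cells than this use
#'   a banded approximation instead of the full quadratic DP.
#' @return a `DiffSummary`: list with `ref_length`, `total_differences`,
#'   `matched`.
#' @export
count_differences <- function(query, ref, k = 21L, max_dp_area = 4e7) {
  stopifnot(inherits(query, "AssemblyRecord"), inherits(ref, "AssemblyRecord"))
  paired <- identical(names(query$sequences), names(ref$sequences))
  qs <- if (paired) query$sequences else
    stats::setNames(paste(query$sequences, collapse = ""), "all")
  rs <- if (paired) ref$sequences else
    stats::setNames(paste(ref$sequences, collapse = ""), "all")

  ref_length <- 0
  diffs <- 0
  matched <- 0
  for (i in seq_along(rs)) {
    ref_length <- ref_length + nchar(rs[[i]])
    res <- .count_differences_cpp(rs[[i]], qs[[i]], k = as.integer(k),
                                  max_dp_area = max_dp_area)
    if (isTRUE(res$no_anchors) && res$matched == 0 && nchar(rs[[i]]) > 0) {
      warning("no alignment anchors found for reference sequence '",
              names(rs)[i], "'; counting it as fully diverged")
    }
    diffs <- diffs + res$total_differences
    matched <- matched + res$matched
  }
  structure(list(ref_length = ref_length, total_differences = diffs,
                 matched = matched), class = "DiffSummary")
}

#' Percent matching bases
#'
#' `PMB = (ref_length - total_differences) / ref_length * 100`: the percent
#' of reference bases correctly reproduced by the query. A self-to-self
#' comparison scores exactly 100. This is the reference-based quantity the
#' quality model is trained to predict (after scaling).
#'
#' @param d a `DiffSummary` from [count_differences()], or a list with
#'   `ref_length` and `total_differences`.
#' @return percent in \[0, 100\].
#' @export
percent_matching_bases <- function(d) {
  if (is.null(d$ref_length) || d$ref_length <= 0) stop("ref_length must be > 0")
  (d$ref_length - d$total_differences) / d$ref_length * 100
}

#' The ideal metric vector
#'
#' Target values a perfectly accurate, continuous and complete sequence
#' would produce: normN50 100, gap percent 0, proper-pair and error-free
#' percents 100, every error-flag percent 0. Used as the origin for the
#' Euclidean distances that drive internal/external score scaling.
#' `norm_contig_number` has no finite worst bound, so it is excluded from
#' the distance metric set; the 12 remaining metrics all live on a 0-100
#' scale.
#'
#' @return named numeric vector over the distance metric set.
#' @export
ideal_vector <- function() {
  c(normN50 = 100, gap_perc = 0, prop_pair_perc = 100,
    FCD_err_in_contig = 0, FCD_err_over_gap = 0, low_fc_in_contig = 0,
    low_fc_over_gap = 0, links = 0, clip = 0, coll_repeat = 0,
    low_read_cov = 0, error_free_bases = 100)
}

# distance from the ideal vector to the all-worst vector: the fixed
# normaliser D of the scaling factor (every metric at its worst 0-100 bound)
worst_distance <- function(ideal = ideal_vector()) {
  sqrt(sum((ideal - (100 - ideal))^2))
}

#' Euclidean distance from the ideal metric vector
#'
#' @param m named numeric vector or one-row data.frame of metrics; must
#'   contain every metric in `ideal`.
#' @param ideal the ideal values, see [ideal_vector()].
#' @return non-negative distance; 0 iff `m` equals the ideal on the
#'   distance metric set.
#' @export
ideal_distance <- function(m, ideal = ideal_vector()) {
  nm <- if (is.data.frame(m)) colnames(m) else names(m)
  missing <- setdiff(names(ideal), nm)
  if (length(missing)) stop("missing metric(s): ", paste(missing, collapse = ", "))
  v <- if (is.data.frame(m)) {
    vapply(names(ideal), function(f) as.numeric(m[[f]][1]), 0)
  } else {
    as.numeric(m[names(ideal)])
  }
  sqrt(sum((v - ideal)^2))
}

#' Internal score scaling within one organism
#'
#' The instance closest to the ideal metric vector keeps its percent of
#' matching bases as its score; every other instance i is scaled by the
#' linear factor `1 - (d_i - d_best) / D`, where D is the fixed distance
#' from the ideal vector to the all-worst vector. Results are clipped below
#' at 0. The factor is 1 when distances tie, so equally good instances keep
#' their PMB.
#'
#' @param instances data.frame with one row per instance, containing the
#'   distance metric columns and a `pmb` column.
#' @param ideal ideal metric values.
#' @return `instances` with columns `ideal_dist` and `scaled_score` added.
#' @export
internal_scale <- function(instances, ideal = ideal_vector()) {
  if (nrow(instances) == 0L) stop("no instances")
  d <- vapply(seq_len(nrow(instances)),
              function(i) ideal_distance(instances[i, ], ideal), 0)
  D <- worst_distance(ideal)
  fac <- pmax(1 - (d - min(d)) / D, 0)
  instances$ideal_dist <- d
  instances$scaled_score <- pmax(instances$pmb * fac, 0)
  instances
}

#' External score scaling across organisms
#'
#' After [internal_scale()], each organism is represented by its best
#' (minimum-distance) instance; the organism whose best instance is
#' globally closest to the ideal keeps its scores, and every other
#' organism's scores are multiplied by `1 - (d_best_org - d_best_global) / D`.
#'
#' @param instances data.frame as in [internal_scale()] but with an
#'   `organism` column; internal scaling is applied per organism first if
#'   `scaled_score` is absent.
#' @param ideal ideal metric values.
#' @return `instances` with a `final_score` column added.
#' @export
external_scale <- function(instances, ideal = ideal_vector()) {
  if (nrow(instances) == 0L) stop("no instances")
  if (is.null(instances$organism)) stop("instances need an 'organism' column")
  if (is.null(instances$scaled_score)) {
    parts <- split(instances, instances$organism)
    instances <- do.call(rbind, lapply(parts, internal_scale, ideal = ideal))
    rownames(instances) <- NULL
  }
  best_d <- tapply(instances$ideal_dist, instances$organism, min)
  D <- worst_distance(ideal)
  fac <- pmax(1 - (best_d - min(best_d)) / D, 0)
  instances$final_score <- as.numeric(pmax(
    instances$scaled_score * fac[as.character(instances$organism)], 0))
  instances
}
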