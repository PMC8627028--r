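#' Default degradation gradient
#'
#' Five quality levels spanning the range a scoring model must resolve:
#' pristine, lightly fragmented/noisy, and three increasingly damaged
#' levels mixing substitutions, indels, copy-number events, inserted gaps
#' and fragmentation.
#'
#' @return list of five [error_profile()]s with attached `fragmentation`.
#' @export
default_gradient <- function() {
  list(
    error_profile(),
    error_profile(snp_rate = 0.002, indel_rate = 2e-4, gap_events = 1L,
                  fragmentation = 2L),
    error_profile(snp_rate = 0.01, indel_rate = 5e-4, cnv_events = 1L,
                  gap_events = 3L, fragmentation = 5L),
    error_profile(snp_rate = 0.05, indel_rate = 1e-3, cnv_events = 2L,
                  gap_events = 5L, fragmentation = 10L),
    error_profile(snp_rate = 0.15, indel_rate = 2e-3, cnv_events = 3L,
                  gap_events = 8L, fragmentation = 20L)
  )
}

#' Generate a synthetic training set
#'
#' For each synthetic reference genome, applies every degradation profile,
#' simulates reads from the pristine source, maps them to the degraded copy
#' (so mapping evidence reflects the injected errors, mirroring real reads
#' mapped to an imperfect assembly), computes the full metric vector, and
#' scores the degraded copy against its reference (percent matching bases
#' with internal scaling per genome and external scaling across genomes).
#'
#' @param n_genomes number of reference genomes (>= 2 so external scaling
#'   is exercised).
#' @param gradient list of [error_profile()]s defining the quality levels.
#' @param ref_length reference length in bp.
#' @param reads a [read_profile()].
#' @param params flag thresholds ([flag_params()]).
#' @param min_identity mapper identity floor.
#' @param seed integer seed; every per-instance seed derives from it.
#' @return a metrics table: one row per (genome, level) with `organism`,
#'   `level`, `id`, the 13 metrics, `pmb`, `ideal_dist`, `scaled_score`,
#'   `final_score` and `score` (= `final_score`, the modelling target).
#' @export
generate_training_set <- function(n_genomes = 20L, gradient = default_gradient(),
                                  ref_length = 5e4, reads = read_profile(),
                                  params = flag_params(), min_identity = 0.5,
                                  seed = 1L) {
  if (n_genomes < 2L) stop("need at least 2 genomes")
  rows <- list()
  for (g in seq_len(n_genomes)) {
    gseed <- (seed * 1000L + g) %% .Machine$integer.max
    ref <- random_genome(length = ref_length, seed = gseed)
    rd <- simulate_reads(ref, reads, seed = gseed + 500L)
    for (lv in seq_along(gradient)) {
      prof <- gradient[[lv]]
      mut <- mutate_assembly(ref, prof, seed = gseed + lv)
      asm <- mut$assembly
      if (prof$fragmentation > 1L) {
        asm <- fragment_assembly(asm, prof$fragmentation, seed = gseed + lv)
      }
      pas <- map_reads(asm, rd, min_identity = min_identity)
      m <- compute_metrics(asm, pas, params = params,
                           id = sprintf("genome%d_level%d", g, lv))
      m$organism <- sprintf("genome%d", g)
      m$level <- lv
      m$pmb <- percent_matching_bases(count_differences(asm, ref))
      rows[[length(rows) + 1L]] <- m
    }
  }
  tab <- do.call(rbind, rows)
  tab <- external_scale(tab)
  tab$score <- tab$final_score
  rownames(tab) <- NULL
  tab
}
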