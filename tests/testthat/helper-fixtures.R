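# Shared fixtures, built lazily once per test run. Sizes are desk-scale:
# large enough for coverage statistics to concentrate, small enough that
# the whole suite stays fast.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_genome <- function() fixture("genome", function() random_genome(2e4, seed = 101))

fx_reads <- function() fixture("reads", function() {
  simulate_reads(fx_genome(), read_profile(coverage = 20, base_error_rate = 0),
                 seed = 102)
})

fx_pas <- function() fixture("pas", function() map_reads(fx_genome(), fx_reads()))

# small synthetic training table over an SNP ladder (shared by the feature
# selection / model tests)
fx_table <- function() fixture("table", function() {
  ladder <- lapply(c(0, 0.05, 0.10, 0.15, 0.20),
                   function(r) error_profile(snp_rate = r, gap_events = 1L,
                                             fragmentation = 3L))
  generate_training_set(n_genomes = 6, gradient = ladder, ref_length = 2e4,
                        reads = read_profile(coverage = 15), seed = 7)
})

# quadratic-time alignment oracle: matched reference bases via LCS,
# computed independently with base R edit distances
oracle_differences <- function(ref, qry) {
  d <- as.numeric(utils::adist(ref, qry, costs = list(ins = 1, del = 1, sub = 2)))
  lcs <- (nchar(ref) + nchar(qry) - d) / 2
  nchar(ref) - lcs
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  k <- rbinom(1, length(v), rate)
  if (k > 0) {
    p <- sample(length(v), k)
    for (i in p) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  }
  paste(v, collapse = "")
}
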