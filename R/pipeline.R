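#' Run configuration
#'
#' Validates and bundles the inputs for one pipeline run. Mode-specific
#' required fields are checked up front so a run fails before any work
#' starts.
#'
#' @param mode one of `score`, `metrics`, `train`, `refscore`, `simulate`.
#' @param assembly path to the assembly FASTA (score/metrics/refscore).
#' @param reads1,reads2 paired FASTQ paths (optionally gzipped).
#' @param bam SAM/BAM of pre-mapped reads; when given, mapping is skipped.
#' @param reference reference FASTA (refscore mode).
#' @param model_dir directory of a persisted model (score mode).
#' @param table CSV of training metrics (train mode).
#' @param min_identity mapper identity floor (0.5 default; 0.75 recommended
#'   for scaffolds).
#' @param per_sequence score every sequence separately in addition to the
#'   whole assembly.
#' @param params flag thresholds ([flag_params()]).
#' @param min_coverage_warn,min_coverage_stop mean read-depth floors: below
#'   the first a warning cites the 10x recommendation; below the second the
#'   run stops.
#' @param seed integer seed.
#' @return validated list of class `RunConfig`.
#' @export
run_config <- function(mode = c("score", "metrics", "train", "refscore",
                                "simulate"),
                       assembly = NULL, reads1 = NULL, reads2 = NULL,
                       bam = NULL, reference = NULL, model_dir = NULL,
                       table = NULL, min_identity = 0.5, per_sequence = TRUE,
                       params = flag_params(), min_coverage_warn = 10,
                       min_coverage_stop = 2, seed = 1L) {
  mode <- match.arg(mode)
  need <- function(x, what) {
    if (is.null(x)) stop("mode '", mode, "' requires ", what)
  }
  if (mode %in% c("score", "metrics")) {
    need(assembly, "an assembly FASTA")
    if (is.null(bam) && (is.null(reads1) || is.null(reads2))) {
      stop("mode '", mode, "' requires paired reads (reads1/reads2) or a bam")
    }
  }
  if (mode == "score") need(model_dir, "a model directory (model_dir)")
  if (mode == "refscore") { need(assembly, "a query FASTA"); need(reference, "a reference FASTA") }
  if (mode == "train") need(table, "a metrics CSV (table)")
  structure(as.list(environment())[c("mode", "assembly", "reads1", "reads2",
                                     "bam", "reference", "model_dir", "table",
                                     "min_identity", "per_sequence", "params",
                                     "min_coverage_warn", "min_coverage_stop",
                                     "seed")],
            class = "RunConfig")
}

# assemble the PairedAlignmentSet for a config (maps or imports)
alignments_for <- function(cfg, asm) {
  if (!is.null(cfg$bam)) {
    pas <- read_alignments(cfg$bam, asm)
  } else {
    reads <- read_fastq_pair(cfg$reads1, cfg$reads2)
    pas <- map_reads(asm, reads, min_identity = cfg$min_identity)
  }
  mean_depth <- sum(vapply(pas$read_depth, function(x) sum(as.numeric(x)), 0)) /
    asm$total_length
  if (mean_depth < cfg$min_coverage_stop) {
    stop(sprintf("mean read depth %.2fx is below the hard floor of %gx",
                 mean_depth, cfg$min_coverage_stop))
  }
  if (mean_depth < cfg$min_coverage_warn) {
    warning(sprintf(paste0("mean read depth %.1fx is below the recommended ",
                           "%gx; accuracy metrics will be noisy"),
                    mean_depth, cfg$min_coverage_warn))
  }
  pas
}

#' Score an assembly end to end
#'
#' FASTA (+ reads or alignments) to metrics to model score. The whole
#' assembly is always scored as one metric set over all sequences
#' (including unplaced pieces); with `per_sequence = TRUE` each sequence is
#' additionally scored as its own single-piece assembly. The output states
#' the granularity of every row: a perfect score for one sequence says
#' nothing about the rest of the assembly.
#'
#' @param cfg a [run_config()] with mode `score` (or `metrics`, which skips
#'   the model).
#' @return list with `metrics` (one row per scored unit, `granularity`
#'   column included) and, in score mode, `scores` (data.frame `id`,
#'   `granularity`, `score`).
#' @export
score_assembly <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (!cfg$mode %in% c("score", "metrics")) stop("config mode must be score or metrics")
  asm <- read_fasta(cfg$assembly)
  pas <- alignments_for(cfg, asm)

  rows <- list(cbind(compute_metrics(asm, pas, params = cfg$params,
                                     id = "whole_assembly"),
                     granularity = "assembly"))
  if (cfg$per_sequence && length(asm$sequences) > 1L) {
    for (id in names(asm$sequences)) {
      sub <- assembly_record(asm$sequences[id])
      subaln <- subset_alignments(pas, asm, id)
      if (is.null(subaln)) next
      rows[[length(rows) + 1L]] <- cbind(
        compute_metrics(sub, subaln, params = cfg$params, id = id),
        granularity = "sequence")
    }
  }
  metrics <- do.call(rbind, rows)

  if (cfg$mode == "metrics") return(list(metrics = metrics))
  model <- load_model(cfg$model_dir)
  scores <- data.frame(id = metrics$id, granularity = metrics$granularity,
                       score = predict(model, metrics))
  list(metrics = metrics, scores = scores)
}

# restrict an alignment set to one target sequence (links to other
# sequences are lost by construction; cross-sequence pairs become orphans)
subset_alignments <- function(pas, asm, id) {
  ti <- match(id, names(asm$sequences))
  aln <- pas$alignments[pas$alignments$tid == ti, , drop = FALSE]
  if (nrow(aln) == 0L) return(NULL)
  aln$tid <- 1L
  sub <- assembly_record(asm$sequences[id])
  build_alignment_set(sub, aln,
                      read_depth = pas$read_depth[id],
                      perfect_depth = pas$perfect_depth[id],
                      n_reads = nrow(aln),
                      insert_stats = pas$insert_stats)
}

#' Full training workflow
#'
#' Validates the table against the 13-metric schema, runs the feature
#' selection cascade, splits the data, trains every model family with its
#' CV protocol on the identical split, evaluates each on the held-out
#' test set, selects the lowest-RMSE family, and refits it on the full
#' table.
#'
#' @param t metrics table with a `score` column.
#' @param families model families to compare.
#' @param train_fraction train split fraction.
#' @param seed integer seed (split + every fit).
#' @param features optional fixed feature set; default runs
#'   [select_features()].
#' @return list with `feature_report`, `split`, `results` (per-family
#'   RMSE/R^2 data.frame), `best_family`, `final_model`.
#' @export
train_workflow <- function(t, families = MODEL_FAMILIES, train_fraction = 0.8,
                           seed = 1L, features = NULL) {
  validate_metrics_table(t)
  if (nrow(t) < 5L) stop("need at least 5 rows")
  report <- NULL
  if (is.null(features)) {
    report <- select_features(t, seed = seed)
    features <- report$final
  }
  sp <- split_data(t, train_fraction = train_fraction, seed = seed)
  evals <- list()
  for (fam in families) {
    model <- train_model(sp$train, family = fam, features = features, seed = seed)
    evals[[fam]] <- evaluate(model, sp$test)
  }
  results <- data.frame(
    family = names(evals),
    rmse = vapply(evals, `[[`, 0, "rmse"),
    r_squared = vapply(evals, `[[`, 0, "r_squared"),
    r_squared_ss = vapply(evals, `[[`, 0, "r_squared_ss"),
    row.names = NULL)
  best <- select_best(evals)
  final <- train_model(t, family = best, features = features, seed = seed)
  list(feature_report = report, split = sp, results = results,
       best_family = best, final_model = final)
}

#' Load a metrics table from CSV
#'
#' @param path CSV with the 13 metric columns and a score column.
#' @param target target column name (renamed to `score`).
#' @return validated data.frame.
#' @export
read_metrics_csv <- function(path, target = "score") {
  if (!file.exists(path)) stop("file not found: ", path)
  t <- utils::read.csv(path, check.names = FALSE)
  if (!target %in% colnames(t) && "quality_score" %in% colnames(t)) {
    target <- "quality_score"
  }
  if (target != "score") {
    colnames(t)[colnames(t) == target] <- "score"
  }
  validate_metrics_table(t)
  t
}

#' The packaged mammalian training table
#'
#' The published 416-instance mammalian training table (chromosome metric
#' vectors with reference-based quality scores) is distributed as
#' supplementary data alongside the original study and is not redistributed
#' inside this package. Place the CSV at the returned search path, or pass
#' an explicit `path`, to reproduce the published feature selection and
#' model comparison.
#'
#' @param path explicit CSV path; default searches
#'   `system.file("extdata", "mammalian_training_416.csv")` and the
#'   `ASMQUAL_TRAINING_TABLE` R option.
#' @return validated 416-row metrics table.
#' @export
packaged_training_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mammalian_training_416.csv",
                        package = "asmqual")
    if (!nzchar(path)) path <- getOption("ASMQUAL_TRAINING_TABLE", "")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("the published 416-instance mammalian training table is not ",
         "bundled with this package; supply its CSV via `path` or the ",
         "ASMQUAL_TRAINING_TABLE option")
  }
  read_metrics_csv(path)
}
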