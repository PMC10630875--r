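#' Default pipeline configuration
#'
#' Houses every numeric threshold of the pipeline: minimum exclusive-intron
#' length 300 nt; 20 nt 5'SS and 250 nt 3'SS fragments; 12 nt UMI on mate 1;
#' minimum retained segment 20 nt; at most 5 mismatches, 10% mismatch rate
#' and 3 nt single indel in the 3' alignment; at most 5% ambiguous bases per
#' read; same-strand exon subtraction.
#'
#' @param ... Named overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_intron_len = 300L,
    five_len = 20L,
    three_len = 250L,
    umi_len = 12L,
    min_segment = 20L,
    max_mismatches = 5L,
    max_mismatch_rate = 0.10,
    max_indel = 3L,
    max_n_frac = 0.05,
    subtract_strand = "same",
    scoring = default_scoring(),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' JSON (always) or YAML (when the yaml package is installed), selected by
#' file extension. Fields present in the file override the defaults;
#' unknown fields are a configuration error.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the yaml package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(default_config, vals)
}

#' Write the resolved configuration as JSON
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline on a samplesheet
#'
#' Equivalent to running build-index, detect and quantify manually: builds
#' the splice-site fragment database, detects lariat reads in every sample,
#' summarizes lariats-per-million, optionally compares two groups, and
#' writes a run manifest with input checksums and per-stage read counts.
#'
#' @param gtf_path,genome Annotation and genome FASTA.
#' @param samplesheet data.table/data.frame with columns `sample_id`,
#'   `group`, `fastq_r1`, `fastq_r2` and optionally `total_reads` (library
#'   denominator; when absent the unmapped-read input count is used with a
#'   warning).
#' @param out_dir Output directory; per-sample results go to
#'   `<out_dir>/<sample_id>/`.
#' @param config A [default_config()].
#' @param group_a,group_b Optional group labels for [compare_groups()].
#' @return list with `db`, `detections` (per sample), `summary`,
#'   `comparison` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(gtf_path, genome, samplesheet, out_dir,
                         config = default_config(),
                         group_a = NULL, group_b = NULL) {
  samplesheet <- as.data.table(samplesheet)
  need <- c("sample_id", "group", "fastq_r1", "fastq_r2")
  miss <- setdiff(need, names(samplesheet))
  if (length(miss)) {
    stop("samplesheet lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.json"))

  db <- build_intron_index(gtf_path, genome,
                           min_intron_len = config$min_intron_len,
                           subtract_strand = config$subtract_strand,
                           out_dir = file.path(out_dir, "index"),
                           five_len = config$five_len,
                           three_len = config$three_len)
  detections <- list()
  summaries <- list()
  stage_tab <- list()
  for (i in seq_len(nrow(samplesheet))) {
    row <- samplesheet[i]
    reads <- read_sample_fastq(row$fastq_r1, row$fastq_r2, row$sample_id)
    qc <- filter_ambiguous(reads, max_n_frac = config$max_n_frac)
    det <- detect_sample(qc$kept, db, params = config)
    sdir <- file.path(out_dir, row$sample_id)
    write_detection(det, sdir)
    fwrite(qc$discarded, file.path(sdir, "qc_discarded.tsv"), sep = "\t")
    total <- if ("total_reads" %in% names(row) && !is.na(row$total_reads)) {
      as.numeric(row$total_reads)
    } else {
      warning("sample ", row$sample_id, ": total_reads not supplied; using ",
              "the unmapped-read input count as the per-million denominator",
              call. = FALSE)
      nrow(reads)
    }
    detections[[row$sample_id]] <- det
    summaries[[i]] <- summarize_sample(det$calls, total, row$sample_id,
                                       row$group)
    stage_tab[[i]] <- data.table(
      sample_id = row$sample_id,
      stage = c("input", "post_qc", names(det$stage_counts)[-1]),
      count = c(nrow(reads), nrow(qc$kept),
                unname(det$stage_counts[-1])))
  }
  summary <- rbindlist(summaries)
  fwrite(summary, file.path(out_dir, "summary.tsv"), sep = "\t")
  comparison <- NULL
  if (!is.null(group_a) && !is.null(group_b)) {
    comparison <- compare_groups(summary, group_a, group_b)
    fwrite(comparison, file.path(out_dir, "comparison.tsv"), sep = "\t")
  }
  manifest <- list(
    tool = "lariatrace",
    version = as.character(packageVersion("lariatrace")),
    inputs = list(
      gtf = unname(tools::md5sum(gtf_path)),
      genome = if (is.character(genome)) unname(tools::md5sum(genome)) else "in-memory",
      fastq = setNames(
        lapply(seq_len(nrow(samplesheet)), function(i) {
          list(r1 = unname(tools::md5sum(samplesheet$fastq_r1[i])),
               r2 = unname(tools::md5sum(samplesheet$fastq_r2[i])))
        }), samplesheet$sample_id)),
    stage_counts = rbindlist(stage_tab))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  list(db = db, detections = detections, summary = summary,
       comparison = comparison, manifest = manifest)
}
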