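#' Pipeline parameters
#'
#' One object holding every stage's thresholds; the defaults are the
#' pipeline's published operating point (overlap 25 bp / Phred 20 /
#' 2% overlap mismatches and the fragment length windows at merging,
#' 99% clustering identity, 98% identity / 25 bp / <= 2 mismatches at
#' the HSP screen, 80 bp / 2% at assembly, and the strict >10%
#' abundance rule at calling).
#'
#' @param merge a [merge_config()].
#' @param cluster_identity greedy clustering identity threshold.
#' @param chimera_min_parent_fold,chimera_min_div,chimera_min_score
#'   chimera screen parameters (see [detect_chimeras()]).
#' @param hsp_min_identity,hsp_min_len,hsp_max_mismatch HSP screen
#'   thresholds (see [screen_pair()]).
#' @param assembly_min_overlap,assembly_max_mismatch_frac assembly
#'   thresholds (see [assemble_pair()]).
#' @param min_frac strict abundance fraction for barcode calling.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(merge = merge_config(),
                            cluster_identity = 0.99,
                            chimera_min_parent_fold = 2,
                            chimera_min_div = 0.008,
                            chimera_min_score = 0.28,
                            hsp_min_identity = 0.98,
                            hsp_min_len = 25L,
                            hsp_max_mismatch = 2L,
                            assembly_min_overlap = 80L,
                            assembly_max_mismatch_frac = 0.02,
                            min_frac = 0.10) {
  structure(list(merge = merge,
                 cluster_identity = cluster_identity,
                 chimera_min_parent_fold = chimera_min_parent_fold,
                 chimera_min_div = chimera_min_div,
                 chimera_min_score = chimera_min_score,
                 hsp_min_identity = hsp_min_identity,
                 hsp_min_len = hsp_min_len,
                 hsp_max_mismatch = hsp_max_mismatch,
                 assembly_min_overlap = assembly_min_overlap,
                 assembly_max_mismatch_frac = assembly_max_mismatch_frac,
                 min_frac = min_frac),
            class = "pipeline_config")
}

#' Run the full barcode-reconstruction pipeline
#'
#' Executes merge -> quality gate -> length gate -> demultiplex ->
#' dereplicate -> chimera screen -> cluster -> fragment pairing ->
#' barcode calling on a table of raw read pairs, keeping per-stage
#' read accounting. Optionally labels calls against a reference set.
#'
#' @param reads a data frame of read pairs with columns `plate`,
#'   `fragment` (the pool's nominal fragment), `id`, `fwd_seq`,
#'   `fwd_qual`, `rev_seq`, `rev_qual` -- the `reads` element of a
#'   [simulate_reads()] result has this shape.
#' @param mapping a mapping tibble (see [read_mapping()]).
#' @param primers a [primer_set()].
#' @param cfg a [pipeline_config()].
#' @param refdb optional reference tibble (`label`, `sequence`) for
#'   best-hit identification of called barcodes.
#' @return an object of class `duobar_run`: a list with `calls`,
#'   `barcodes` (assembled), `clusters`, `uniques`, `demux`,
#'   `stage_report`, `cfg`. Use [tidy()], [glance()] and
#'   [ggplot2::autoplot()] on it.
#' @export
run_pipeline <- function(reads, mapping, primers = primer_set(),
                         cfg = pipeline_config(), refdb = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  reads <- tibble::as_tibble(reads)
  stages <- list()
  log_stage <- function(stage, n_in, n_out, unit = "reads") {
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out,
      n_dropped = n_in - n_out, unit = unit)
  }

  n0 <- nrow(reads)
  merged <- merge_pairs(reads, cfg$merge)
  log_stage("merge", n0, sum(merged$merged))
  merged <- merged[merged$merged, , drop = FALSE]

  merged <- quality_gate(merged, cfg$merge)
  log_stage("quality_gate", nrow(merged), sum(merged$pass_quality))
  merged <- merged[merged$pass_quality, , drop = FALSE]

  merged <- length_gate(merged, cfg$merge)
  log_stage("length_gate", nrow(merged), sum(merged$pass_length))
  merged <- merged[merged$pass_length, , drop = FALSE]

  demux <- assign_wells(merged, mapping, primers)
  log_stage("demultiplex", nrow(demux), sum(demux$assigned))
  demux <- demux[demux$assigned, , drop = FALSE]

  uniques <- dereplicate(demux, col = "insert")
  log_stage("dereplicate", sum(uniques$count), sum(uniques$count))

  uniques <- detect_chimeras(uniques,
                             min_parent_fold = cfg$chimera_min_parent_fold,
                             min_div = cfg$chimera_min_div,
                             min_score = cfg$chimera_min_score)
  log_stage("chimera_filter", sum(uniques$count),
            sum(uniques$count[!uniques$chimera]))

  clusters <- greedy_cluster(uniques, identity = cfg$cluster_identity)
  log_stage("cluster", sum(uniques$count[!uniques$chimera]),
            sum(clusters$size))

  barcodes <- pair_specimens(clusters,
                             min_identity = cfg$hsp_min_identity,
                             min_len = cfg$hsp_min_len,
                             max_mismatch = cfg$hsp_max_mismatch,
                             min_overlap = cfg$assembly_min_overlap,
                             max_mismatch_frac = cfg$assembly_max_mismatch_frac)
  log_stage("pair_fragments",
            length(unique(clusters$specimen)),
            length(unique(barcodes$specimen)), unit = "specimens")

  all_specimens <- unique(paste(mapping$plate, mapping$well, sep = ":"))
  calls <- call_barcodes(barcodes, min_frac = cfg$min_frac,
                         specimens = all_specimens)
  log_stage("call_barcodes", length(all_specimens),
            sum(tapply(calls$status, calls$specimen,
                       function(s) s[1] != "none")),
            unit = "specimens")
  if (!is.null(refdb)) calls <- identify_calls(calls, refdb)

  structure(list(calls = calls, barcodes = barcodes, clusters = clusters,
                 uniques = uniques, demux = demux,
                 stage_report = dplyr::bind_rows(stages), cfg = cfg),
            class = "duobar_run")
}

#' @export
print.duobar_run <- function(x, ...) {
  g <- glance(x)
  cat("<duobar_run>\n")
  cat(sprintf("  read pairs in:      %d\n", g$n_reads_in))
  cat(sprintf("  merged:             %d\n", g$n_merged))
  cat(sprintf("  assigned to wells:  %d\n", g$n_assigned))
  cat(sprintf("  specimens:          %d (single %d / multiple %d / none %d)\n",
              g$n_specimens, g$n_single, g$n_multiple, g$n_none))
  invisible(x)
}

#' Tidy methods for pipeline runs
#'
#' `tidy()` returns the per-specimen calls table; `glance()` a one-row
#' run summary.
#'
#' @param x a `duobar_run`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.duobar_run <- function(x, ...) x$calls

#' @rdname tidy.duobar_run
#' @export
glance.duobar_run <- function(x, ...) {
  sr <- x$stage_report
  status <- tapply(x$calls$status, x$calls$specimen, function(s) s[1])
  tibble::tibble(
    n_reads_in = sr$n_in[sr$stage == "merge"],
    n_merged = sr$n_out[sr$stage == "merge"],
    n_assigned = sr$n_out[sr$stage == "demultiplex"],
    n_specimens = length(status),
    n_single = sum(status == "single"),
    n_multiple = sum(status == "multiple"),
    n_none = sum(status == "none"),
    n_barcodes = sum(!is.na(x$calls$sequence)),
    mean_support = mean(x$barcodes$support)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-stage read retention
#'
#' A funnel of reads (or specimens) in and out of every pipeline
#' stage.
#'
#' @param object a `duobar_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.duobar_run <- function(object, ...) {
  plot_stage_report(object$stage_report)
}

#' @rdname autoplot.duobar_run
#' @param report a stage-report tibble (`stage`, `n_in`, `n_out`,
#'   `n_dropped`, `unit`).
#' @export
plot_stage_report <- function(report, ...) {
  df <- tidyr::pivot_longer(report, c("n_out", "n_dropped"),
                            names_to = "fate", values_to = "n")
  df$fate <- ifelse(df$fate == "n_out", "retained", "dropped")
  df$stage <- factor(df$stage, levels = rev(unique(report$stage)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n,
                                   fill = .data$fate)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~unit, scales = "free") +
    ggplot2::labs(x = NULL, y = "count", fill = NULL,
                  title = "Pipeline stage retention") +
    ggplot2::theme_minimal()
}

#' Plot per-specimen call status
#'
#' Bar chart of specimens by call status (none / single / multiple),
#' optionally split by plate.
#'
#' @param calls a calls tibble from [call_barcodes()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_call_status <- function(calls, ...) {
  per <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(calls),
                                          .data$specimen),
                          status = .data$status[1], .groups = "drop")
  per$plate <- sub(":.*$", "", per$specimen)
  ggplot2::ggplot(per, ggplot2::aes(x = .data$plate,
                                    fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "plate", y = "specimens", fill = "status",
                  title = "Barcode calls per specimen") +
    ggplot2::theme_minimal()
}

#' Plot Sanger/HTS pairwise distances
#'
#' Dot plot of per-specimen p-distances between the Sanger sequence
#' and each ranked HTS sequence, with the concordance threshold drawn
#' as a dashed line.
#'
#' @param concordance result of [sanger_concordance()].
#' @param threshold the threshold to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_concordance <- function(concordance, threshold = 0.02, ...) {
  df <- concordance$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$specimen, y = .data$p_dist,
                                   shape = factor(.data$hts_rank))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "specimen", y = "p-distance to Sanger",
                  shape = "HTS rank",
                  title = "Sanger vs HTS pairwise distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
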