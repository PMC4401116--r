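#' Simulation parameters
#'
#' Defines the study design the simulator emulates: 96-well plates of
#' specimens, each with one true 658-nt barcode amplified as two
#' overlapping fragments (FC spanning barcode positions 1-307, BR
#' spanning 226-658, so the fragments share 82 nt), dual 5-mer MIDs and
#' flanking primers on every amplicon, and 300-nt paired-end reads.
#' The spans are the unique geometry compatible with a 658-nt barcode,
#' an 82-nt fragment overlap and merged amplicon reads inside the
#' 300-400 (FC) / 400-500 (BR) length windows once 10 nt of MIDs and
#' ~40 nt of primers are added.
#'
#' Noise model: substitution errors uniform over the three alternative
#' bases at `per_base_error` per sequenced base; Phred scores drawn
#' from a truncated normal. Cross-well contamination affects a fraction
#' `contaminant_rate` of wells, where a second specimen's barcode
#' contributes `contaminant_frac` of reads. Endosymbiont (Wolbachia-like)
#' co-amplicons behave analogously. In wells carrying more than one
#' template, each amplicon is, with probability `chimera_rate`, replaced
#' by a two-parent PCR chimera with a crossover drawn from the central
#' half of the fragment.
#'
#' @param n_plates number of plates.
#' @param wells_per_plate occupied wells per plate (<= 96).
#' @param barcode_length true barcode length (nt).
#' @param fc_span,br_span 1-based inclusive barcode coordinates of the
#'   two fragments.
#' @param read_length sequenced read length (nt).
#' @param coverage read pairs per fragment per specimen.
#' @param per_base_error substitution probability per sequenced base.
#' @param quality_mean,quality_sd Phred score distribution.
#' @param contaminant_rate fraction of wells carrying a contaminant.
#' @param contaminant_frac read fraction of the contaminant within an
#'   affected well.
#' @param chimera_rate per-amplicon chimera probability in
#'   multi-template wells.
#' @param endosymbiont_rate fraction of wells with an endosymbiont
#'   co-amplicon.
#' @param endosymbiont_frac read fraction of the endosymbiont within an
#'   affected well.
#' @param seed integer seed; identical configs give byte-identical
#'   output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_plates = 1L, wells_per_plate = 96L,
                       barcode_length = 658L,
                       fc_span = c(1L, 307L), br_span = c(226L, 658L),
                       read_length = 300L, coverage = 50L,
                       per_base_error = 0.001,
                       quality_mean = 35, quality_sd = 3,
                       contaminant_rate = 0.05, contaminant_frac = 0.3,
                       chimera_rate = 0.02,
                       endosymbiont_rate = 0.05, endosymbiont_frac = 0.25,
                       seed = 1L) {
  stopifnot(wells_per_plate >= 1L, wells_per_plate <= 96L,
            fc_span[1] == 1L, br_span[2] == barcode_length,
            fc_span[2] > br_span[1])
  cfg <- list(n_plates = as.integer(n_plates),
              wells_per_plate = as.integer(wells_per_plate),
              barcode_length = as.integer(barcode_length),
              fc_span = as.integer(fc_span), br_span = as.integer(br_span),
              read_length = as.integer(read_length),
              coverage = as.integer(coverage),
              per_base_error = per_base_error,
              quality_mean = quality_mean, quality_sd = quality_sd,
              contaminant_rate = contaminant_rate,
              contaminant_frac = contaminant_frac,
              chimera_rate = chimera_rate,
              endosymbiont_rate = endosymbiont_rate,
              endosymbiont_frac = endosymbiont_frac,
              seed = as.integer(seed))
  cfg$overlap <- cfg$fc_span[2] - cfg$br_span[1] + 1L
  structure(cfg, class = "sim_config")
}

#' Generate reference barcode sequences
#'
#' Random sequences of fixed length with every pairwise uncorrected
#' distance at least `min_div` (rejection sampling; unconstrained
#' random pairs sit near 75% divergence, so rejections are rare).
#'
#' @param n number of references.
#' @param length sequence length (nt).
#' @param min_div minimum pairwise p-distance.
#' @param seed integer seed.
#' @param max_tries rejection-sampling attempts per sequence.
#' @return a tibble with columns `label`, `sequence`.
#' @export
generate_references <- function(n, length = 658L, min_div = 0.05,
                                seed = 1L, max_tries = 50L) {
  stopifnot(n >= 1L)
  withr::with_seed(seed, {
    seqs <- character(0)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                      collapse = "")
        if (!base::length(seqs) ||
            all(vapply(seqs, function(s) p_distance(s, cand),
                       numeric(1)) >= min_div)) {
          seqs <- c(seqs, cand); ok <- TRUE; break
        }
      }
      if (!ok) {
        stop("could not satisfy min_div after ", max_tries, " tries",
             call. = FALSE)
      }
    }
    tibble::tibble(label = sprintf("taxon_%03d", seq_len(n)),
                   sequence = seqs)
  })
}

# Synthetic endosymbiont template, labelled as such. Random sequences
# are far (~75%) from any reference; the >= 15% divergence requirement
# is asserted, not hoped for.
endosymbiont_reference <- function(refs, length = 658L, seed = 1L) {
  withr::with_seed(seed + 7919L, {
    repeat {
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      if (all(vapply(refs$sequence, function(s) p_distance(s, cand),
                     numeric(1)) >= 0.15)) break
    }
    tibble::tibble(label = "Wolbachia-like_synthetic", sequence = cand)
  })
}

# Realize degenerate positions of a primer into n concrete strings.
realize_primer <- function(primer, n) {
  sets <- iupac_sets()
  pch <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  cols <- lapply(pch, function(ch) {
    s <- sets[[ch]]
    if (length(s) == 1L) rep(s, n) else sample(s, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

# Apply iid substitution errors to a batch of equal-length sequences.
add_errors <- function(seqs, p) {
  if (p <= 0 || !length(seqs)) return(seqs)
  L <- nchar(seqs[1])
  n <- length(seqs)
  ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  hit <- which(stats::runif(n * L) < p)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    cur <- ch[hit]
    pick <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- vapply(seq_along(hit), function(i) {
      a <- alt[[cur[i]]]
      if (is.null(a)) cur[i] else a[pick[i]]
    }, character(1))
  }
  apply(ch, 1L, paste, collapse = "")
}

# Phred+33 quality strings from a truncated normal.
draw_quals <- function(n, L, mean, sd) {
  q <- matrix(pmin(40L, pmax(2L, round(stats::rnorm(n * L, mean, sd)))),
              nrow = n)
  vapply(seq_len(n), function(i) intToUtf8(q[i, ] + 33L), character(1))
}

#' Simulate plates of dual-indexed paired-end amplicon reads
#'
#' Builds, for every occupied well, the FC and BR amplicons
#' (`MID + primer + fragment + revcomp(primer) + revcomp(MID)`), mixes
#' in contaminant, endosymbiont and chimeric amplicons per the
#' configured rates, sequences each amplicon as a 300-nt read pair with
#' substitution errors and drawn qualities, and returns the reads
#' together with a complete ground-truth table.
#'
#' @param cfg a [sim_config()].
#' @param refs optional reference tibble (`label`, `sequence`); by
#'   default one reference per specimen is generated.
#' @param mapping optional mapping tibble; defaults to
#'   [default_mapping()] for the configured plates.
#' @param primers a [primer_set()].
#' @return a list of class `duobar_sim` with elements `reads` (tibble:
#'   `plate`, `fragment`, `id`, `fwd_seq`, `fwd_qual`, `rev_seq`,
#'   `rev_qual`), `truth` (list of `specimens` and `reads` tibbles),
#'   `mapping`, `refs` (references plus the endosymbiont, usable as a
#'   reference database), `primers`, `cfg`.
#' @export
simulate_reads <- function(cfg = sim_config(), refs = NULL, mapping = NULL,
                           primers = primer_set()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(mapping)) {
    mapping <- default_mapping(cfg$n_plates, cfg$wells_per_plate)
  } else {
    mapping <- validate_mapping(mapping)
  }
  n_spec <- cfg$n_plates * cfg$wells_per_plate
  if (is.null(refs)) {
    refs <- generate_references(n_spec, cfg$barcode_length, 0.05, cfg$seed)
  }
  endo <- endosymbiont_reference(refs, cfg$barcode_length, cfg$seed)

  withr::with_seed(cfg$seed, {
    wells <- unique(mapping[c("plate", "well")])
    ns <- nrow(wells)
    spec <- tibble::tibble(
      plate = wells$plate, well = wells$well,
      specimen = paste(wells$plate, wells$well, sep = ":"),
      label = refs$label[(seq_len(ns) - 1L) %% nrow(refs) + 1L],
      barcode = refs$sequence[(seq_len(ns) - 1L) %% nrow(refs) + 1L]
    )
    spec$contaminated <- stats::runif(ns) < cfg$contaminant_rate
    don <- vapply(seq_len(ns), function(i) {
      if (!spec$contaminated[i] || ns < 2L) return(NA_integer_)
      sample(setdiff(seq_len(ns), i), 1L)
    }, integer(1))
    spec$contaminant_label <- ifelse(is.na(don), NA_character_,
                                     spec$label[don])
    spec$contaminant_barcode <- ifelse(is.na(don), NA_character_,
                                       spec$barcode[don])
    spec$contaminated <- !is.na(don)
    spec$endosymbiont <- stats::runif(ns) < cfg$endosymbiont_rate

    span <- list(FC = cfg$fc_span, BR = cfg$br_span)
    read_rows <- list(); truth_rows <- list()
    for (i in seq_len(ns)) {
      templates <- tibble::tibble(label = spec$label[i],
                                  barcode = spec$barcode[i],
                                  origin = "true", frac = 1)
      if (spec$contaminated[i]) {
        templates <- dplyr::bind_rows(templates, tibble::tibble(
          label = spec$contaminant_label[i],
          barcode = spec$contaminant_barcode[i],
          origin = "contaminant", frac = cfg$contaminant_frac))
      }
      if (spec$endosymbiont[i]) {
        templates <- dplyr::bind_rows(templates, tibble::tibble(
          label = endo$label, barcode = endo$sequence,
          origin = "endosymbiont", frac = cfg$endosymbiont_frac))
      }
      templates$frac[1] <- 1 - sum(templates$frac[-1])
      for (fg in c("FC", "BR")) {
        sp_rng <- span[[fg]]
        frag_len <- sp_rng[2] - sp_rng[1] + 1L
        nmap <- mapping[mapping$plate == spec$plate[i] &
                          mapping$well == spec$well[i] &
                          mapping$fragment == fg, ]
        if (!nrow(nmap)) {
          stop(sprintf("mapping has no %s entry for %s", fg,
                       spec$specimen[i]), call. = FALSE)
        }
        fmid <- nmap$forward_mid[1]; rmid <- nmap$reverse_mid[1]
        fp <- if (fg == "FC") primers$fc_forward else primers$br_forward
        rp <- if (fg == "FC") primers$fc_reverse else primers$br_reverse
        cov <- cfg$coverage
        tmpl_idx <- sample.int(nrow(templates), cov, replace = TRUE,
                               prob = templates$frac)
        frag <- substr(templates$barcode[tmpl_idx], sp_rng[1], sp_rng[2])
        origin <- templates$origin[tmpl_idx]
        tlabel <- templates$label[tmpl_idx]
        parent2 <- rep(NA_character_, cov)
        parent_div <- rep(NA_real_, cov)
        brk <- rep(NA_integer_, cov)
        if (nrow(templates) >= 2L && cfg$chimera_rate > 0) {
          chim <- stats::runif(cov) < cfg$chimera_rate
          for (ci in which(chim)) {
            pr <- sample.int(nrow(templates), 2L)
            fa <- substr(templates$barcode[pr[1]], sp_rng[1], sp_rng[2])
            fb <- substr(templates$barcode[pr[2]], sp_rng[1], sp_rng[2])
            k <- sample(seq(floor(frag_len * 0.25),
                            ceiling(frag_len * 0.75)), 1L)
            frag[ci] <- paste0(substr(fa, 1L, k),
                               substr(fb, k + 1L, frag_len))
            origin[ci] <- "chimera"
            tlabel[ci] <- templates$label[pr[1]]
            parent2[ci] <- templates$label[pr[2]]
            parent_div[ci] <- p_distance(fa, fb)
            brk[ci] <- k
          }
        }
        amp <- paste0(fmid, realize_primer(fp, cov), frag,
                      revcomp(realize_primer(rp, cov)), revcomp(rmid))
        alen <- nchar(amp[1])
        rl <- min(cfg$read_length, alen)
        fwd <- substr(amp, 1L, rl)
        rev_ <- revcomp(substr(amp, alen - rl + 1L, alen))
        fwd <- add_errors(fwd, cfg$per_base_error)
        rev_ <- add_errors(rev_, cfg$per_base_error)
        ids <- sprintf("%s_%s_%s_%04d", spec$plate[i], spec$well[i], fg,
                       seq_len(cov))
        read_rows[[length(read_rows) + 1L]] <- tibble::tibble(
          plate = spec$plate[i], fragment = fg, id = ids,
          fwd_seq = fwd, fwd_qual = draw_quals(cov, rl, cfg$quality_mean,
                                               cfg$quality_sd),
          rev_seq = rev_, rev_qual = draw_quals(cov, rl, cfg$quality_mean,
                                                cfg$quality_sd))
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          id = ids, plate = spec$plate[i], well = spec$well[i],
          specimen = spec$specimen[i], fragment = fg,
          origin = origin, template_label = tlabel,
          chimera_parent2 = parent2, chimera_break = brk,
          parent_divergence = parent_div)
      }
    }
    structure(list(
      reads = dplyr::bind_rows(read_rows),
      truth = list(specimens = spec,
                   reads = dplyr::bind_rows(truth_rows)),
      mapping = mapping,
      refs = dplyr::bind_rows(refs, endo),
      primers = primers,
      cfg = cfg), class = "duobar_sim")
  })
}

#' Write a simulation to disk
#'
#' Emits per plate-and-fragment paired FASTQ (gzipped), the mapping
#' TSV, the ground-truth tables and the reference FASTA.
#'
#' @param sim a `duobar_sim` object from [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "duobar_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pl in unique(sim$reads$plate)) {
    for (fg in c("FC", "BR")) {
      rr <- sim$reads[sim$reads$plate == pl & sim$reads$fragment == fg, ]
      if (!nrow(rr)) next
      write_fastq(tibble::tibble(id = rr$id, sequence = rr$fwd_seq,
                                 quality = rr$fwd_qual),
                  file.path(dir, sprintf("%s_%s_R1.fastq.gz", pl, fg)))
      write_fastq(tibble::tibble(id = rr$id, sequence = rr$rev_seq,
                                 quality = rr$rev_qual),
                  file.path(dir, sprintf("%s_%s_R2.fastq.gz", pl, fg)))
    }
  }
  write_mapping(sim$mapping, file.path(dir, "mapping.tsv"))
  utils::write.table(sim$truth$specimens,
                     file.path(dir, "truth_specimens.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$reads, file.path(dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(tibble::tibble(id = sim$refs$label,
                             sequence = sim$refs$sequence),
              file.path(dir, "references.fasta"))
  invisible(dir)
}
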