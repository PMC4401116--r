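#' Merging and filtering parameters
#'
#' Defaults are the pipeline's published operating point: minimum
#' overlap 25 bp, mean read quality Phred 20, at most 2% mismatches in
#' the overlap, and fragment length windows of 300-400 bp (FC) and
#' 400-500 bp (BR) applied to the merged amplicon read.
#'
#' @param min_overlap smallest acceptable forward/reverse overlap (bp).
#' @param min_mean_phred smallest acceptable mean Phred score of a
#'   merged read (inclusive).
#' @param max_overlap_mismatch_frac largest acceptable mismatch fraction
#'   inside the overlap.
#' @param fc_length,br_length closed length intervals `c(min, max)` for
#'   the merged FC and BR reads.
#' @return a list of class `merge_config`.
#' @export
merge_config <- function(min_overlap = 25L,
                         min_mean_phred = 20,
                         max_overlap_mismatch_frac = 0.02,
                         fc_length = c(300L, 400L),
                         br_length = c(400L, 500L)) {
  stopifnot(min_overlap > 0, length(fc_length) == 2, length(br_length) == 2,
            fc_length[1] <= fc_length[2], br_length[1] <= br_length[2],
            max_overlap_mismatch_frac >= 0, max_overlap_mismatch_frac <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 min_mean_phred = min_mean_phred,
                 max_overlap_mismatch_frac = max_overlap_mismatch_frac,
                 fc_length = as.integer(fc_length),
                 br_length = as.integer(br_length)),
            class = "merge_config")
}

# Core single-pair merge. Scans ungapped overlaps between the forward
# read and the reverse-complemented reverse read from longest to
# shortest >= min_overlap and accepts the first whose mismatch fraction
# is within bounds. Returns NULL when no overlap qualifies.
merge_one <- function(fs, fq, rs, rq, min_overlap, max_mm_frac) {
  r_seq <- revcomp(rs)
  fb <- charToRaw(fs); rb <- charToRaw(r_seq)
  fqv <- phred_to_int(fq)[[1]]
  rqv <- rev(phred_to_int(rq)[[1]])
  nf <- length(fb); nr <- length(rb)
  if (min(nf, nr) < min_overlap) return(NULL)
  for (L in seq(min(nf, nr), min_overlap, by = -1L)) {
    fi <- (nf - L + 1L):nf
    ri <- 1L:L
    neq <- fb[fi] != rb[ri]
    mm <- sum(neq)
    if (mm <= max_mm_frac * L) {
      # consensus across the overlap: agreeing columns take max quality;
      # disagreements take the higher-quality base with quality |q1 - q2|
      ov_base <- fb[fi]
      ov_q <- pmax(fqv[fi], rqv[ri])
      if (mm > 0L) {
        w <- which(neq)
        take_r <- rqv[ri][w] > fqv[fi][w]
        ov_base[w[take_r]] <- rb[ri][w[take_r]]
        ov_q[w] <- abs(fqv[fi][w] - rqv[ri][w])
      }
      seq_out <- paste0(substr(fs, 1L, nf - L), rawToChar(ov_base),
                        substr(r_seq, L + 1L, nr))
      qual_out <- int_to_phred(list(c(fqv[seq_len(nf - L)], ov_q,
                                      rqv[seq(L + 1L, length.out = nr - L)])))
      return(list(sequence = seq_out, quality = qual_out,
                  overlap_length = L, overlap_mismatches = mm))
    }
  }
  NULL
}

#' Merge paired-end reads by overlap
#'
#' For each read pair, scans all ungapped overlaps between the forward
#' read and the reverse-complemented reverse read, longest first, and
#' accepts the first overlap of at least `min_overlap` bases whose
#' mismatch fraction does not exceed `max_overlap_mismatch_frac`.
#' The consensus takes the higher-quality base at disagreeing columns
#' (quality `|q1 - q2|`) and the maximum quality at agreeing columns.
#'
#' @param pairs a data frame with columns `fwd_seq`, `fwd_qual`,
#'   `rev_seq`, `rev_qual`; any other columns (ids, plate, fragment)
#'   are carried through.
#' @param cfg a [merge_config()].
#' @return the input tibble plus columns `merged` (logical),
#'   `sequence`, `quality`, `overlap_length`, `overlap_mismatches`
#'   (NA where unmerged). The merged length always equals
#'   `nchar(fwd) + nchar(rev) - overlap_length`.
#' @export
merge_pairs <- function(pairs, cfg = merge_config()) {
  stopifnot(inherits(cfg, "merge_config"),
            all(c("fwd_seq", "fwd_qual", "rev_seq", "rev_qual") %in%
                  names(pairs)))
  n <- nrow(pairs)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[i] <- list(merge_one(pairs$fwd_seq[i], pairs$fwd_qual[i],
                             pairs$rev_seq[i], pairs$rev_qual[i],
                             cfg$min_overlap, cfg$max_overlap_mismatch_frac))
  }
  ok <- !vapply(res, is.null, logical(1))
  out <- tibble::as_tibble(pairs)
  out$merged <- ok
  out$sequence <- NA_character_
  out$quality <- NA_character_
  out$overlap_length <- NA_integer_
  out$overlap_mismatches <- NA_integer_
  if (any(ok)) {
    out$sequence[ok] <- vapply(res[ok], `[[`, character(1), "sequence")
    out$quality[ok] <- vapply(res[ok], `[[`, character(1), "quality")
    out$overlap_length[ok] <- vapply(res[ok], `[[`, integer(1),
                                     "overlap_length")
    out$overlap_mismatches[ok] <- vapply(res[ok], function(x)
      as.integer(x$overlap_mismatches), integer(1))
  }
  out
}

#' Mean-quality and fragment-length gates
#'
#' `quality_gate()` flags merged reads whose mean Phred score reaches
#' `min_mean_phred` (inclusive). `length_gate()` flags reads whose
#' length falls inside the closed interval for their fragment
#' (300-400 bp FC, 400-500 bp BR by default); it is applied to the raw
#' merged read, i.e. before index/primer trimming.
#'
#' @param x a data frame with a `quality` column (`quality_gate`) or
#'   `fragment` plus a sequence column (`length_gate`).
#' @param cfg a [merge_config()].
#' @param column which column's lengths to gate (default `"sequence"`).
#' @return the input tibble with a logical `pass_quality` /
#'   `pass_length` column added.
#' @export
quality_gate <- function(x, cfg = merge_config()) {
  stopifnot("quality" %in% names(x))
  out <- tibble::as_tibble(x)
  out$pass_quality <- !is.na(out$quality) &
    mean_phred(out$quality) >= cfg$min_mean_phred
  out
}

#' @rdname quality_gate
#' @export
length_gate <- function(x, cfg = merge_config(), column = "sequence") {
  stopifnot(all(c("fragment", column) %in% names(x)))
  out <- tibble::as_tibble(x)
  len <- nchar(out[[column]])
  lo <- ifelse(out$fragment == "FC", cfg$fc_length[1], cfg$br_length[1])
  hi <- ifelse(out$fragment == "FC", cfg$fc_length[2], cfg$br_length[2])
  out$pass_length <- !is.na(len) & len >= lo & len <= hi
  out
}
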