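# Best-scoring ungapped local segment between a and b, exhaustively over
# all diagonals. Score +1 match / -1 mismatch; ties resolved in favour
# of the first diagonal/segment encountered (deterministic).
best_hsp <- function(a, b) {
  ar <- charToRaw(a); br_ <- charToRaw(b)
  n <- length(ar); m <- length(br_)
  best <- list(score = -Inf, length = 0L, mismatches = 0L,
               fc_start = NA_integer_, br_start = NA_integer_)
  for (d in (-(n - 1L)):(m - 1L)) {
    i0 <- max(1L, 1L - d)            # a-coordinate where diagonal enters
    j0 <- i0 + d
    L <- min(n - i0, m - j0) + 1L
    if (L < 1L) next
    eq <- ar[i0:(i0 + L - 1L)] == br_[j0:(j0 + L - 1L)]
    cs <- cumsum(2L * eq - 1L)
    prev <- cummin(c(0L, cs[-L]))
    val <- cs - prev
    jbest <- which.max(val)
    if (val[jbest] > best$score) {
      pref <- c(0L, cs)[seq_len(jbest)]
      start <- which(pref == prev[jbest])[1]   # segment starts after this prefix
      seg <- start:jbest
      best <- list(score = val[jbest],
                   length = length(seg),
                   mismatches = sum(!eq[seg]),
                   fc_start = i0 + start - 1L,
                   br_start = j0 + start - 1L)
    }
  }
  best
}

#' Screen an FC/BR cluster pair for compatibility
#'
#' Finds the highest-scoring ungapped local segment pair (HSP) between
#' the FC centroid and the BR centroid, trying the BR centroid in both
#' orientations, and accepts the pair when the HSP reaches
#' `min_identity`, spans at least `min_len` bases, and carries at most
#' `max_mismatch` mismatches. The search is an exhaustive diagonal scan
#' (score +1/-1), so results are exact, not heuristic.
#'
#' @param fc,br centroid sequences (character scalars).
#' @param min_identity minimum HSP identity.
#' @param min_len minimum HSP length (bp).
#' @param max_mismatch maximum mismatches inside the HSP.
#' @return a one-row tibble with columns `length`, `identity`,
#'   `mismatches`, `fc_start`, `br_start`, `br_revcomp`, `accepted`.
#' @export
screen_pair <- function(fc, br, min_identity = 0.98, min_len = 25L,
                        max_mismatch = 2L) {
  stopifnot(nzchar(fc), nzchar(br))
  fwd <- best_hsp(fc, br)
  rev_ <- best_hsp(fc, revcomp(br))
  use_rc <- rev_$score > fwd$score
  h <- if (use_rc) rev_ else fwd
  id <- if (h$length > 0) (h$length - h$mismatches) / h$length else 0
  tibble::tibble(
    length = h$length, identity = id, mismatches = h$mismatches,
    fc_start = h$fc_start, br_start = h$br_start, br_revcomp = use_rc,
    accepted = h$length >= min_len & id >= min_identity &
      h$mismatches <= max_mismatch
  )
}

#' Assemble a full-length barcode from an FC/BR cluster pair
#'
#' Scans ungapped suffix(FC)/prefix(BR) overlaps, longest first, and
#' accepts the first of at least `min_overlap` bases whose mismatch
#' fraction is within `max_mismatch_frac`. At disagreeing overlap
#' columns the consensus takes the base from the larger cluster (ties
#' go to FC). The assembled length always equals
#' `nchar(fc) + nchar(br) - overlap_length`.
#'
#' @param fc,br centroid sequences, BR already in FC orientation.
#' @param fc_size,br_size cluster sizes (used for consensus and
#'   support).
#' @param min_overlap minimum overlap (bp).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap.
#' @return a one-row tibble (`sequence`, `overlap_length`,
#'   `overlap_mismatches`, `fc_size`, `br_size`, `support`), or a
#'   zero-row tibble when no overlap qualifies.
#' @export
assemble_pair <- function(fc, br, fc_size = 1, br_size = 1,
                          min_overlap = 80L, max_mismatch_frac = 0.02) {
  empty <- tibble::tibble(sequence = character(0),
                          overlap_length = integer(0),
                          overlap_mismatches = integer(0),
                          fc_size = numeric(0), br_size = numeric(0),
                          support = numeric(0))
  nf <- nchar(fc); nb <- nchar(br)
  if (min(nf, nb) < min_overlap) return(empty)
  fb <- charToRaw(fc); bb <- charToRaw(br)
  for (L in seq(min(nf, nb), min_overlap, by = -1L)) {
    fi <- (nf - L + 1L):nf
    bi <- 1L:L
    neq <- fb[fi] != bb[bi]
    mm <- sum(neq)
    if (mm <= max_mismatch_frac * L) {
      ov <- if (br_size > fc_size) bb[bi] else fb[fi]
      seq_out <- paste0(substr(fc, 1L, nf - L), rawToChar(ov),
                        substr(br, L + 1L, nb))
      return(tibble::tibble(sequence = seq_out, overlap_length = L,
                            overlap_mismatches = as.integer(mm),
                            fc_size = fc_size, br_size = br_size,
                            support = min(fc_size, br_size)))
    }
  }
  empty
}

#' Pair and assemble fragment clusters per specimen
#'
#' For each specimen, all FC x BR cluster pairs are screened with
#' [screen_pair()]; accepted pairs are assembled greedily in order of
#' descending `min(fc_size, br_size)` (ties by FC size, then centroid),
#' with each FC and each BR cluster used in at most one assembly.
#' Outputs are sorted by descending support within specimen.
#'
#' @param clusters a cluster tibble from [greedy_cluster()] containing
#'   both fragments.
#' @param min_identity,min_len,max_mismatch HSP screen thresholds (see
#'   [screen_pair()]).
#' @param min_overlap,max_mismatch_frac assembly thresholds (see
#'   [assemble_pair()]).
#' @return a tibble of assembled barcodes: `specimen`, `sequence`,
#'   `overlap_length`, `overlap_mismatches`, `fc_size`, `br_size`,
#'   `support`.
#' @export
pair_specimens <- function(clusters, min_identity = 0.98, min_len = 25L,
                           max_mismatch = 2L, min_overlap = 80L,
                           max_mismatch_frac = 0.02) {
  stopifnot(all(c("specimen", "fragment", "centroid", "size") %in%
                  names(clusters)))
  out <- list()
  for (sp in unique(clusters$specimen)) {
    fc <- clusters[clusters$specimen == sp & clusters$fragment == "FC", ]
    br <- clusters[clusters$specimen == sp & clusters$fragment == "BR", ]
    if (!nrow(fc) || !nrow(br)) next
    cand <- tidyr::expand_grid(fi = seq_len(nrow(fc)), bi = seq_len(nrow(br)))
    scr <- dplyr::bind_rows(lapply(seq_len(nrow(cand)), function(r) {
      screen_pair(fc$centroid[cand$fi[r]], br$centroid[cand$bi[r]],
                  min_identity, min_len, max_mismatch)
    }))
    cand <- dplyr::bind_cols(cand, scr)
    cand <- cand[cand$accepted, , drop = FALSE]
    if (!nrow(cand)) next
    cand$support <- pmin(fc$size[cand$fi], br$size[cand$bi])
    cand <- cand[order(-cand$support, -fc$size[cand$fi],
                       fc$centroid[cand$fi], br$centroid[cand$bi]), ]
    used_f <- used_b <- integer(0)
    for (r in seq_len(nrow(cand))) {
      fi <- cand$fi[r]; bi <- cand$bi[r]
      if (fi %in% used_f || bi %in% used_b) next
      brc <- br$centroid[bi]
      if (cand$br_revcomp[r]) brc <- revcomp(brc)
      asm <- assemble_pair(fc$centroid[fi], brc, fc$size[fi], br$size[bi],
                           min_overlap, max_mismatch_frac)
      if (!nrow(asm)) next
      asm$specimen <- sp
      out[[length(out) + 1L]] <- asm
      used_f <- c(used_f, fi); used_b <- c(used_b, bi)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(specimen = character(0), sequence = character(0),
                          overlap_length = integer(0),
                          overlap_mismatches = integer(0),
                          fc_size = numeric(0), br_size = numeric(0),
                          support = numeric(0)))
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::relocate(res, "specimen")
  dplyr::arrange(res, .data$specimen, dplyr::desc(.data$support))
}
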