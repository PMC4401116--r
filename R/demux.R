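#' Amplification primer set
#'
#' The two half-barcode amplicons are flanked by a conventional Folmer
#' primer on their outer end and an internal inosine-containing primer
#' on the shared-overlap end. The internal primers are fixed by the
#' assay design; the outer (Folmer-type) primers default to the
#' classical LCO1490/HCO2198 pair and may be replaced by the user.
#'
#' @param fc_forward forward primer of the FC (5') fragment.
#' @param fc_reverse internal reverse primer of the FC fragment.
#' @param br_forward internal forward primer of the BR (3') fragment.
#' @param br_reverse reverse primer of the BR fragment.
#' @return a list of class `primer_set`.
#' @export
primer_set <- function(fc_forward = "GGTCAACAAATCATAAAGATATTGG",
                       fc_reverse = "GGIGGRTAIACIGTTCAICC",
                       br_forward = "CCIGAYATRGCITTYCCICG",
                       br_reverse = "TAAACTTCAGGGTGACCAAAAAATCA") {
  p <- list(fc_forward = toupper(fc_forward), fc_reverse = toupper(fc_reverse),
            br_forward = toupper(br_forward), br_reverse = toupper(br_reverse))
  for (nm in names(p)) {
    if (!nzchar(p[[nm]])) stop(nm, " primer is empty", call. = FALSE)
    check_seq_chr(p[[nm]], nm)
  }
  structure(p, class = "primer_set")
}

#' Find a degenerate primer in a sequence window
#'
#' Scans `window` left to right for the leftmost occurrence of `primer`
#' with at most `max_mismatch` mismatching positions. IUPAC degeneracy
#' codes in the primer match their base sets; inosine (`I`) and `N`
#' match any base. An `N` in the window matches only primer `N`/`I`.
#'
#' @param primer degenerate primer string (IUPAC codes plus `I`).
#' @param window nucleotide string to scan, at least as long as the
#'   primer.
#' @param max_mismatch maximum tolerated mismatches.
#' @return the 1-based offset of the leftmost match, or `NA_integer_`
#'   when no offset qualifies.
#' @examples
#' match_degenerate("CCIGAYATRGCITTYCCICG", "CCAGATATGGCTTTTCCACG", 0)
#' @export
match_degenerate <- function(primer, window, max_mismatch = 0L) {
  primer <- toupper(primer); window <- toupper(window)
  np <- nchar(primer); nw <- nchar(window)
  if (nw < np) stop("window is shorter than the primer", call. = FALSE)
  sets <- iupac_sets()
  pch <- strsplit(primer, "", fixed = TRUE)[[1]]
  wch <- strsplit(window, "", fixed = TRUE)[[1]]
  allowed <- sets[pch]
  for (off in seq_len(nw - np + 1L)) {
    mm <- 0L
    for (j in seq_len(np)) {
      if (!(wch[off + j - 1L] %in% allowed[[j]])) {
        mm <- mm + 1L
        if (mm > max_mismatch) break
      }
    }
    if (mm <= max_mismatch) return(off)
  }
  NA_integer_
}

# degenerate primer -> regex with character classes ("I"/"N" -> ".")
primer_regex <- function(primer) {
  sets <- iupac_sets()
  pch <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  paste(vapply(pch, function(ch) {
    s <- sets[[ch]]
    if (length(s) == 1L) s
    else if (length(s) == 4L) "."
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Trim one end's primer from a MID-stripped insert. side = "left" looks
# for `primer` in the first `window` nt; side = "right" for
# revcomp(primer) in the last `window` nt. Returns the trimmed string or
# NA when the primer is not found.
trim_primer <- function(seqs, primer, side, window = 30L, max_mismatch = 2L) {
  n <- nchar(seqs)
  if (side == "right") {
    flipped <- trim_primer(revcomp(seqs), primer, "left", window, max_mismatch)
    out <- revcomp(ifelse(is.na(flipped), "", flipped))
    out[is.na(flipped)] <- NA_character_
    return(out)
  }
  np <- nchar(primer)
  win <- substr(seqs, 1L, pmin(n, window + np - 1L))
  # fast path: degeneracy-aware exact match via regex
  hit <- regexpr(primer_regex(primer), win)
  off <- ifelse(hit > 0L, as.integer(hit), NA_integer_)
  # slow path: tolerate up to max_mismatch mismatches
  todo <- which(is.na(off) & nchar(win) >= np)
  for (i in todo) off[i] <- match_degenerate(primer, win[i], max_mismatch)
  out <- substr(seqs, off + np, n)
  out[is.na(off)] <- NA_character_
  out
}

#' Assign merged reads to wells by their terminal 5-mer MIDs
#'
#' Each merged amplicon read is expected to carry a 5-mer MID at both
#' ends (the 3' one reverse-complemented). The ordered pair (first
#' 5-mer, reverse complement of the last 5-mer) is looked up in the
#' plate's mapping; both orientations of the read are tried, and a read
#' whose two orientations resolve to different wells is left
#' unassigned. On a unique hit, the MIDs and (where found) the
#' fragment's primers are trimmed, yielding the bare insert.
#'
#' MID matching is exact: with 5-mers, a single tolerated mismatch
#' already collides with other table entries.
#'
#' @param merged a data frame of merged reads with columns `plate`,
#'   `sequence` (and optionally `id`).
#' @param mapping a validated mapping tibble (see [read_mapping()]).
#' @param primers a [primer_set()].
#' @param primer_window how far inward of each MID to search for the
#'   primer (nt).
#' @param primer_max_mismatch tolerated mismatches in primer matching.
#' @return the input tibble plus columns `assigned` (logical), `well`,
#'   `fragment`, `insert` (MID- and primer-trimmed sequence) and
#'   `primer_trimmed` (logical; `FALSE` means the MIDs matched but one
#'   or both primers were not located, so only the MIDs were removed --
#'   downstream length gates police such reads).
#' @export
assign_wells <- function(merged, mapping, primers = primer_set(),
                         primer_window = 30L, primer_max_mismatch = 2L) {
  stopifnot(all(c("plate", "sequence") %in% names(merged)))
  mapping <- validate_mapping(mapping)
  out <- tibble::as_tibble(merged)
  n <- nrow(out)
  key <- function(plate, fwd, rev) paste(plate, fwd, rev, sep = "\r")
  lut <- stats::setNames(seq_len(nrow(mapping)),
                         key(mapping$plate, mapping$forward_mid,
                             mapping$reverse_mid))
  s <- out$sequence
  len <- nchar(s)
  first5 <- substr(s, 1L, 5L)
  last5rc <- revcomp(substr(s, len - 4L, len))
  # orientation 2 swaps the two terminal 5-mers
  i1 <- unname(lut[key(out$plate, first5, last5rc)])
  i2 <- unname(lut[key(out$plate, last5rc, first5)])
  # ambiguous if both orientations hit (different rows); palindromic
  # double hits on the same row resolve to that row
  amb <- !is.na(i1) & !is.na(i2) & i1 != i2
  hit <- ifelse(is.na(i1), i2, i1)
  hit[amb] <- NA_integer_
  flip <- is.na(i1) & !is.na(i2) & !amb
  out$assigned <- !is.na(hit) & len > 10L
  out$well <- ifelse(out$assigned, mapping$well[hit], NA_character_)
  out$fragment <- ifelse(out$assigned, mapping$fragment[hit], NA_character_)
  out$insert <- NA_character_
  out$primer_trimmed <- NA
  if (any(out$assigned)) {
    idx <- which(out$assigned)
    core <- s[idx]
    core[flip[idx]] <- revcomp(core[flip[idx]])
    core <- substr(core, 6L, nchar(core) - 5L)   # strip both MIDs
    frag <- out$fragment[idx]
    ins <- core
    ptrim <- rep(TRUE, length(idx))
    for (fg in c("FC", "BR")) {
      sel <- which(frag == fg)
      if (!length(sel)) next
      fwd_p <- if (fg == "FC") primers$fc_forward else primers$br_forward
      rev_p <- if (fg == "FC") primers$fc_reverse else primers$br_reverse
      lt <- trim_primer(core[sel], fwd_p, "left", primer_window,
                        primer_max_mismatch)
      rt <- trim_primer(ifelse(is.na(lt), core[sel], lt), rev_p, "right",
                        primer_window, primer_max_mismatch)
      bad <- is.na(lt) | is.na(rt)
      res <- ifelse(bad, core[sel], rt)
      # salvage a one-sided trim when only one primer was located
      res[is.na(lt) & !is.na(rt)] <- rt[is.na(lt) & !is.na(rt)]
      lt_only <- !is.na(lt) & is.na(rt)
      res[lt_only] <- lt[lt_only]
      ins[sel] <- res
      ptrim[sel] <- !bad
    }
    empty <- !nzchar(ins)
    out$assigned[idx[empty]] <- FALSE
    keep <- !empty
    out$insert[idx[keep]] <- ins[keep]
    out$primer_trimmed[idx[keep]] <- ptrim[keep]
    out$well[idx[empty]] <- NA_character_
    out$fragment[idx[empty]] <- NA_character_
  }
  out$specimen <- ifelse(out$assigned,
                         paste(out$plate, out$well, sep = ":"),
                         NA_character_)
  out
}
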