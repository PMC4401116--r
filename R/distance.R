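#' Kimura 2-parameter distance between two aligned sequences
#'
#' With P the transition and Q the transversion fraction over included
#' sites, the distance is `-1/2 log((1 - 2P - Q) sqrt(1 - 2Q))`
#' substitutions per site. Sites where either sequence has a gap or an
#' ambiguity code are excluded pairwise. Saturated pairs (either log
#' argument non-positive) raise an error rather than returning a
#' non-finite value.
#'
#' @param a,b aligned nucleotide strings of equal length.
#' @return the K2P distance (non-negative real).
#' @examples
#' k2p(strrep("A", 90), strrep("A", 90))
#' @export
k2p <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  m <- rbind(strsplit(a, "", fixed = TRUE)[[1]],
             strsplit(b, "", fixed = TRUE)[[1]])
  rownames(m) <- c("a", "b")
  d <- ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                     pairwise.deletion = TRUE)
  d <- as.numeric(d)
  if (!is.finite(d)) {
    stop("K2P distance is saturated (log of a non-positive value)",
         call. = FALSE)
  }
  d
}

#' Uncorrected pairwise distance
#'
#' Proportion of differing sites among sites where both sequences carry
#' a plain base (gaps and ambiguities excluded pairwise).
#'
#' @param a,b aligned nucleotide strings of equal length.
#' @return p-distance in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no comparable sites", call. = FALSE)
  mean(av[keep] != bv[keep])
}

#' Pairwise K2P distance matrix
#'
#' @param seqs a data frame with columns `id` and `sequence`; all
#'   sequences must be aligned to a common length (the caller supplies
#'   the alignment).
#' @return a `dist` object labelled by `id`.
#' @export
k2p_matrix <- function(seqs) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  lens <- nchar(seqs$sequence)
  if (length(unique(lens)) != 1L) {
    stop("sequences must be aligned to a common length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(seqs$sequence), "", fixed = TRUE))
  rownames(m) <- seqs$id
  d <- ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                     pairwise.deletion = TRUE)
  if (any(!is.finite(d))) {
    stop("K2P distance matrix contains saturated pairs", call. = FALSE)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (as implemented in ape). On additive
#' matrices the generating topology and branch lengths are recovered
#' exactly; branch lengths may be negative on non-additive input and
#' are reported as computed.
#'
#' @param d a `dist` object or symmetric matrix with at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa",
                         call. = FALSE)
  if (any(!is.finite(m))) stop("distance matrix has non-finite entries",
                               call. = FALSE)
  ape::nj(stats::as.dist(m))
}

#' Write and read a PHYLIP square distance matrix
#'
#' @param d a `dist` object or symmetric matrix with labels.
#' @param path output path.
#' @return `read_phylip_dist()` returns a labelled `dist` object.
#' @export
write_phylip_dist <- function(d, path) {
  m <- as.matrix(d)
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(formatC(labs[i], width = -10),
                       formatC(m[i, ], format = "f", digits = 9)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labs <- vapply(rows, `[[`, character(1), 1)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(m) <- list(labs, labs)
  stats::as.dist(m)
}

#' Sanger / HTS concordance report
#'
#' For each specimen present in both inputs, computes the uncorrected
#' and K2P distances between the Sanger sequence and each reported HTS
#' sequence, ranks HTS sequences by similarity, and flags pairs whose
#' p-distance is below `threshold` (default 2%) as concordant.
#' Distances are computed over the aligned overlap: equal-length pairs
#' are compared directly, otherwise a global alignment is used.
#'
#' @param calls output of [call_barcodes()].
#' @param sanger a data frame with columns `specimen`, `sequence`.
#' @param threshold strict upper bound on the concordant p-distance.
#' @return a list with `pairs` (per specimen x HTS-sequence distances)
#'   and `summary` (specimens concordant / discordant / without HTS or
#'   Sanger sequence).
#' @export
sanger_concordance <- function(calls, sanger, threshold = 0.02) {
  stopifnot(all(c("specimen", "sequence") %in% names(sanger)))
  calls <- tibble::as_tibble(calls)
  specs <- unique(calls$specimen)
  pairs <- list(); tally <- c(concordant = 0L, discordant = 0L,
                              hts_none = 0L, sanger_none = 0L)
  for (sp in specs) {
    rows <- calls[calls$specimen == sp & !is.na(calls$sequence), ]
    srow <- sanger[sanger$specimen == sp, ]
    if (!nrow(srow) || is.na(srow$sequence[1])) {
      tally["sanger_none"] <- tally["sanger_none"] + 1L
      next
    }
    if (!nrow(rows)) {
      tally["hts_none"] <- tally["hts_none"] + 1L
      next
    }
    ss <- srow$sequence[1]
    d <- vapply(rows$sequence, function(hs) {
      if (nchar(hs) != nchar(ss)) {
        al <- Biostrings::pairwiseAlignment(hs, ss, type = "global")
        hs <- as.character(Biostrings::alignedPattern(al))
        ss2 <- as.character(Biostrings::alignedSubject(al))
        p_distance(chartr("-", "N", hs), chartr("-", "N", ss2))
      } else {
        p_distance(hs, ss)
      }
    }, numeric(1), USE.NAMES = FALSE)
    k <- vapply(seq_along(d), function(i) {
      hs <- rows$sequence[i]
      if (nchar(hs) == nchar(ss)) {
        tryCatch(k2p(hs, ss), error = function(e) NA_real_)
      } else NA_real_
    }, numeric(1))
    ord <- order(d)
    pairs[[length(pairs) + 1L]] <- tibble::tibble(
      specimen = sp, hts_rank = seq_along(ord),
      p_dist = d[ord], k2p_dist = k[ord],
      concordant = d[ord] < threshold)
    if (any(d < threshold)) tally["concordant"] <- tally["concordant"] + 1L
    else tally["discordant"] <- tally["discordant"] + 1L
  }
  list(pairs = dplyr::bind_rows(pairs),
       summary = tibble::tibble(outcome = names(tally),
                                n = as.integer(tally)))
}
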