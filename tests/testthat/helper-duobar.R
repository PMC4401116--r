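# shared fixture builders; all randomness is locally seeded

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# substitute k bases at distinct positions, never to the original base
mutate_seq <- function(s, k, positions = NULL) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (is.null(positions)) positions <- sample(length(ch), k)
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

q40 <- function(n) strrep("I", n)   # Phred 40

# independent oracle: global-alignment identity via Biostrings only,
# no fast paths (used to audit sequence_identity's Hamming shortcut)
align_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(al) / nchar(as.character(Biostrings::alignedPattern(al)))
}

# literal replay of the greedy clustering definition, used as the
# brute-force oracle: no shortcuts, always full alignment identity
brute_greedy <- function(seqs, counts, identity = 0.99) {
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]; counts <- counts[ord]
  centroids <- character(0); sizes <- numeric(0)
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      if (align_identity(seqs[i], centroids[ci]) >= identity) {
        sizes[ci] <- sizes[ci] + counts[i]; placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, seqs[i])
      sizes <- c(sizes, counts[i])
    }
  }
  list(centroids = centroids, sizes = sizes)
}

# exhaustive oracle for the best-scoring ungapped local segment:
# literal enumeration of every (i, j, L) triple
brute_hsp <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- list(score = -Inf, length = 0L, mismatches = 0L)
  for (i in seq_along(av)) {
    for (j in seq_along(bv)) {
      L <- min(length(av) - i, length(bv) - j) + 1L
      eq <- av[i:(i + L - 1L)] == bv[j:(j + L - 1L)]
      sc <- cumsum(ifelse(eq, 1L, -1L))
      for (l in seq_len(L)) {
        if (sc[l] > best$score) {
          best <- list(score = sc[l], length = l,
                       mismatches = sum(!eq[seq_len(l)]))
        }
      }
    }
  }
  best
}

# one error-free specimen worth of read pairs at packaged defaults
tiny_clean_sim <- function(wells = 1L, coverage = 10L, seed = 1L, ...) {
  simulate_reads(sim_config(wells_per_plate = wells, coverage = coverage,
                            per_base_error = 0, contaminant_rate = 0,
                            chimera_rate = 0, endosymbiont_rate = 0,
                            seed = seed, ...))
}
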