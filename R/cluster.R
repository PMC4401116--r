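#' Pairwise sequence identity
#'
#' Identity is defined as matching columns over total alignment columns
#' of a global alignment scored +1 match, -1 mismatch, -2 gap open,
#' -1 gap extend. Equal-length pairs whose Hamming divergence is small
#' (<= 10%) take a direct column-compare fast path, where a gapless
#' alignment is score-optimal under this scoring.
#'
#' @param a,b nucleotide strings.
#' @return identity in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) stop("empty sequence", call. = FALSE)
  if (a == b) return(1)
  if (na == nb) {
    mm <- hamming(a, b)
    if (mm / na <= 0.1) return((na - mm) / na)
  }
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = duobar_submat(),
    gapOpening = 2, gapExtension = 1)
  ncol_al <- nchar(as.character(Biostrings::alignedPattern(al)))
  Biostrings::nmatch(al) / ncol_al
}

.duobar_cache <- new.env(parent = emptyenv())

duobar_submat <- function() {
  if (is.null(.duobar_cache$submat)) {
    .duobar_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  }
  .duobar_cache$submat
}

# Sound upper bound on alignment identity: matched columns cannot exceed
# the shared base composition, and a global alignment has at least
# max(|a|, |b|) columns.
identity_upper_bound <- function(query, refs) {
  comp <- function(s) tabulate(as.integer(charToRaw(s)), nbins = 128L)
  qc <- comp(query)
  nq <- nchar(query)
  vapply(refs, function(r) {
    sum(pmin(qc, comp(r))) / max(nq, nchar(r))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Collapse identical sequences, retaining counts
#'
#' Exact full-length string identity defines uniqueness; singletons are
#' retained. Output is sorted by descending count, ties broken
#' lexicographically by sequence -- the deterministic processing order
#' used by the chimera screen and the greedy clusterer.
#'
#' @param x a data frame with columns `specimen`, `fragment` and the
#'   sequence column named by `col`.
#' @param col name of the sequence column (default `"insert"`).
#' @return a tibble with columns `specimen`, `fragment`, `sequence`,
#'   `count`, sorted within each specimen-fragment group.
#' @export
dereplicate <- function(x, col = "insert") {
  stopifnot(all(c("specimen", "fragment", col) %in% names(x)))
  out <- tibble::as_tibble(x)
  out$sequence <- out[[col]]
  out <- dplyr::count(out, .data$specimen, .data$fragment, .data$sequence,
                      name = "count")
  dplyr::arrange(out, .data$specimen, .data$fragment,
                 dplyr::desc(.data$count), .data$sequence)
}

# Per-position match profile of sequence p against query q, on query
# coordinates. Equal lengths compare columns directly; otherwise a
# global alignment is projected onto ungapped query positions.
match_profile <- function(q, p) {
  if (nchar(q) == nchar(p)) return(charToRaw(q) == charToRaw(p))
  al <- Biostrings::pairwiseAlignment(
    p, q, type = "global",
    substitutionMatrix = duobar_submat(),
    gapOpening = 2, gapExtension = 1)
  pa <- charToRaw(as.character(Biostrings::alignedPattern(al)))
  sa <- charToRaw(as.character(Biostrings::alignedSubject(al)))
  keep <- sa != charToRaw("-")
  (pa == sa)[keep]
}

# Best two-parent crossover model for query q given match profiles
# eqA/eqB (logical, length n). Returns the model's match count and the
# crossover column, considering both parent orders.
best_crossover <- function(eqA, eqB) {
  n <- length(eqA)
  csA <- cumsum(eqA); csB <- cumsum(eqB)
  totB <- csB[n]; totA <- csA[n]
  k <- seq_len(n - 1L)
  ab <- csA[k] + (totB - csB[k])   # A left, B right
  ba <- csB[k] + (totA - csA[k])   # B left, A right
  if (max(ab) >= max(ba)) {
    list(matches = max(ab), k = k[which.max(ab)], order = "AB")
  } else {
    list(matches = max(ba), k = k[which.max(ba)], order = "BA")
  }
}

# UCHIME-style vote score for a crossover model. Votes are cast only at
# parent-diagnostic columns (A != B): "yes" where the query follows the
# model's local parent, "no" (weighted beta) where it follows the other
# parent, abstain where it matches neither.
uchime_score <- function(eqA, eqB, diffAB, k, order, beta = 8) {
  n <- length(eqA)
  left <- seq_len(n) <= k
  model_is_A <- if (order == "AB") left else !left
  model_eq <- ifelse(model_is_A, eqA, eqB)
  other_eq <- ifelse(model_is_A, eqB, eqA)
  y <- sum(diffAB & model_eq)
  no <- sum(diffAB & other_eq)
  ab <- sum(diffAB & !model_eq & !other_eq)
  denom <- y + ab + beta * no
  if (denom == 0) 0 else y / denom
}

#' Flag putative PCR chimeras de novo
#'
#' A de novo, abundance-ranked chimera screen in the style of UCHIME:
#' for each unique sequence, candidate parents are the more abundant
#' uniques of the same specimen and fragment (count at least
#' `min_parent_fold` times the query's). Over all parent pairs and all
#' crossover columns, the best two-segment model is computed; the query
#' is flagged when the model explains it better than any single parent,
#' the query diverges at least `min_div` from every candidate parent,
#' and the vote score reaches `min_score`.
#'
#' A query with fewer than two candidate parents can never be flagged.
#'
#' @param uniques output of [dereplicate()] (sorted by descending
#'   count within specimen and fragment).
#' @param min_parent_fold minimum parent/query abundance ratio.
#' @param min_div minimum divergence of the query from every single
#'   parent.
#' @param min_score minimum vote score `h`.
#' @param beta weight of "no" votes in the score denominator.
#' @param max_parents cap on candidate parents considered per query
#'   (most abundant first).
#' @return `uniques` with a logical `chimera` column added.
#' @export
detect_chimeras <- function(uniques, min_parent_fold = 2, min_div = 0.008,
                            min_score = 0.28, beta = 8, max_parents = 10L) {
  stopifnot(all(c("specimen", "fragment", "sequence", "count") %in%
                  names(uniques)))
  out <- dplyr::arrange(tibble::as_tibble(uniques),
                        .data$specimen, .data$fragment,
                        dplyr::desc(.data$count), .data$sequence)
  out$chimera <- FALSE
  grp <- paste(out$specimen, out$fragment, sep = "\r")
  for (g in split(seq_len(nrow(out)), grp)) {
    if (length(g) < 3L) next
    seqs <- out$sequence[g]
    counts <- out$count[g]
    for (qi in seq_along(g)) {
      par_idx <- which(counts >= min_parent_fold * counts[qi])
      par_idx <- setdiff(par_idx, qi)
      if (length(par_idx) < 2L) next
      par_idx <- utils::head(par_idx, max_parents)
      q <- seqs[qi]
      profiles <- lapply(seqs[par_idx], function(p) match_profile(q, p))
      divs <- vapply(profiles, function(e) 1 - mean(e), numeric(1))
      if (any(divs < min_div)) next   # query is (nearly) a single parent
      best_single <- 1 - min(divs)
      flagged <- FALSE
      for (ai in seq_len(length(par_idx) - 1L)) {
        for (bi in seq(ai + 1L, length(par_idx))) {
          eqA <- profiles[[ai]]; eqB <- profiles[[bi]]
          if (length(eqA) != length(eqB)) next
          bc <- best_crossover(eqA, eqB)
          model_id <- bc$matches / length(eqA)
          if (model_id <= best_single) next
          # parent-diagnostic columns: where A and B disagree. Exact
          # when all three sequences are colinear (equal length);
          # otherwise approximated by columns where exactly one parent
          # matches the query.
          pa <- seqs[par_idx[ai]]; pb <- seqs[par_idx[bi]]
          diffAB <- if (nchar(pa) == nchar(pb) && nchar(pa) == nchar(q)) {
            charToRaw(pa) != charToRaw(pb)
          } else {
            xor(eqA, eqB)
          }
          h <- uchime_score(eqA, eqB, diffAB, bc$k, bc$order, beta)
          if (h >= min_score) { flagged <- TRUE; break }
        }
        if (flagged) break
      }
      out$chimera[g[qi]] <- flagged
    }
  }
  out
}

#' Greedy centroid clustering at a fixed identity threshold
#'
#' UCLUST-style greedy assignment: uniques are scanned in order of
#' descending count (ties lexicographic); each joins the first existing
#' centroid whose identity (see [sequence_identity()]) reaches
#' `identity`, otherwise it founds a new centroid. Cluster size is the
#' sum of member counts. Clusters are returned per specimen and
#' fragment in descending size order.
#'
#' @param uniques a dereplicated tibble (columns `specimen`,
#'   `fragment`, `sequence`, `count`); a `chimera` column, if present,
#'   is respected by excluding flagged rows.
#' @param identity identity threshold in `[0, 1]`.
#' @return a tibble with columns `specimen`, `fragment`, `centroid`,
#'   `size`, `n_members`, `members` (list of member tibbles).
#' @export
greedy_cluster <- function(uniques, identity = 0.99) {
  stopifnot(all(c("specimen", "fragment", "sequence", "count") %in%
                  names(uniques)))
  x <- tibble::as_tibble(uniques)
  if ("chimera" %in% names(x)) x <- x[!x$chimera, ]
  x <- dplyr::arrange(x, .data$specimen, .data$fragment,
                      dplyr::desc(.data$count), .data$sequence)
  empty <- tibble::tibble(specimen = character(0), fragment = character(0),
                          centroid = character(0), size = numeric(0),
                          n_members = integer(0), members = list())
  if (!nrow(x)) return(empty)
  grp <- paste(x$specimen, x$fragment, sep = "\r")
  res <- lapply(split(seq_len(nrow(x)), grp), function(g) {
    seqs <- x$sequence[g]; counts <- x$count[g]
    cent <- integer(0)            # indices (into g-local) of centroids
    assign <- integer(length(g))
    for (i in seq_along(g)) {
      joined <- 0L
      for (ci in seq_along(cent)) {
        if (sequence_identity(seqs[i], seqs[cent[ci]]) >= identity) {
          joined <- ci; break
        }
      }
      if (joined == 0L) {
        cent <- c(cent, i)
        joined <- length(cent)
      }
      assign[i] <- joined
    }
    tibble::tibble(
      specimen = x$specimen[g[1]], fragment = x$fragment[g[1]],
      centroid = seqs[cent],
      size = vapply(seq_along(cent), function(ci)
        sum(counts[assign == ci]), numeric(1)),
      n_members = vapply(seq_along(cent), function(ci)
        sum(assign == ci), integer(1)),
      members = lapply(seq_along(cent), function(ci)
        tibble::tibble(sequence = seqs[assign == ci],
                       count = counts[assign == ci]))
    )
  })
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, .data$specimen, .data$fragment,
                 dplyr::desc(.data$size), .data$centroid)
}
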