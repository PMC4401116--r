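#' Call per-specimen barcodes by abundance
#'
#' Applies the abundance rule used to separate a specimen's true
#' barcode(s) from low-level contamination: among a specimen's
#' assembled barcodes, report those whose support exceeds `min_frac`
#' (strictly) of the specimen's total support. Specimens are then
#' classified `none` (no sequence reported), `single` (exactly one) or
#' `multiple`.
#'
#' With the default `min_frac = 0.10`, at most 9 sequences can ever be
#' reported per specimen.
#'
#' @param assembled assembled barcodes from [pair_specimens()].
#' @param min_frac strict lower bound on the abundance fraction.
#' @param specimens optional character vector of all specimens expected
#'   (so specimens with no assembly are reported with status `none`).
#' @return a tibble with columns `specimen`, `status`, `rank`,
#'   `sequence`, `support`, `abundance_fraction`; specimens with
#'   status `none` get one all-NA row.
#' @export
call_barcodes <- function(assembled, min_frac = 0.10, specimens = NULL) {
  x <- tibble::as_tibble(assembled)
  stopifnot(all(c("specimen", "sequence", "support") %in% names(x)))
  x <- dplyr::group_by(x, .data$specimen)
  x <- dplyr::mutate(x, abundance_fraction =
                       .data$support / sum(.data$support))
  x <- dplyr::filter(x, .data$abundance_fraction > min_frac)
  x <- dplyr::arrange(x, dplyr::desc(.data$abundance_fraction),
                      .by_group = TRUE)
  x <- dplyr::mutate(x, rank = dplyr::row_number(),
                     status = dplyr::if_else(dplyr::n() == 1L,
                                             "single", "multiple"))
  x <- dplyr::ungroup(x)
  out <- dplyr::select(x, "specimen", "status", "rank", "sequence",
                       "support", "abundance_fraction")
  missing_sp <- setdiff(unique(c(specimens, assembled$specimen)),
                        out$specimen)
  if (length(missing_sp)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      specimen = missing_sp, status = "none", rank = NA_integer_,
      sequence = NA_character_, support = NA_real_,
      abundance_fraction = NA_real_))
  }
  dplyr::arrange(out, .data$specimen, .data$rank)
}

#' Best-hit identification against a labelled reference set
#'
#' A local stand-in for database comparison: each query is assigned the
#' label of the reference record with the highest global-alignment
#' identity (see [sequence_identity()]); ties go to the earlier record
#' in `db` order.
#'
#' @param seq a nucleotide string.
#' @param db a reference tibble with columns `label`, `sequence`.
#' @return a one-row tibble `label`, `identity`.
#' @export
best_hit <- function(seq, db) {
  stopifnot(all(c("label", "sequence") %in% names(db)))
  if (!nrow(db)) stop("reference set is empty", call. = FALSE)
  # prune with a sound identity upper bound (shared base composition /
  # max length): records whose bound cannot beat the current best are
  # never aligned. Ties still resolve to the earliest db record.
  ub <- identity_upper_bound(seq, db$sequence)
  ord <- order(-ub, seq_len(nrow(db)))
  best_id <- -Inf; best_i <- NA_integer_
  for (i in ord) {
    if (ub[i] < best_id) break
    id <- sequence_identity(seq, db$sequence[i])
    if (id > best_id || (id == best_id && i < best_i)) {
      best_id <- id; best_i <- i
    }
  }
  tibble::tibble(label = db$label[best_i], identity = best_id)
}

#' Label called barcodes by best reference hit
#'
#' @param calls output of [call_barcodes()].
#' @param db a reference tibble with columns `label`, `sequence`.
#' @return `calls` with `label` and `identity` columns added (NA for
#'   status-`none` rows).
#' @export
identify_calls <- function(calls, db) {
  out <- tibble::as_tibble(calls)
  out$label <- NA_character_
  out$identity <- NA_real_
  idx <- which(!is.na(out$sequence))
  if (length(idx)) {
    hits <- dplyr::bind_rows(lapply(out$sequence[idx], best_hit, db = db))
    out$label[idx] <- hits$label
    out$identity[idx] <- hits$identity
  }
  out
}

#' Concordance of called barcodes with expectations
#'
#' Compares each specimen's called sequences against an expectation --
#' either an expected taxon label (matched against the `label` column
#' of identified calls) or an expected sequence (matched exactly). A
#' specimen matches when any of its reported sequences agrees with the
#' expectation. Specimens absent from `truth` are tallied as
#' `no_expectation` and excluded from percentages.
#'
#' @param calls output of [call_barcodes()] (optionally through
#'   [identify_calls()]).
#' @param truth a data frame with column `specimen` and one of
#'   `label` / `sequence` as the expectation.
#' @return a list with `per_specimen` (tibble: specimen, status,
#'   outcome) and `summary` (tibble of outcome counts and percentages).
#' @export
concordance_table <- function(calls, truth) {
  stopifnot("specimen" %in% names(truth))
  by_label <- "label" %in% names(truth) && "label" %in% names(calls)
  expect_col <- if (by_label) "label" else "sequence"
  stopifnot(expect_col %in% names(truth))
  calls <- tibble::as_tibble(calls)
  per <- lapply(unique(c(calls$specimen, truth$specimen)), function(sp) {
    rows <- calls[!is.na(calls$specimen) & calls$specimen == sp, ]
    trow <- truth[truth$specimen == sp, ]
    status <- if (nrow(rows)) rows$status[1] else "none"
    outcome <- if (!nrow(trow)) {
      "no_expectation"
    } else if (!nrow(rows) || all(is.na(rows$sequence))) {
      "no_sequence"
    } else {
      got <- rows[[expect_col]]
      if (any(!is.na(got) & got == trow[[expect_col]][1])) "match"
      else "non_match"
    }
    tibble::tibble(specimen = sp, status = status, outcome = outcome)
  })
  per <- dplyr::bind_rows(per)
  scored <- per[per$outcome != "no_expectation", ]
  summary <- dplyr::count(scored, .data$outcome, name = "n")
  summary$percent <- if (nrow(scored)) 100 * summary$n / nrow(scored)
                     else numeric(nrow(summary))
  list(per_specimen = per, summary = tibble::as_tibble(summary))
}
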