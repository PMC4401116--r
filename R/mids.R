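#' The 40-entry 5-mer well-index (MID) table
#'
#' The dual-indexing design uses 40 distinct 5-mer multiplex identifiers
#' (MIDs): 20 designed for the 5' half-barcode amplicon (FC) and 20 for
#' the 3' half (BR). Every amplicon carries one MID at each end, so a
#' well is addressed by an ordered (forward, reverse) MID pair per
#' fragment.
#'
#' @return a tibble with columns `mid` (5-mer), `list` (`"FC"` or `"BR"`,
#'   the design list the MID belongs to) and `index` (1-20 within its
#'   list).
#' @examples
#' mid_table()
#' @export
mid_table <- function() {
  fc <- c("AAGCT", "ATTGC", "AGATC", "AGCAT", "TTCAG", "TGATC", "TCAAG",
          "TGAGC", "CAATG", "CATTG", "CTTGA", "CTGAA", "ATGCA", "AGCTT",
          "TGCAA", "TGCCA", "TCATG", "CATGA", "CTGAT", "CATGC")
  br <- c("ATGCT", "ATGCC", "AGCTG", "AGCTC", "TGCAT", "TGCAG", "TCAGA",
          "TCAGG", "CAGAT", "CCTGA", "CTCAG", "CTGCA", "ATCAG", "AGCCT",
          "ATCTG", "TCAGC", "TCTGA", "TCCAG", "CAGCT", "CTGAG")
  tibble::tibble(
    mid = c(fc, br),
    list = rep(c("FC", "BR"), each = 20L),
    index = rep(seq_len(20L), 2L)
  )
}

#' Build a default well-to-MID-pair mapping
#'
#' The published design does not fix how the two 20-MID lists encode the
#' 96 wells of a plate, so the layout travels in the mapping table.
#' This helper produces one systematic layout: for each fragment, wells
#' (column-major A1..H12) are assigned the ordered MID pairs
#' `(list[i], list[j])` with `i < j`, enumerated lexicographically from
#' that fragment's own 20-entry list. Restricting to `i < j` means a
#' pair and its swap are never both in use, so reading an amplicon in
#' either orientation resolves to a unique well (C(20,2) = 190 pairs
#' cover a 96-well plate comfortably).
#'
#' @param n_plates number of 96-well plates.
#' @param wells_per_plate number of occupied wells per plate (<= 96).
#' @return a mapping tibble with columns `plate`, `well`, `fragment`,
#'   `forward_mid`, `reverse_mid`.
#' @export
default_mapping <- function(n_plates = 1L, wells_per_plate = 96L) {
  stopifnot(n_plates >= 1L, wells_per_plate >= 1L, wells_per_plate <= 96L)
  wells <- paste0(rep(LETTERS[1:8], times = 12), rep(1:12, each = 8))
  wells <- wells[seq_len(wells_per_plate)]
  mids <- mid_table()
  one_frag <- function(frag) {
    lst <- mids$mid[mids$list == frag]
    ij <- which(upper.tri(matrix(0, 20, 20)), arr.ind = TRUE)
    ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
    w <- seq_along(wells)
    tibble::tibble(
      well = wells, fragment = frag,
      forward_mid = lst[ij[w, "row"]],
      reverse_mid = lst[ij[w, "col"]]
    )
  }
  per_plate <- dplyr::bind_rows(one_frag("FC"), one_frag("BR"))
  out <- dplyr::bind_rows(lapply(seq_len(n_plates), function(p) {
    dplyr::mutate(per_plate, plate = sprintf("P%d", p), .before = 1)
  }))
  validate_mapping(out)
}

#' Read a well/MID mapping table
#'
#' The mapping file is a tab-separated table with a header line and
#' columns `plate`, `well`, `fragment`, `forward_mid`, `reverse_mid`.
#' Every MID must be one of the 40 published 5-mers, and the
#' (fragment, forward, reverse) triple must be unique within a plate --
#' otherwise demultiplexing would be ambiguous.
#'
#' @param path path to a TSV mapping file (optionally gz-compressed).
#' @param mapping a mapping data frame to validate or write.
#' @return a validated mapping tibble.
#' @export
read_mapping <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", strip.white = TRUE)
  validate_mapping(tibble::as_tibble(df))
}

#' @rdname read_mapping
#' @export
write_mapping <- function(mapping, path) {
  mapping <- validate_mapping(mapping)
  utils::write.table(mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_mapping
#' @export
validate_mapping <- function(mapping) {
  need <- c("plate", "well", "fragment", "forward_mid", "reverse_mid")
  miss <- setdiff(need, names(mapping))
  if (length(miss)) {
    stop("mapping is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  mapping <- tibble::as_tibble(mapping)[need]
  mapping$fragment <- toupper(mapping$fragment)
  if (!all(mapping$fragment %in% c("FC", "BR"))) {
    stop("mapping fragment must be FC or BR", call. = FALSE)
  }
  mids <- mid_table()$mid
  used <- c(mapping$forward_mid, mapping$reverse_mid)
  unknown <- setdiff(used, mids)
  if (length(unknown)) {
    stop(sprintf("MID '%s' is not in the 40-entry MID table", unknown[1]),
         call. = FALSE)
  }
  key <- paste(mapping$plate, mapping$fragment, mapping$forward_mid,
               mapping$reverse_mid, sep = "\r")
  if (anyDuplicated(key)) {
    d <- mapping[duplicated(key), ]
    stop(sprintf(
      "duplicate MID pair within plate '%s' fragment %s: %s/%s (ambiguous wells)",
      d$plate[1], d$fragment[1], d$forward_mid[1], d$reverse_mid[1]),
      call. = FALSE)
  }
  mapping
}
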