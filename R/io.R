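#' Read a FASTQ file into a tibble
#'
#' Reads a 4-line FASTQ file (plain or gzipped) with Phred+33 qualities.
#' Sequences are uppercased on read; qualities are kept as the encoded
#' string (decode with [phred_to_int()]).
#'
#' Only the Phred+33 offset is supported; files whose quality characters
#' fall outside the printable Phred+33 range are rejected rather than
#' silently reinterpreted.
#'
#' @param path path to a FASTQ file, optionally gz-compressed.
#' @return a tibble with columns `id`, `sequence`, `quality`, one row per
#'   read, in file order.
#' @export
read_fastq <- function(path) {
  parsed <- tryCatch({
    # suppressWarnings: Biostrings warns about dropped metadata columns
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    list(id = as.character(names(x)),
         sequence = unname(toupper(as.character(x))),
         quality = unname(suppressWarnings(
           as.character(Biostrings::quality(x)))))
  },
  error = function(e) {
    stop(sprintf("malformed FASTQ in '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  out <- tibble::as_tibble(parsed)
  # Biostrings pads short quality lines instead of erroring; reject any
  # record whose qualities fall outside the printable Phred+33 range or
  # whose lengths disagree
  bad <- nchar(out$sequence, type = "bytes") !=
    nchar(out$quality, type = "bytes") |
    vapply(out$quality, function(q) {
      r <- charToRaw(q)
      length(r) == 0L || any(r < as.raw(33L)) || any(r > as.raw(126L))
    }, logical(1), USE.NAMES = FALSE)
  if (any(bad)) {
    stop(sprintf("malformed FASTQ record '%s': sequence and quality lines disagree",
                 out$id[which(bad)[1]]), call. = FALSE)
  }
  out
}

#' Write reads to a FASTQ file
#'
#' @param reads a data frame with columns `id`, `sequence`, `quality`
#'   (Phred+33 strings).
#' @param path output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality)
  )
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read and write FASTA files
#'
#' Thin tibble-first wrappers around Biostrings. Sequences are uppercased
#' on read. `write_fasta()` refuses duplicate ids so that every written
#' file round-trips unambiguously.
#'
#' @param path path to a FASTA file, optionally gz-compressed.
#' @param records a data frame with columns `id` and `sequence`.
#' @return `read_fasta()` returns a tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble::tibble(id = as.character(names(x)),
                 sequence = unname(toupper(as.character(x))))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop(sprintf("duplicate FASTA id '%s'",
                 records$id[duplicated(records$id)][1]), call. = FALSE)
  }
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}
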