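#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over the IUPAC alphabet plus inosine
#' (`I`), which is self-complementary for matching purposes. Case is
#' preserved on output as uppercase (all duobar sequences are stored
#' uppercase).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @examples
#' revcomp("AAGCT")
#' revcomp("GGIGGRTAIACIGTTCAICC")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTUMRWSYKVHDBNI", "TGCAAKYWSRMBDHVNI", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# IUPAC code -> set of plain bases it stands for; I (inosine) and N match all
iupac_sets <- function() {
  list(A = "A", C = "C", G = "G", T = "T", U = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"),
       H = c("A", "C", "T"), V = c("A", "C", "G"),
       N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T"))
}

#' Decode and encode Phred+33 quality strings
#'
#' @param q character vector of Phred+33 encoded quality strings.
#' @param scores list or vector of integer Phred scores.
#' @return `phred_to_int()` returns a list of integer vectors;
#'   `int_to_phred()` a character vector.
#' @examples
#' phred_to_int("IIII")
#' int_to_phred(c(40, 40, 2))
#' @export
phred_to_int <- function(q) {
  lapply(q, function(s) {
    if (is.na(s)) return(integer(0))
    as.integer(utf8ToInt(s)) - 33L
  })
}

#' @rdname phred_to_int
#' @export
int_to_phred <- function(scores) {
  if (!is.list(scores)) scores <- list(scores)
  vapply(scores, function(v) intToUtf8(as.integer(v) + 33L), character(1))
}

# mean Phred score per read, NA-safe for missing qualities
mean_phred <- function(q) {
  vapply(phred_to_int(q), function(v) if (length(v)) mean(v) else NA_real_,
         numeric(1))
}

# Hamming mismatch count between two equal-length strings (plain bases)
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

check_seq_chr <- function(x, arg = "sequence") {
  bad <- grepl("[^ACGTUMRWSYKVHDBNI]", toupper(x))
  if (any(bad)) {
    stop(sprintf("%s contains non-nucleotide characters (first offender: %s)",
                 arg, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}
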