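pair_from_template <- function(template, fwd_len, rev_from) {
  n <- nchar(template)
  tibble::tibble(
    fwd_seq = substr(template, 1, fwd_len), fwd_qual = q40(fwd_len),
    rev_seq = revcomp(substr(template, rev_from, n)),
    rev_qual = q40(n - rev_from + 1))
}

test_that("overlap merging reconstructs the template and respects the 25 bp floor", {
  tpl <- withr::with_seed(3, rand_seq(35))
  m <- merge_pairs(pair_from_template(tpl, 30, 6))   # true overlap 25
  expect_true(m$merged)
  expect_equal(m$sequence, tpl)
  expect_equal(m$overlap_length, 25L)
  expect_equal(m$overlap_mismatches, 0L)

  tpl36 <- withr::with_seed(4, rand_seq(36))
  m24 <- merge_pairs(pair_from_template(tpl36, 30, 7))  # true overlap 24
  expect_false(m24$merged)
})

test_that("fully overlapping equal-length pairs merge to the forward read", {
  f <- withr::with_seed(5, rand_seq(40))
  m <- merge_pairs(tibble::tibble(fwd_seq = f, fwd_qual = q40(40),
                                  rev_seq = revcomp(f), rev_qual = q40(40)))
  expect_equal(m$sequence, f)
  expect_equal(m$overlap_length, 40L)
})

test_that("merged length equals |fwd| + |rev| - overlap for random geometries", {
  withr::with_seed(6, {
    for (i in 1:20) {
      n <- sample(60:120, 1)
      tpl <- rand_seq(n)
      fl <- sample(40:(n - 5), 1)
      rf <- sample(2:max(2, min(fl - 25, n - 40)), 1)
      m <- merge_pairs(pair_from_template(tpl, fl, rf))
      if (m$merged) {
        expect_equal(nchar(m$sequence),
                     fl + (n - rf + 1) - m$overlap_length)
        expect_equal(m$overlap_mismatches, 0L)
      }
    }
  })
})

test_that("lowering min_overlap never merges fewer pairs", {
  pairs <- withr::with_seed(7, dplyr::bind_rows(lapply(1:15, function(i) {
    n <- sample(50:90, 1)
    pair_from_template(rand_seq(n), 40, sample(2:30, 1))
  })))
  n_merged <- vapply(c(40L, 30L, 20L, 10L), function(mo)
    sum(merge_pairs(pairs, merge_config(min_overlap = mo))$merged),
    numeric(1))
  expect_true(all(diff(n_merged) >= 0))
})

test_that("disagreeing overlap columns take the higher-quality base", {
  f <- "ACGTACGTAC"
  r_true <- revcomp(f)
  # corrupt one reverse-read base but give it higher quality
  r_bad <- paste0("T", substr(r_true, 2, 10))   # disagrees at last fwd column
  m <- merge_pairs(tibble::tibble(
    fwd_seq = f, fwd_qual = int_to_phred(c(rep(40, 9), 10)),
    rev_seq = r_bad, rev_qual = int_to_phred(rep(30, 10))),
    merge_config(min_overlap = 10, max_overlap_mismatch_frac = 0.1))
  expect_true(m$merged)
  expect_equal(substr(m$sequence, 10, 10), "A")  # revcomp("T")
  expect_equal(phred_to_int(m$quality)[[1]][10], 20)  # |30 - 10|
})

test_that("mean-quality gate is inclusive at Phred 20", {
  mk <- function(quals) tibble::tibble(sequence = strrep("A", length(quals)),
                                       quality = int_to_phred(quals))
  expect_true(quality_gate(mk(rep(20, 10)))$pass_quality)
  expect_false(quality_gate(mk(rep(19, 10)))$pass_quality)
  expect_true(quality_gate(mk(c(rep(10, 5), rep(30, 5))))$pass_quality)
})

test_that("fragment length windows are closed intervals", {
  mk <- function(frag, len) tibble::tibble(fragment = frag,
                                           sequence = strrep("A", len))
  expect_true(length_gate(mk("FC", 300))$pass_length)
  expect_false(length_gate(mk("FC", 299))$pass_length)
  expect_true(length_gate(mk("FC", 400))$pass_length)
  expect_false(length_gate(mk("FC", 401))$pass_length)
  expect_true(length_gate(mk("FC", 350))$pass_length)
  expect_true(length_gate(mk("BR", 400))$pass_length)
  expect_true(length_gate(mk("BR", 500))$pass_length)
  expect_false(length_gate(mk("BR", 501))$pass_length)
  expect_false(length_gate(mk("BR", 399))$pass_length)
})
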