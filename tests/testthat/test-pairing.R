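test_that("an exact shared 82-nt region passes the HSP screen", {
  ref <- withr::with_seed(61, rand_seq(658))
  fc <- substr(ref, 1, 307)
  br <- substr(ref, 226, 658)
  h <- screen_pair(fc, br)
  expect_true(h$accepted)
  expect_gte(h$length, 82L)
  expect_equal(h$identity, 1.0)
  expect_false(h$br_revcomp)
  # and with BR handed over reverse-complemented
  hrc <- screen_pair(fc, revcomp(br))
  expect_true(hrc$accepted)
  expect_true(hrc$br_revcomp)
})

test_that("three mismatches in the shared region fail the <= 2 mismatch rule", {
  ref <- withr::with_seed(62, rand_seq(658))
  fc <- substr(ref, 1, 307)
  br <- substr(ref, 226, 658)
  # spread three mismatches across the 82-nt overlap of the BR copy
  br3 <- mutate_seq(br, 3, positions = c(15, 40, 70))
  h <- screen_pair(fc, br3)
  expect_false(h$accepted)
  expect_gt(h$mismatches, 2L)
})

test_that("unrelated sequences produce no qualifying HSP", {
  withr::with_seed(63, {
    for (i in 1:5) {
      h <- screen_pair(rand_seq(300), rand_seq(300))
      expect_false(h$accepted)
      expect_lt(h$length - h$mismatches, 25L)
    }
  })
})

test_that("the HSP search equals the exhaustive all-diagonals oracle", {
  withr::with_seed(64, {
    for (i in 1:8) {
      a <- rand_seq(60)
      b <- if (i %% 2 == 0) {
        paste0(rand_seq(10), substr(a, 20, 50), rand_seq(15))
      } else {
        rand_seq(55)
      }
      got <- duobar:::best_hsp(a, b)
      want <- brute_hsp(a, b)
      expect_equal(got$score, want$score)
      expect_equal(got$length - 2L * got$mismatches, want$score)
    }
  })
})

test_that("assembly reproduces the 658/82 geometry and its boundaries", {
  ref <- withr::with_seed(65, rand_seq(658))
  fc <- substr(ref, 1, 307)
  br <- substr(ref, 226, 658)
  asm <- assemble_pair(fc, br, 10, 8)
  expect_equal(asm$sequence, ref)
  expect_equal(asm$overlap_length, 82L)
  expect_equal(asm$support, 8)
  # a 79-nt true overlap fails the 80 bp minimum
  br79 <- substr(ref, 229, 658)
  expect_equal(nrow(assemble_pair(fc, br79, 10, 8)), 0L)
})

test_that("assembly tolerates exactly 2% overlap mismatches", {
  ref <- withr::with_seed(66, rand_seq(600))
  fc <- substr(ref, 1, 350)
  br <- substr(ref, 251, 600)   # 100-nt overlap
  br2 <- mutate_seq(br, 2, positions = c(20, 60))
  br3 <- mutate_seq(br, 3, positions = c(20, 60, 90))
  expect_equal(assemble_pair(fc, br2, 1, 1)$overlap_length, 100L)
  expect_equal(nrow(assemble_pair(fc, br3, 1, 1)), 0L)
})

test_that("assembled length always equals |FC| + |BR| - overlap", {
  withr::with_seed(67, {
    for (i in 1:10) {
      n <- sample(500:700, 1)
      ref <- rand_seq(n)
      cut_f <- sample(250:350, 1)
      cut_b <- sample(80:min(200, cut_f - 81), 1)
      fc <- substr(ref, 1, cut_f)
      br <- substr(ref, cut_f - cut_b + 1, n)
      asm <- assemble_pair(fc, br)
      expect_equal(nchar(asm$sequence),
                   nchar(fc) + nchar(br) - asm$overlap_length)
    }
  })
})

test_that("overlap consensus takes the base from the larger cluster", {
  ref <- withr::with_seed(68, rand_seq(500))
  fc <- substr(ref, 1, 300)
  br <- substr(ref, 201, 500)
  br_mut <- mutate_seq(br, 1, positions = 50)   # inside the 100-nt overlap
  big_br <- assemble_pair(fc, br_mut, fc_size = 2, br_size = 10)
  expect_equal(substr(big_br$sequence, 250, 250), substr(br_mut, 50, 50))
  big_fc <- assemble_pair(fc, br_mut, fc_size = 10, br_size = 2)
  expect_equal(big_fc$sequence, ref)
  tie <- assemble_pair(fc, br_mut, fc_size = 5, br_size = 5)
  expect_equal(tie$sequence, ref)   # tie goes to FC
})

test_that("per-specimen pairing recovers truth and separates co-amplicons", {
  sim <- tiny_clean_sim(wells = 3, coverage = 8, seed = 69)
  merged <- merge_pairs(sim$reads)
  d <- assign_wells(merged, sim$mapping, sim$primers)
  cl <- greedy_cluster(detect_chimeras(dereplicate(d[d$assigned, ])))
  asm <- pair_specimens(cl)
  expect_equal(nrow(asm), 3L)
  truth <- sim$truth$specimens
  expect_equal(asm$sequence[match(truth$specimen, asm$specimen)],
               truth$barcode)

  # an FC facing only a >= 5%-divergent BR yields nothing
  ref <- withr::with_seed(70, rand_seq(658))
  other <- withr::with_seed(71, mutate_seq(ref, 60))
  cl2 <- tibble::tibble(
    specimen = "X", fragment = c("FC", "BR"),
    centroid = c(substr(ref, 1, 307), substr(other, 226, 658)),
    size = c(10, 10))
  expect_equal(nrow(pair_specimens(cl2)), 0L)

  # two co-amplified templates give two assembled barcodes
  ref2 <- withr::with_seed(72, rand_seq(658))
  cl3 <- tibble::tibble(
    specimen = "Y", fragment = c("FC", "FC", "BR", "BR"),
    centroid = c(substr(ref, 1, 307), substr(ref2, 1, 307),
                 substr(ref, 226, 658), substr(ref2, 226, 658)),
    size = c(60, 40, 55, 35))
  asm3 <- pair_specimens(cl3)
  expect_equal(nrow(asm3), 2L)
  expect_setequal(asm3$sequence, c(ref, ref2))
  expect_equal(asm3$support, c(55, 35))
})
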