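test_that("K2P matches the closed form and detects saturation", {
  a <- strrep("A", 100)
  expect_equal(k2p(a, a), 0)
  # 10 transitions (A->G), no transversions: -1/2 log(0.8)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p(a, b), -0.5 * log(0.8), tolerance = 1e-12)
  expect_error(k2p("AAAA", "GGGG"), "saturated")
  expect_error(k2p("AAAA", "GG"), "equal length")
  # transversions enter through the sqrt term
  withr::with_seed(91, {
    s1 <- rand_seq(500)
    s2 <- mutate_seq(s1, 20)
    ch1 <- strsplit(s1, "")[[1]]; ch2 <- strsplit(s2, "")[[1]]
    ts <- sum((ch1 == "A" & ch2 == "G") | (ch1 == "G" & ch2 == "A") |
                (ch1 == "C" & ch2 == "T") | (ch1 == "T" & ch2 == "C"))
    tv <- sum(ch1 != ch2) - ts
    P <- ts / 500; Q <- tv / 500
    expect_equal(k2p(s1, s2), -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)),
                 tolerance = 1e-12)
  })
})

test_that("K2P is non-negative, zero iff sequences agree, gaps excluded pairwise", {
  withr::with_seed(92, {
    for (i in 1:5) {
      s1 <- rand_seq(200)
      s2 <- mutate_seq(s1, sample(0:30, 1))
      d <- k2p(s1, s2)
      expect_gte(d, 0)
      expect_equal(d == 0, s1 == s2)
    }
  })
  # N-ed sites drop out pairwise
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 85), strrep("N", 5))
  expect_equal(k2p(a, b), {P <- 10 / 95; -0.5 * log(1 - 2 * P)},
               tolerance = 1e-12)
})

test_that("three-taxon NJ branch lengths follow the closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  el <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["a"]], (3 + 4 - 5) / 2)
  expect_equal(el[["b"]], (3 + 5 - 4) / 2)
  expect_equal(el[["c"]], (4 + 5 - 3) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive trees exactly", {
  withr::with_seed(93, {
    for (i in 1:8) {
      n <- sample(4:10, 1)
      tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
      tr <- ape::unroot(tr)
      d <- ape::cophenetic.phylo(tr)
      got <- nj_tree(d)
      expect_equal(ape::dist.topo(got, tr), structure(0, class = NULL),
                   ignore_attr = TRUE)
      expect_equal(max(abs(ape::cophenetic.phylo(got)[rownames(d),
                                                      colnames(d)] - d)),
                   0, tolerance = 1e-9)
    }
  })
})

test_that("NJ is deterministic on tie-laden matrices", {
  m <- matrix(1, 5, 5) - diag(5)
  dimnames(m) <- list(letters[1:5], letters[1:5])
  t1 <- nj_tree(m); t2 <- nj_tree(m)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("PHYLIP square distance matrices round-trip", {
  withr::with_seed(94, {
    seqs <- tibble::tibble(id = paste0("t", 1:5),
                           sequence = vapply(1:5, function(i) {
                             mutate_seq(strrep("ACGT", 50), sample(1:20, 1))
                           }, character(1)))
  })
  d <- k2p_matrix(seqs)
  tmp <- withr::local_tempfile(fileext = ".phy")
  write_phylip_dist(d, tmp)
  back <- read_phylip_dist(tmp)
  expect_equal(as.matrix(back), as.matrix(d), tolerance = 1e-6)
})

test_that("Sanger/HTS concordance applies the 2% threshold strictly", {
  base <- withr::with_seed(95, rand_seq(658))
  mk_calls <- function(seqs) tibble::tibble(
    specimen = "s", status = "single", sequence = seqs)
  sang <- tibble::tibble(specimen = "s", sequence = base)

  same <- sanger_concordance(mk_calls(base), sang)
  expect_equal(same$pairs$p_dist, 0)
  expect_true(same$pairs$concordant)

  d13 <- withr::with_seed(96, mutate_seq(base, 13))   # 13/658 < 0.02
  d14 <- withr::with_seed(97, mutate_seq(base, 14))   # 14/658 > 0.02
  expect_true(sanger_concordance(mk_calls(d13), sang)$pairs$concordant)
  expect_false(sanger_concordance(mk_calls(d14), sang)$pairs$concordant)

  # specimens with no HTS sequence are tallied separately
  none <- sanger_concordance(
    tibble::tibble(specimen = "s", status = "none",
                   sequence = NA_character_), sang)
  expect_equal(none$summary$n[none$summary$outcome == "hts_none"], 1L)
})
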