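uniq_tbl <- function(seqs, counts, specimen = "S1", fragment = "FC") {
  tibble::tibble(specimen = specimen, fragment = fragment,
                 sequence = seqs, count = counts)
}

test_that("dereplication collapses exact duplicates and keeps singletons", {
  x <- tibble::tibble(specimen = "S1", fragment = "FC",
                      insert = c("ACGT", "ACGT", "ACGT", "TTTT"))
  u <- dereplicate(x)
  expect_equal(u$sequence, c("ACGT", "TTTT"))
  expect_equal(u$count, c(3L, 1L))

  all_diff <- tibble::tibble(specimen = "S1", fragment = "FC",
                             insert = withr::with_seed(41, vapply(
                               1:7, function(i) rand_seq(20), character(1))))
  expect_true(all(dereplicate(all_diff)$count == 1L))
  expect_equal(sum(dereplicate(all_diff)$count), 7L)
})

test_that("identity threshold behaves exactly at the 99% boundary", {
  base <- withr::with_seed(42, rand_seq(1000))
  ten <- mutate_seq(base, 0, positions = NULL)
  ten <- withr::with_seed(43, mutate_seq(base, 10))
  eleven <- withr::with_seed(44, mutate_seq(base, 11))
  expect_equal(sequence_identity(base, ten), 0.99)
  cl10 <- greedy_cluster(uniq_tbl(c(base, ten), c(5, 3)))
  expect_equal(nrow(cl10), 1L)
  cl11 <- greedy_cluster(uniq_tbl(c(base, eleven), c(5, 3)))
  expect_equal(nrow(cl11), 2L)
})

test_that("greedy order makes the most abundant sequence the centroid", {
  base <- withr::with_seed(45, rand_seq(500))
  v1 <- withr::with_seed(46, mutate_seq(base, 2))
  v2 <- withr::with_seed(47, mutate_seq(base, 3))
  cl <- greedy_cluster(uniq_tbl(c(v1, base, v2), c(3, 5, 1)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$centroid, base)
  expect_equal(cl$size, 9)
})

test_that("greedy clustering equals the literal brute-force replay", {
  withr::with_seed(48, {
    for (case in 1:12) {
      n_base <- sample(2:3, 1)
      bases <- vapply(seq_len(n_base), function(i) rand_seq(300),
                      character(1))
      seqs <- unique(unlist(lapply(bases, function(b) {
        c(b, vapply(seq_len(sample(1:3, 1)), function(i)
          mutate_seq(b, sample(1:6, 1)), character(1)))
      })))
      seqs <- utils::head(seqs, 8)
      counts <- sample(1:50, length(seqs))
      got <- greedy_cluster(uniq_tbl(seqs, counts))
      want <- brute_greedy(seqs, counts)
      expect_setequal(got$centroid, want$centroids)
      expect_equal(got$size[order(got$centroid)],
                   want$sizes[order(want$centroids)])
    }
  })
})

test_that("cluster sizes conserve the dereplicated read counts", {
  sim <- tiny_clean_sim(wells = 4, coverage = 8, seed = 51)
  merged <- merge_pairs(sim$reads)
  d <- assign_wells(merged, sim$mapping, sim$primers)
  u <- dereplicate(d[d$assigned, ])
  cl <- greedy_cluster(u)
  expect_equal(sum(cl$size), sum(u$count))
  expect_equal(sum(u$count), sum(d$assigned))
})

test_that("constructed two-parent chimeras are flagged across crossover points", {
  base <- withr::with_seed(52, rand_seq(300))
  parentB <- withr::with_seed(53, mutate_seq(base, 15))  # 5% divergence
  for (k in c(120, 150, 180)) {
    chim <- paste0(substr(base, 1, k), substr(parentB, k + 1, 300))
    u <- detect_chimeras(uniq_tbl(c(base, parentB, chim), c(100, 100, 1)))
    expect_true(u$chimera[u$sequence == chim], label = paste("k =", k))
    expect_false(any(u$chimera[u$sequence != chim]))
  }
})

test_that("non-chimeric configurations are never flagged", {
  base <- withr::with_seed(54, rand_seq(300))
  parentB <- withr::with_seed(55, mutate_seq(base, 15))
  # query identical to a parent
  u <- detect_chimeras(uniq_tbl(c(base, parentB, base), c(100, 100, 1)))
  expect_false(any(u$chimera))
  # a lone unique has no parent pair
  u1 <- detect_chimeras(uniq_tbl(base, 10))
  expect_false(any(u1$chimera))
  # abundant sequences cannot be their own parents' chimera target
  u2 <- detect_chimeras(uniq_tbl(c(base, parentB), c(100, 100)))
  expect_false(any(u2$chimera))
})

test_that("clean simulated data yields zero chimera flags", {
  sim <- tiny_clean_sim(wells = 4, coverage = 10, seed = 56)
  merged <- merge_pairs(sim$reads)
  d <- assign_wells(merged, sim$mapping, sim$primers)
  u <- detect_chimeras(dereplicate(d[d$assigned, ]))
  expect_false(any(u$chimera))
})

test_that("labelled chimeras from divergent parents are recovered with no false flags", {
  sim <- simulate_reads(sim_config(
    wells_per_plate = 12, coverage = 40, per_base_error = 0,
    contaminant_rate = 0.5, contaminant_frac = 0.35,
    chimera_rate = 0.08, endosymbiont_rate = 0, seed = 57))
  merged <- merge_pairs(sim$reads)
  d <- assign_wells(merged, sim$mapping, sim$primers)
  u <- detect_chimeras(dereplicate(d[d$assigned, ]))
  truth <- sim$truth$reads
  # eligible: chimeric amplicons whose parents diverge >= 3% in-fragment
  # and whose parents outnumber them >= 10x
  elig <- truth[truth$origin == "chimera" &
                  !is.na(truth$parent_divergence) &
                  truth$parent_divergence >= 0.03, ]
  key <- paste(u$specimen, u$fragment, u$sequence)
  d$key <- paste(d$specimen, d$fragment, d$insert)
  truth_by_id <- truth[match(d$id, truth$id), ]
  chim_keys <- unique(d$key[truth_by_id$origin == "chimera" &
                              d$id %in% elig$id])
  chim_counts <- table(d$key)[chim_keys]
  chim_keys <- names(chim_counts)[chim_counts == 1]  # parents >> chimera
  flagged <- key[u$chimera]
  expect_gte(mean(chim_keys %in% flagged), 0.9)
  # no true barcode sequence is ever flagged
  true_keys <- unique(d$key[truth_by_id$origin %in%
                              c("true", "contaminant")])
  expect_length(intersect(true_keys, flagged), 0)
})
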