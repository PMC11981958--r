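test_that("dereplicate collapses identical reads per site-replicate", {
  rec <- data.frame(
    seq = c("ACGT", "ACGT", "ACGT", "TTTT", "ACGT"),
    sample = c("Y01_r1", "Y01_r1", "Y01_r1", "Y01_r1", "Y01_r2"),
    count = 1L)
  tab <- dereplicate(rec)
  expect_equal(nrow(tab$counts), 2L)
  acgt <- names(tab$sequences)[tab$sequences == "ACGT"]
  expect_equal(unname(tab$counts[acgt, "Y01_r1"]), 3L)
  expect_equal(unname(tab$counts[acgt, "Y01_r2"]), 1L)  # two nonzero cells
  expect_equal(sum(tab$counts), 5L)
})

test_that("cluster_d1 merges single-nucleotide neighbours onto the most abundant", {
  tab <- make_table(list(a = c(Y01_r1 = 10L), b = c(Y01_r1 = 2L)),
                    sequences = c(a = "AAAA", b = "AAAT"))
  out <- cluster_d1(tab)
  expect_equal(rownames(out$counts), "a")          # representative "AAAA"
  expect_equal(unname(out$counts["a", 1]), 12L)

  far <- make_table(list(a = c(Y01_r1 = 5L), b = c(Y01_r1 = 5L)),
                    sequences = c(a = "AAAA", b = "TTTT"))
  expect_equal(nrow(cluster_d1(far)$counts), 2L)   # distance 4: two clusters
})

test_that("cluster_d1 links chains transitively and merges one-indel pairs", {
  chain <- make_table(list(a = c(Y01_r1 = 9L), b = c(Y01_r1 = 3L),
                           c = c(Y01_r1 = 1L)),
                      sequences = c(a = "AAAA", b = "AAAT", c = "AATT"))
  out <- cluster_d1(chain)    # AAAA-AAAT-AATT: one cluster by single linkage
  expect_equal(nrow(out$counts), 1L)
  expect_equal(sum(out$counts), 13L)

  indel <- make_table(list(a = c(Y01_r1 = 6L), b = c(Y01_r1 = 1L)),
                      sequences = c(a = "ACGTA", b = "ACTA"))
  expect_equal(nrow(cluster_d1(indel)$counts), 1L)
})

test_that("cluster_d1 and lulu_curate conserve the grand total read count", {
  set.seed(21)
  for (rep in 1:5) {
    seqs <- replicate(12, rand_dna(30))
    counts <- lapply(seq_along(seqs), function(i) {
      c(Y01_r1 = rpois(1, 50), Y01_r2 = rpois(1, 50), T01_r1 = rpois(1, 50),
        T01_r2 = rpois(1, 50))
    })
    names(counts) <- sprintf("z%02d", seq_along(seqs))
    tab <- make_table(counts, sequences = setNames(seqs, names(counts)))
    expect_equal(sum(cluster_d1(tab)$counts), sum(tab$counts))
    expect_equal(sum(lulu_curate(tab)$counts), sum(tab$counts))
  }
})

test_that("filter_asvs applies the read/length/fish/frequency cascade once", {
  seqs <- c(keep = rand_dna(170), low = rand_dna(170), long = rand_dna(210),
            nonfish = rand_dna(170), rare = rand_dna(170))
  tab <- make_table(list(keep = c(Y01_r1 = 5000L),
                         low = c(Y01_r1 = 9L),       # < 10 reads
                         long = c(Y01_r1 = 4000L),   # 210 bp
                         nonfish = c(Y01_r1 = 3000L),
                         rare = c(Y01_r1 = 11L)),    # freq < 0.001
                    sequences = seqs)
  fish <- c(keep = TRUE, low = TRUE, long = TRUE, nonfish = FALSE,
            rare = TRUE)
  out <- filter_asvs(tab, fish)
  expect_equal(rownames(out$counts), "keep")
})

test_that("filter_asvs frequency uses the pre-filter grand total and ignores row order", {
  # 'rare' has freq 11/12020 < 0.001 against the pre-filter total even
  # though it would pass against the post-filter total
  seqs <- c(a = rand_dna(170), b = rand_dna(170), c = rand_dna(170))
  tab <- make_table(list(a = c(Y01_r1 = 6000L), b = c(Y01_r1 = 6009L),
                         c = c(Y01_r1 = 11L)),
                    sequences = seqs)
  fish <- c(a = TRUE, b = TRUE, c = TRUE)
  out <- filter_asvs(tab, fish)
  expect_setequal(rownames(out$counts), c("a", "b"))

  perm <- asv_table(tab$counts[c(3, 1, 2), , drop = FALSE],
                    sequences = tab$sequences)
  out_perm <- filter_asvs(perm, fish)
  expect_setequal(rownames(out_perm$counts), rownames(out$counts))
})

test_that("lulu_curate merges by identity, co-occurrence and abundance ratio", {
  base <- rand_dna(100)
  daughter <- mutate_k(base, 1)      # identity 0.99
  far <- mutate_k(base, 20)          # identity 0.80
  tab <- make_table(
    list(p = c(Y01_r1 = 100L, Y02_r1 = 80L, Y03_r1 = 60L),
         d = c(Y01_r1 = 10L, Y02_r1 = 8L, Y03_r1 = 0L),
         f = c(Y01_r1 = 50L, Y02_r1 = 50L, Y03_r1 = 50L)),
    sequences = c(p = base, d = daughter, f = far))
  out <- lulu_curate(tab)
  expect_setequal(rownames(out$counts), c("p", "f"))  # d merged, f kept
  expect_equal(unname(out$counts["p", "Y01_r1"]), 110L)
})

test_that("lulu_curate keeps daughters that occur where the parent is absent", {
  base <- rand_dna(100)
  daughter <- mutate_k(base, 1)
  tab <- make_table(
    list(p = c(Y01_r1 = 100L, Y02_r1 = 80L, Y03_r1 = 0L),
         d = c(Y01_r1 = 10L, Y02_r1 = 0L, Y03_r1 = 8L)),
    sequences = c(p = base, d = daughter))
  out <- lulu_curate(tab)    # co-occurrence 1/2 < 0.95
  expect_setequal(rownames(out$counts), c("p", "d"))
})

test_that("lulu_curate result does not depend on input row order", {
  set.seed(8)
  base <- rand_dna(120)
  tab <- make_table(
    list(a = c(Y01_r1 = 200L, Y02_r1 = 150L),
         b = c(Y01_r1 = 20L, Y02_r1 = 15L),
         c = c(Y01_r1 = 90L, Y02_r1 = 200L)),
    sequences = c(a = base, b = mutate_k(base, 2), c = mutate_k(base, 40)))
  out1 <- lulu_curate(tab)
  perm <- asv_table(tab$counts[c(2, 3, 1), ], sequences = tab$sequences)
  out2 <- lulu_curate(perm)
  expect_setequal(rownames(out1$counts), rownames(out2$counts))
  expect_equal(out1$counts[sort(rownames(out1$counts)), ],
               out2$counts[sort(rownames(out2$counts)), ])
})

test_that("replicate_filter requires detection in at least two replicates", {
  tab <- make_table(list(
    a = c(Y01_r1 = 5L, Y01_r2 = 3L, Y01_r3 = 0L),   # 2 of 3 -> present
    b = c(Y01_r1 = 7L, Y01_r2 = 0L, Y01_r3 = 0L),   # 1 of 3 -> absent
    c = c(Y01_r1 = 0L, Y01_r2 = 0L, Y01_r3 = 0L)))  # absent
  inc <- replicate_filter(tab)
  expect_equal(unname(inc["Y01", ]), c(1L, 0L, 0L))

  single <- make_table(list(a = c(Y01_r1 = 5L, Y02_r1 = 3L, Y02_r2 = 2L)))
  expect_error(replicate_filter(single), "Y01")
})

test_that("curation removes planted errors and recovers the true ASV set", {
  cfg <- sim_config(seed = 11)   # default conditions, 20% planted errors
  st <- simulate_study(cfg)
  expect_gt(nrow(st$asv$truth$daughters), 0)
  cur <- lulu_curate(cluster_d1(st$asv$table))
  expect_setequal(rownames(cur$counts), st$asv$truth$pool$asv_id)
  expect_equal(sum(cur$counts), sum(st$asv$table$counts))
})
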