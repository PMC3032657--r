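test_that("nucleotide diversity matches closed forms and the pair-loop oracle", {
  # two sequences of length 10 differing at 2 sites -> pi = 0.2
  aln <- toy_alignment(c("AAAAAAAAAA", "AAAAAAAAGG"))
  expect_equal(nucleotide_diversity(aln), 0.2)
  # identical sequences -> 0
  expect_equal(nucleotide_diversity(toy_alignment(c("ACGT", "ACGT"))), 0)
  # toy alignments equal the brute-force pairwise loop
  set.seed(42)
  for (rep in 1:5) {
    mat <- matrix(sample(c("A", "C", "G", "T", "N"), 6 * 30, replace = TRUE,
                         prob = c(.3, .3, .2, .15, .05)), 6, 30)
    aln <- toy_alignment(apply(mat, 1, paste, collapse = ""))
    expect_equal(nucleotide_diversity(aln), oracle_pi(mat))
    expect_equal(nucleotide_diversity(aln, per_site = FALSE),
                 oracle_pi(mat, per_site = FALSE))
  }
})

test_that("pi excludes gap columns per pair and honours region masks", {
  # the gap carrier is compared over its non-gap columns only
  mat <- rbind(c("A", "A", "A", "T"),
               c("A", "-", "-", "T"),
               c("A", "A", "A", "C"))
  aln <- toy_alignment(apply(mat, 1, paste, collapse = ""))
  expect_equal(nucleotide_diversity(aln), oracle_pi(mat))
  # exon mask restricts to annotated exon columns
  ann <- gene_annotation(data.frame(start = c(0, 4), end = c(4, 8),
                                    region = c("intron", "exon")), 0)
  aln <- toy_alignment(c("AAAATTTT", "CAAATTTG"), annotation = ann)
  expect_equal(nucleotide_diversity(aln), 2 / 8)
  expect_equal(nucleotide_diversity(aln, "exon"), 1 / 4)
  expect_error(nucleotide_diversity(aln, rep(FALSE, 8)), "no columns")
})

test_that("pi is invariant under row permutation", {
  seqs <- c("ACGTAC", "ACGAAC", "TCGTAC", "ACGTGC")
  p1 <- nucleotide_diversity(toy_alignment(seqs))
  p2 <- nucleotide_diversity(toy_alignment(seqs[c(3, 1, 4, 2)]))
  expect_equal(p1, p2)
})

test_that("haplotype_table counts haplotypes with indels as binary states", {
  # monomorphic -> one haplotype at frequency 1
  ht <- haplotype_table(toy_alignment(c("ACGT", "ACGT", "ACGT")))
  expect_equal(nrow(ht), 1L)
  expect_equal(ht$freq, 1)
  # all distinct -> each 0.25
  ht <- haplotype_table(toy_alignment(c("AATT", "AGTT", "CATT", "CGTT")))
  expect_equal(nrow(ht), 4L)
  expect_equal(ht$freq, rep(0.25, 4))
  expect_equal(sum(ht$freq), 1)
  # indel presence/absence distinguishes haplotypes with identical bases
  ht <- haplotype_table(toy_alignment(c("ACGTT", "A--TT", "ACGTT", "A--TT")))
  expect_equal(nrow(ht), 2L)
  expect_equal(ht$freq, c(0.5, 0.5))
})

test_that("haplotype_diversity matches Nei's formulas", {
  expect_equal(haplotype_diversity(1, 10)$Hd, 0)
  expect_equal(haplotype_diversity(rep(0.25, 4), 4)$Hd, 1)
  h <- haplotype_diversity(c(0.5, 0.5), 10)
  expect_equal(h$Hd, (10 / 9) * 0.5, tolerance = 1e-12)
  expect_equal(round(h$Hd, 4), 0.5556)
  expect_gt(h$sd, 0)
  expect_error(haplotype_diversity(1, 1), "n must be")
  expect_error(haplotype_diversity(c(0.6, 0.3), 10), "sum to 1")
})

test_that("tajimas_d reproduces a hand-computed constants oracle", {
  # n = 4 toy alignment with S = 2
  seqs <- c("AAAA", "AAAT", "GAAA", "AAAA")
  aln <- toy_alignment(seqs)
  res <- tajimas_d(aln)
  expect_equal(res$S, 2L)
  # independent recomputation, all constants spelled out
  n <- 4
  a1 <- 1 + 1 / 2 + 1 / 3
  a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  k <- oracle_pi(do.call(rbind, strsplit(seqs, "")), per_site = FALSE)
  S <- 2
  D_oracle <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(res$D, D_oracle, tolerance = 1e-12)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("tajimas_d flags S = 0 and zeroes the numerator when k = S/a1", {
  res <- tajimas_d(toy_alignment(c("ACGT", "ACGT", "ACGT", "AC-T")))
  expect_true(res$flagged)
  expect_true(is.na(res$D))
  # 2 of 6 pairs differ at the single segregating site -> k = 1/3... build a
  # case with k exactly S/a1 is contrived; instead check sign logic both ways
  bal <- tajimas_d(toy_alignment(c("AAAA", "AAAA", "TTAA", "TTAA")))
  expect_gt(bal$D, 0)       # intermediate-frequency variants
  sing <- tajimas_d(toy_alignment(c("AAAAAA", "TAAAAA", "ACAAAA", "AAGAAA",
                                    "AAATAA", "AAAACA")))
  expect_lt(sing$D, 0)      # singletons only
})

test_that("excess singletons drive D negative in most simulations", {
  neg <- 0; total <- 12
  for (s in seq_len(total)) {
    # star-like genealogy: many singleton rows on a common background
    n <- 12; L <- 120
    set.seed(1000 + s)
    mat <- matrix("A", n, L)
    for (i in seq_len(n)) {
      cols <- sample.int(L, 2)
      mat[i, cols] <- c("C", "G")
    }
    D <- tajimas_d(toy_alignment(apply(mat, 1, paste, collapse = "")))$D
    if (!is.na(D) && D < 0) neg <- neg + 1
  }
  expect_gte(neg / total, 0.9)
})

test_that("diversity_summary assembles consistent per-gene rows", {
  aln <- toy_alignment(c("AAATTTGGG", "AAAT--GGG", "AACTTTGGG", "AAATTTGGG",
                         "AACTTTGGG"))
  d <- diversity_summary(aln)
  expect_equal(d$S, 1L)
  expect_equal(d$n_indels, 1L)
  expect_equal(d$n_haplotypes, 3L)
  expect_equal(d$bp_per_snp, 9)
  expect_true(d$Hd >= 0 && d$Hd <= 1)
})
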