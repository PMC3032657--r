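test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_pops = 2L, pop_sizes = c(5L, 5L, 5L)),
               "pop_sizes")
  expect_error(sim_config(mu = 1.5), "is_prob")
  expect_s3_class(small_config(1), "sim_config")
})

test_that("mu = 0 yields monomorphic alignments and empty site tables", {
  st <- simulate_study(small_config(2, mu = 0, indel_mu = 0))
  for (aln in st$alignments) {
    expect_equal(nrow(call_sites(aln)), 0L)
  }
})

test_that("a fixed seed reproduces identical FASTA bytes", {
  cfg <- small_config(42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixtures(simulate_study(cfg), d1)
  write_fixtures(simulate_study(cfg), d2)
  for (f in list.files(file.path(d1, "genes"), pattern = "fasta$")) {
    expect_identical(readBin(file.path(d1, "genes", f), "raw", 1e6),
                     readBin(file.path(d2, "genes", f), "raw", 1e6))
  }
})

test_that("oversized sample requests name the offending population", {
  cfg <- small_config(1)
  cfg$pop_sizes <- c(12L, 99L)
  expect_error(simulate_study(cfg), "pop2.*99.*exceeds.*40")
})

test_that("fixtures round-trip through write_fixtures/read_study", {
  st <- simulate_study(small_config(9))
  dir <- withr::local_tempdir()
  write_fixtures(st, dir)
  back <- read_study(dir)
  expect_equal(names(back$alignments), names(st$alignments))
  for (g in names(st$alignments)) {
    expect_equal(back$alignments[[g]]$seqs, st$alignments[[g]]$seqs)
    expect_equal(back$alignments[[g]]$populations,
                 st$alignments[[g]]$populations)
    expect_equal(back$alignments[[g]]$annotation$intervals,
                 st$alignments[[g]]$annotation$intervals)
    expect_equal(back$alignments[[g]]$annotation$frame_offset,
                 st$alignments[[g]]$annotation$frame_offset)
  }
  expect_equal(back$ssr$calls, st$ssr$calls)
  expect_equal(back$ssr$populations, st$ssr$populations)
  expect_equal(back$populations, st$populations)
  expect_true(!is.null(back$truth))
})

test_that("annotation intervals are disjoint and cover each fragment", {
  st <- simulate_study(small_config(17, n_genes = 4L,
                                    gene_lengths = c(400L, 500L, 800L, 1300L)))
  for (aln in st$alignments) {
    iv <- aln$annotation$intervals
    expect_equal(iv$start[1], 0L)
    expect_equal(iv$end[nrow(iv)], ncol(aln$seqs))
    if (nrow(iv) > 1) expect_equal(iv$start[-1], iv$end[-nrow(iv)])
  }
})

test_that("call_sites recovers the simulated truth exactly", {
  # no dropout so every truth site segregates among emitted lines
  st <- simulate_study(small_config(23, line_dropout = 0))
  for (g in names(st$alignments)) {
    truth <- st$truth$genes[[g]]$sites
    called <- call_sites(st$alignments[[g]])
    expect_equal(sum(called$kind == "SNP"), sum(!truth$is_indel))
    expect_equal(sum(called$kind == "indel"), sum(truth$is_indel))
    expect_setequal(called$pos[called$kind == "SNP"],
                    truth$pos[!truth$is_indel])
    expect_setequal(called$pos[called$kind == "indel"],
                    truth$pos[truth$is_indel])
  }
})

test_that("haplotype inventory matches the generator's truth", {
  st <- simulate_study(small_config(29, line_dropout = 0, indel_mu = 0))
  for (g in names(st$alignments)) {
    truth_h <- st$truth$genes[[g]]$haplotypes
    n_truth <- length(unique(truth_h))
    ht <- haplotype_table(st$alignments[[g]])
    expect_equal(nrow(ht), n_truth)
  }
})

test_that("SNP density is monotone non-decreasing in mu over paired seeds", {
  wins <- 0; runs <- 6
  for (s in seq_len(runs)) {
    lo <- simulate_study(small_config(500 + s, mu = 2e-6, indel_mu = 0))
    hi <- simulate_study(small_config(500 + s, mu = 1.2e-5, indel_mu = 0))
    n_lo <- sum(vapply(lo$alignments,
                       function(a) nrow(call_sites(a)), numeric(1)))
    n_hi <- sum(vapply(hi$alignments,
                       function(a) nrow(call_sites(a)), numeric(1)))
    if (n_hi >= n_lo) wins <- wins + 1
  }
  expect_gte(wins / runs, 0.8)
})

test_that("zero migration with long divergence raises the among component", {
  # sequence-based AMOVA (haplotype mismatch distances) on the gene data,
  # where migration acts; paired seeds, isolated run should dominate
  seq_amova_pct <- function(st) {
    pct <- c()
    for (aln in st$alignments) {
      sites <- call_sites(aln)
      if (nrow(sites) < 2) next
      am <- allele_matrix(aln, sites)
      n <- nrow(am)
      D2 <- matrix(0, n, n, dimnames = list(rownames(am), rownames(am)))
      for (j in seq_len(ncol(am))) {
        m <- outer(am[, j], am[, j], "!=")
        m[is.na(m)] <- 0
        D2 <- D2 + m
      }
      res <- amova(D2, populations = aln$populations, n_perm = 10, seed = 1)
      pct <- c(pct, res$pct_among)
    }
    mean(pct)
  }
  wins <- 0; runs <- 3
  for (s in seq_len(runs)) {
    mig <- simulate_study(small_config(600 + s, n_generations = 250L,
                                       migration_rate = 0.05, mu = 2e-5,
                                       line_dropout = 0))
    iso <- simulate_study(small_config(600 + s, n_generations = 250L,
                                       migration_rate = 0, mu = 2e-5,
                                       line_dropout = 0))
    if (seq_amova_pct(iso) > seq_amova_pct(mig)) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("decay scatter lies on the curve when noiseless and is seeded", {
  d <- seq(10, 1000, by = 10)
  sc <- simulate_decay_scatter(0.01, 100, d, 0)
  expect_equal(sc$r2, hill_weir_expectation(0.01 * d, 100))
  s1 <- simulate_decay_scatter(0.01, 100, d, 0.05, seed = 3)
  s2 <- simulate_decay_scatter(0.01, 100, d, 0.05, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(s1$r2 >= 0 & s1$r2 <= 1))
  # very large gamma: everything at the large-C asymptote
  sc <- simulate_decay_scatter(50, 100, d, 0)
  expect_lt(max(sc$r2), hill_weir_expectation(50 * 10, 100) + 1e-12)
  expect_error(simulate_decay_scatter(0.01, 100, numeric(0), 0), "non-empty")
})

test_that("pi on neutral single-population runs tracks the theta expectation", {
  # haploid Wright-Fisher: theta = 2*N*mu, pairwise coalescence timescale N,
  # so the finite-horizon expectation is theta * (1 - exp(-G / N))
  N <- 50L; G <- 300L; mu <- 2e-5; L <- 500L
  theta <- 2 * N * mu
  expected <- theta * (1 - exp(-G / N))
  pis <- vapply(1:20, function(s) {
    st <- simulate_study(sim_config(
      n_pops = 1L, pop_sizes = 25L, n_genes = 1L, gene_lengths = L,
      mu = mu, n_generations = G, census_n = N, migration_rate = 0,
      n_ssr_loci = 2L, indel_mu = 0, line_dropout = 0, seed = 9000 + s))
    nucleotide_diversity(st$alignments[[1]])
  }, numeric(1))
  se <- stats::sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 3 * se + 0.1 * expected)
})
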