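# build an allele matrix with given two-locus haplotype counts
hap_am <- function(nAB, nAb, naB, nab) {
  rows <- c(rep("A/B", nAB), rep("A/b", nAb), rep("a/B", naB), rep("a/b", nab))
  am <- do.call(rbind, strsplit(rows, "/"))
  rownames(am) <- sprintf("L%03d", seq_len(nrow(am)))
  colnames(am) <- c("s1", "s2")
  am
}

test_that("r2 matches closed forms from haplotype counts", {
  # complete association
  ld <- ld_matrix(hap_am(25, 0, 0, 25))
  expect_equal(ld$r2[1, 2], 1)
  # independence
  ld <- ld_matrix(hap_am(25, 25, 25, 25))
  expect_equal(ld$r2[1, 2], 0)
  # AB=40 Ab=10 aB=10 ab=40: D = 0.4 - 0.25 = 0.15, r2 = 0.15^2/0.0625
  ld <- ld_matrix(hap_am(40, 10, 10, 40))
  expect_equal(ld$r2[1, 2], 0.36, tolerance = 1e-12)
  expect_equal(diag(ld$r2), c(s1 = 1, s2 = 1))
})

test_that("r2 equals the squared Pearson correlation of 0/1 codes", {
  set.seed(8)
  for (rep in 1:20) {
    counts <- stats::rmultinom(1, 60, runif(4) + 0.1)
    am <- hap_am(counts[1], counts[2], counts[3], counts[4])
    if (length(unique(am[, 1])) < 2 || length(unique(am[, 2])) < 2) next
    ld <- ld_matrix(am)
    r <- stats::cor(am[, 1] == "A", am[, 2] == "B")^2
    expect_equal(ld$r2[1, 2], r, tolerance = 1e-10)
  }
})

test_that("r2 is invariant to allele relabeling and row permutation", {
  am <- hap_am(40, 10, 10, 40)
  r_base <- ld_matrix(am)$r2[1, 2]
  relab <- am
  relab[relab == "A"] <- "T"; relab[relab == "a"] <- "G"
  expect_equal(ld_matrix(relab)$r2[1, 2], r_base)
  perm <- am[sample(nrow(am)), ]
  expect_equal(ld_matrix(perm)$r2[1, 2], r_base)
})

test_that("monomorphic sites violate the filter contract", {
  am <- hap_am(10, 10, 0, 0)   # second site monomorphic
  expect_error(ld_matrix(am), "monomorphic")
})

test_that("multiallelic composite r2 behaves and fisher p is NA there", {
  am <- cbind(a = c("150", "150", "152", "152", "154", "154"),
              b = c("200", "200", "202", "202", "204", "204"))
  rownames(am) <- sprintf("L%02d", 1:6)
  ld <- ld_matrix(am)
  # composite formula, computed by hand: with 3 equifrequent alleles in
  # perfect association, D_ii = 2/9 and D_ij = -1/9, so
  # sum(D^2) = 3*(2/9)^2 + 6*(1/9)^2 = 2/9 and the denominator is
  # (1 - 1/3)^2 = 4/9, giving r2 = 1/2
  expect_equal(ld$r2[1, 2], 0.5, tolerance = 1e-12)
  expect_true(is.na(ld$p_fisher[1, 2]))            # multiallelic pair
})

test_that("fisher_ld_test equals full hypergeometric enumeration", {
  t1 <- matrix(c(3, 0, 0, 3), 2)
  expect_equal(fisher_ld_test(t1), 0.1, tolerance = 1e-9)
  expect_equal(fisher_ld_test(t1), oracle_fisher(t1), tolerance = 1e-9)
  t2 <- matrix(c(25, 25, 25, 25), 2)
  expect_equal(fisher_ld_test(t2), 1)
  set.seed(3)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_ld_test(tab), oracle_fisher(tab), tolerance = 1e-8)
    expect_equal(fisher_ld_test(tab), fisher_ld_test(t(tab)[2:1, 2:1]),
                 tolerance = 1e-12)   # swap rows and columns
  }
})

test_that("gene_mean_r2 averages the upper triangle and returns NA when empty", {
  am <- cbind(hap_am(20, 5, 5, 20), s3 = rep(c("C", "T"), 25))
  ld <- ld_matrix(am, positions = c(0, 100, 250), genes = rep("g", 3))
  pr <- ld_pairs(ld)
  expect_equal(nrow(pr), 3L)
  expect_equal(gene_mean_r2(ld), mean(pr$r2), tolerance = 1e-12)
  expect_equal(pr$distance_bp, c(100, 250, 150))
  # single site -> no pair -> NA
  single <- ld_matrix(hap_am(20, 5, 5, 20)[, 1, drop = FALSE])
  expect_true(is.na(gene_mean_r2(single)))
})

test_that("intergenic r2: self-consistency, null level, disjoint lines", {
  am1 <- hap_am(30, 10, 10, 30)
  # same gene twice reproduces the intra-genic values
  r12 <- ld_matrix(am1)$r2[1, 2]
  res <- intergenic_r2(list(g1 = am1, g2 = am1))
  expect_equal(res$mean_r2, mean(c(1, r12, r12, 1)), tolerance = 1e-10)
  # independent simulated genes decay to the null expectation
  set.seed(21)
  n <- 120
  mk <- function() {
    am <- cbind(s1 = sample(c("A", "G"), n, TRUE),
                s2 = sample(c("C", "T"), n, TRUE))
    rownames(am) <- sprintf("L%03d", seq_len(n)); am
  }
  res <- intergenic_r2(list(g1 = mk(), g2 = mk()))
  expect_lte(res$mean_r2, 2 / (n - 1) + 0.05)
  # disjoint line sets -> error
  am2 <- am1; rownames(am2) <- paste0("X", seq_len(nrow(am2)))
  expect_error(intergenic_r2(list(g1 = am1, g2 = am2)), "shared lines")
})

test_that("unlinked SSR loci show null-scale mean r2", {
  st <- simulate_study(small_config(31, n_ssr_loci = 15L,
                                    pop_sizes = c(30L, 30L)))
  r2 <- ssr_r2_values(st$ssr)
  n <- length(st$ssr$line_ids)
  expect_lte(mean(r2, na.rm = TRUE), 2 / (n - 1) + 0.05)
})
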