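# In-code fixtures shared across test files.

# alignment from a character vector of equal-length strings; default
# annotation is a single exon covering the fragment, frame 0
toy_alignment <- function(seqs, populations = rep("pop1", length(seqs)),
                          annotation = NULL, gene_id = "toy",
                          line_ids = sprintf("L%02d", seq_along(seqs))) {
  if (is.null(annotation)) {
    annotation <- gene_annotation(
      data.frame(start = 0, end = nchar(seqs[1]), region = "exon"), 0)
  }
  haplotype_alignment(gene_id, seqs, line_ids, populations, annotation)
}

# small, fast simulation settings for property tests
small_config <- function(seed, ...) {
  args <- list(n_pops = 2L, pop_sizes = c(12L, 12L), n_genes = 2L,
               gene_lengths = c(400L, 600L), n_generations = 150L,
               census_n = 40L, n_ssr_loci = 10L, line_dropout = 0,
               mu = 2e-5, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# single-population neutral config used for Tajima-D calibration tests
neutral_config <- function(seed, n_lines = 30L, L = 600L, G = 400L, N = 60L) {
  sim_config(n_pops = 1L, pop_sizes = n_lines, n_genes = 1L,
             gene_lengths = L, n_generations = G, census_n = N,
             mu = 2e-5, migration_rate = 0, n_ssr_loci = 2L, indel_mu = 0,
             line_dropout = 0, seed = seed)
}

# brute-force nucleotide diversity: explicit O(n^2 L) pair loop
oracle_pi <- function(mat, per_site = TRUE) {
  n <- nrow(mat)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- mat[i, ]; b <- mat[j, ]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!any(ok)) next
    d <- sum(a[ok] != b[ok])
    vals <- c(vals, if (per_site) d / sum(ok) else d)
  }
  mean(vals)
}

# brute-force allelic richness: enumerate every subsample of size n
oracle_richness <- function(counts, n) {
  pool <- rep(seq_along(counts), counts)
  combs <- utils::combn(length(pool), n)
  mean(apply(combs, 2, function(idx) length(unique(pool[idx]))))
}

# two-sided Fisher p by full hypergeometric enumeration on fixed margins
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    exp(lchoose(c1, a) + lchoose(N - c1, r1 - a) - lchoose(N, r1))
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
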