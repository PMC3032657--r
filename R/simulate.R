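#' Simulation configuration
#'
#' Parameters of the forward-time Wright-Fisher generator that produces
#' study-shaped synthetic inputs: five populations of unequal size sampled
#' from larger breeding populations, around a dozen gene fragments of 0.4-1.4
#' kb accumulating infinite-sites SNPs and rare single-event indels with
#' intra-genic recombination, and a panel of unlinked multiallelic SSR loci.
#'
#' Defaults encode the emulated survey: samples of 33/44/15/41/68 lines (201
#' total) from five populations, eleven fragments with the survey's lengths,
#' a per-site mutation rate calibrated so the pooled sample segregates about
#' one SNP per 50 bp, an indel rate giving roughly 0-2 indels per gene,
#' recombination strong enough that intra-genic LD decays within hundreds of
#' bp, migration tuned for moderate differentiation (about 13%
#' among-population variance), and 37 SSR loci with 2-18 alleles each.
#'
#' @param n_pops number of populations.
#' @param pop_sizes lines sampled per population (length `n_pops`).
#' @param n_genes number of gene fragments.
#' @param gene_lengths fragment lengths in bp (length `n_genes`).
#' @param mu per-site per-generation mutation probability.
#' @param rec_per_bp per-bp per-meiosis recombination probability.
#' @param n_generations forward generations simulated. The default follows
#'   the equilibrium rule `G = 2.5 * n_pops * census_n`: the emulated
#'   populations are long-established, and the decay analysis assumes
#'   mutation-drift-recombination equilibrium, which the metapopulation only
#'   approaches on the scale of its total (coalescent) size.
#' @param migration_rate per-generation probability that a parent is drawn
#'   from another population.
#' @param n_ssr_loci number of unlinked SSR loci.
#' @param ssr_allele_range integer (min, max) allele counts per SSR locus.
#' @param census_n haploid census size of each simulated population (the
#'   sample `pop_sizes` are drawn from this without replacement).
#' @param indel_mu per-gene per-generation indel mutation probability.
#' @param line_dropout per-gene probability that a line failed amplification
#'   (row absent from that gene's alignment).
#' @param ssr_fst target differentiation of SSR allele frequencies.
#' @param ssr_missing per-call missing probability in the SSR table.
#' @param seed integer; fully determines the output.
#' @return `sim_config` list.
#' @export
sim_config <- function(n_pops = 5L,
                       pop_sizes = c(33L, 44L, 15L, 41L, 68L),
                       n_genes = 11L,
                       gene_lengths = c(619L, 495L, 1371L, 623L, 754L,
                                        560L, 502L, 435L, 514L, 1224L, 542L),
                       mu = 3.4e-6,
                       rec_per_bp = 6e-5,
                       n_generations = 1250L,
                       migration_rate = 0.016,
                       n_ssr_loci = 37L,
                       ssr_allele_range = c(2L, 18L),
                       census_n = 100L,
                       indel_mu = 1e-4,
                       line_dropout = 0.1,
                       ssr_fst = 0.13,
                       ssr_missing = 0.02,
                       seed = 1L) {
  stopifnot(is_count(n_pops), n_pops >= 1,
            length(pop_sizes) == n_pops, all(pop_sizes >= 1),
            is_count(n_genes), length(gene_lengths) == n_genes,
            is_prob(mu), is_prob(rec_per_bp), is_count(n_generations),
            is_prob(migration_rate), is_count(n_ssr_loci),
            length(ssr_allele_range) == 2L,
            ssr_allele_range[1] >= 1, ssr_allele_range[2] >= ssr_allele_range[1],
            is_count(census_n), is_prob(indel_mu), is_prob(line_dropout),
            is_prob(ssr_fst), is_prob(ssr_missing),
            is_count(abs(as.integer(seed))))
  structure(list(
    n_pops = as.integer(n_pops), pop_sizes = as.integer(pop_sizes),
    n_genes = as.integer(n_genes), gene_lengths = as.integer(gene_lengths),
    mu = mu, rec_per_bp = rec_per_bp,
    n_generations = as.integer(n_generations),
    migration_rate = migration_rate,
    n_ssr_loci = as.integer(n_ssr_loci),
    ssr_allele_range = as.integer(ssr_allele_range),
    census_n = as.integer(census_n), indel_mu = indel_mu,
    line_dropout = line_dropout, ssr_fst = ssr_fst,
    ssr_missing = ssr_missing, seed = as.integer(seed)),
    class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# random fragment structure: disjoint 5'UTR/exon/intron/3'UTR intervals
# covering [0, L), with a random frame offset for the first exon base
random_annotation <- function(L) {
  cuts <- integer(0); regions <- character(0)
  pos <- 0L
  if (stats::runif(1) < 0.5 && L >= 150L) {
    u5 <- as.integer(stats::runif(1, 0.10, 0.25) * L)
    cuts <- rbind(cuts, c(pos, pos + u5)); regions <- c(regions, "5UTR")
    pos <- pos + u5
  }
  u3 <- if (stats::runif(1) < 0.3 && L - pos >= 200L) {
    as.integer(stats::runif(1, 0.05, 0.15) * L)
  } else 0L
  coding_end <- L - u3
  if (stats::runif(1) < 0.35 && coding_end - pos >= 240L) {
    e1 <- as.integer(stats::runif(1, 0.25, 0.45) * (coding_end - pos))
    il <- as.integer(stats::runif(1, 0.15, 0.30) * (coding_end - pos))
    cuts <- rbind(cuts, c(pos, pos + e1), c(pos + e1, pos + e1 + il),
                  c(pos + e1 + il, coding_end))
    regions <- c(regions, "exon", "intron", "exon")
  } else {
    cuts <- rbind(cuts, c(pos, coding_end))
    regions <- c(regions, "exon")
  }
  if (u3 > 0L) {
    cuts <- rbind(cuts, c(coding_end, L)); regions <- c(regions, "3UTR")
  }
  gene_annotation(data.frame(start = cuts[, 1], end = cuts[, 2],
                             region = regions),
                  sample(0:2, 1L))
}

# does substituting `alt` at 0-based position `pos0` create a stop codon in
# the reference reading frame? (used to keep simulated exons nonsense-free)
creates_ref_stop <- function(ref, pos0, alt, idx_map, cds_cols) {
  ci <- idx_map[pos0 + 1L]
  if (is.na(ci)) return(FALSE)
  codon_start <- ((ci - 1L) %/% 3L) * 3L + 1L
  span <- codon_start:(codon_start + 2L)
  if (max(span) > length(cds_cols)) return(FALSE)
  codon <- ref[cds_cols[span]]
  codon[(ci - 1L) %% 3L + 1L] <- alt
  unname(Biostrings::GENETIC_CODE[paste(codon, collapse = "")]) == "*"
}

# Forward-time Wright-Fisher for one gene across all populations.
# State: per-pop logical matrices (census x segregating sites) of derived
# alleles, shared site registry (positions, derived bases, indel spec).
simulate_gene <- function(L, config, annotation) {
  P <- config$n_pops; N <- config$census_n
  G <- config$n_generations
  mu_gene <- config$mu * L
  rec_gene <- config$rec_per_bp * L
  ref <- sample(BASES, L, replace = TRUE)
  idx_map <- cds_index_map(annotation, L)
  cds_cols <- order(idx_map, na.last = NA)
  # the reference coding sequence must be an open reading frame: replace any
  # stop codon by a random sense codon
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  n_codon <- length(cds_cols) %/% 3L
  for (k in seq_len(n_codon)) {
    cols <- cds_cols[(3L * (k - 1L) + 1L):(3L * k)]
    if (gc[paste(ref[cols], collapse = "")] == "*") {
      ref[cols] <- strsplit(sample(sense, 1L), "")[[1L]]
    }
  }

  pos <- integer(0)       # 1-based anchor positions
  alt <- character(0)     # derived base ("-" for indels)
  is_indel <- logical(0)
  indel_len <- integer(0)
  M <- replicate(P, matrix(FALSE, N, 0L), simplify = FALSE)

  add_site <- function(pop, row, p1, a, indel, len) {
    pos <<- c(pos, p1); alt <<- c(alt, a)
    is_indel <<- c(is_indel, indel); indel_len <<- c(indel_len, len)
    for (q in seq_len(P)) {
      newcol <- matrix(FALSE, N, 1L)
      if (q == pop) newcol[row, 1L] <- TRUE
      M[[q]] <<- cbind(M[[q]], newcol)
    }
  }

  prune <- function() {
    if (!length(pos)) return()
    tot <- Reduce(`+`, lapply(M, colSums))
    keep <- tot > 0L & tot < P * N
    if (all(keep)) return()
    pos <<- pos[keep]; alt <<- alt[keep]
    is_indel <<- is_indel[keep]; indel_len <<- indel_len[keep]
    for (q in seq_len(P)) M[[q]] <<- M[[q]][, keep, drop = FALSE]
  }

  for (g in seq_len(G)) {
    Mnew <- vector("list", P)
    for (p in seq_len(P)) {
      src_pop <- rep.int(p, N)
      if (P > 1L && config$migration_rate > 0) {
        mig <- stats::runif(N) < config$migration_rate
        if (any(mig)) {
          others <- setdiff(seq_len(P), p)
          src_pop[mig] <- others[sample.int(length(others), sum(mig),
                                            replace = TRUE)]
        }
      }
      p1 <- sample.int(N, N, replace = TRUE)
      rows <- matrix(FALSE, N, length(pos))
      for (q in unique(src_pop)) {
        sel <- src_pop == q
        rows[sel, ] <- M[[q]][p1[sel], , drop = FALSE]
      }
      nx <- stats::rpois(N, rec_gene)
      for (i in which(nx > 0L)) {
        p2 <- sample.int(N, 1L)
        other <- M[[src_pop[i]]][p2, ]
        bp <- sort(sample.int(L - 1L, min(nx[i], L - 1L)))
        take_first <- findInterval(pos, bp) %% 2L == 0L
        rows[i, !take_first] <- other[!take_first]
      }
      Mnew[[p]] <- rows
    }
    M <- Mnew
    # new point mutations (infinite sites: occupied positions resampled)
    for (p in seq_len(P)) {
      nm <- stats::rpois(1L, N * mu_gene)
      for (k in seq_len(nm)) {
        for (try in 1:5) {
          p1b <- sample.int(L, 1L)
          if (!p1b %in% pos) break
          p1b <- NA_integer_
        }
        if (is.na(p1b)) next
        a <- sample(setdiff(BASES, ref[p1b]), 1L)
        if (creates_ref_stop(ref, p1b - 1L, a, idx_map, cds_cols)) next
        add_site(p, sample.int(N, 1L), p1b, a, FALSE, NA_integer_)
      }
      ni <- stats::rpois(1L, N * config$indel_mu)
      for (k in seq_len(ni)) {
        len <- sample(c(1L, 2L, 3L, 200L), 1L, prob = c(0.4, 0.3, 0.2, 0.1))
        if (len >= L) len <- 2L
        for (try in 1:8) {
          anchor <- sample.int(L - len, 1L)
          span <- anchor:(anchor + len - 1L)
          clash <- any(vapply(which(is_indel), function(s) {
            max(anchor, pos[s]) <= min(anchor + len - 1L,
                                       pos[s] + indel_len[s] - 1L) + 1L
          }, logical(1))) || anchor %in% pos
          if (!clash) break
          anchor <- NA_integer_
        }
        if (is.na(anchor)) next
        add_site(p, sample.int(N, 1L), anchor, "-", TRUE, len)
      }
    }
    if (g %% 20L == 0L) prune()
  }
  prune()
  list(ref = ref, pos = pos, alt = alt, is_indel = is_indel,
       indel_len = indel_len, M = M, annotation = annotation)
}

# render sampled rows of a simulated gene into an aligned character matrix
render_gene <- function(sim, sample_rows, line_ids) {
  L <- length(sim$ref)
  n <- length(line_ids)
  mat <- matrix(rep(sim$ref, each = n), n, L, dimnames = list(line_ids, NULL))
  carried <- do.call(rbind, sample_rows)   # n x S logical
  if (length(sim$pos)) {
    for (s in seq_along(sim$pos)) {
      who <- carried[, s]
      if (!any(who)) next
      if (sim$is_indel[s]) {
        span <- sim$pos[s]:(sim$pos[s] + sim$indel_len[s] - 1L)
        mat[who, span] <- "-"
      } else {
        mat[who, sim$pos[s]] <- sim$alt[s]
      }
    }
  }
  mat
}

#' Simulate a complete study with known ground truth
#'
#' Runs the forward-time Wright-Fisher model (symmetric migration, intra-genic
#' recombination, infinite-sites SNPs, rare atomic indels stored as
#' presence/absence at an anchor) for every gene, samples the final generation
#' without replacement to the configured per-population sizes, and draws
#' unlinked multiallelic SSR genotypes from per-population Dirichlet allele
#' frequencies (one haploid call per line per locus).
#'
#' @param config a [sim_config()].
#' @return `synthetic_study` list: `alignments` (list of
#'   [haplotype_alignment()]), `ssr` (an [ssr_matrix()]), `populations`
#'   (line_id/population table) and `truth` (per-gene site/haplotype ground
#'   truth, SSR allele frequencies, and the gamma-equivalent recombination
#'   intensity `4 * total census * rec_per_bp`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bad <- which(config$pop_sizes > config$census_n)
  if (length(bad)) {
    stopf("population pop%d: requested sample %d exceeds simulated census %d",
          bad[1L], config$pop_sizes[bad[1L]], config$census_n)
  }
  with_seed(config$seed, {
    P <- config$n_pops
    pop_names <- sprintf("pop%d", seq_len(P))
    n_total <- sum(config$pop_sizes)
    line_ids <- sprintf("L%03d", seq_len(n_total))
    line_pops <- rep(pop_names, config$pop_sizes)
    pop_table <- data.frame(line_id = line_ids, population = line_pops,
                            stringsAsFactors = FALSE)

    alignments <- vector("list", config$n_genes)
    gene_truth <- vector("list", config$n_genes)
    gene_ids <- sprintf("gene%02d", seq_len(config$n_genes))
    for (g in seq_len(config$n_genes)) {
      L <- config$gene_lengths[g]
      ann <- random_annotation(L)
      sim <- simulate_gene(L, config, ann)
      sampled <- vector("list", P)
      for (p in seq_len(P)) {
        idx <- sample.int(config$census_n, config$pop_sizes[p])
        sampled[[p]] <- sim$M[[p]][idx, , drop = FALSE]
      }
      carried <- do.call(rbind, sampled)
      # keep only sites segregating in the emitted sample
      seg <- colSums(carried) > 0L & colSums(carried) < n_total
      sim$pos <- sim$pos[seg]; sim$alt <- sim$alt[seg]
      sim$is_indel <- sim$is_indel[seg]; sim$indel_len <- sim$indel_len[seg]
      carried <- carried[, seg, drop = FALSE]
      mat <- render_gene(sim, list(carried), line_ids)
      # per-gene amplification failure: drop lines, keeping >= 2 per pop
      present <- stats::runif(n_total) >= config$line_dropout
      for (p in pop_names) {
        sel <- which(line_pops == p)
        if (sum(present[sel]) < 2L) {
          present[sel[seq_len(min(2L, length(sel)))]] <- TRUE
        }
      }
      alignments[[g]] <- haplotype_alignment(
        gene_ids[g], mat[present, , drop = FALSE],
        line_ids[present], line_pops[present], ann)
      hap_key <- if (ncol(carried)) {
        apply(carried, 1L, paste, collapse = "")
      } else rep("", n_total)
      gene_truth[[g]] <- list(
        gene_id = gene_ids[g],
        sites = data.frame(pos = sim$pos - 1L, derived = sim$alt,
                           is_indel = sim$is_indel,
                           indel_length = sim$indel_len,
                           stringsAsFactors = FALSE),
        haplotypes = stats::setNames(hap_key, line_ids),
        emitted = line_ids[present],
        annotation = ann)
    }

    # --- unlinked SSR loci -------------------------------------------------
    amin <- config$ssr_allele_range[1L]; amax <- config$ssr_allele_range[2L]
    loci <- sprintf("ssr%02d", seq_len(config$n_ssr_loci))
    chrom <- sprintf("%dR", (seq_len(config$n_ssr_loci) - 1L) %% 7L + 1L)
    calls <- matrix(NA_integer_, n_total, config$n_ssr_loci,
                    dimnames = list(line_ids, loci))
    ssr_freqs <- vector("list", config$n_ssr_loci)
    theta_f <- (1 - config$ssr_fst) / config$ssr_fst
    for (l in seq_len(config$n_ssr_loci)) {
      k <- min(amax, max(amin, stats::rgeom(1L, 0.22) + amin))
      sizes <- sample(80:300, 1L) + 2L * (seq_len(k) - 1L)
      base_p <- stats::rgamma(k, 0.8); base_p <- base_p / sum(base_p)
      pop_p <- lapply(seq_len(P), function(p) {
        x <- stats::rgamma(k, base_p * theta_f + 1e-6)
        x / sum(x)
      })
      for (p in seq_len(P)) {
        sel <- which(line_pops == pop_names[p])
        calls[sel, l] <- sizes[sample.int(k, length(sel), replace = TRUE,
                                          prob = pop_p[[p]])]
      }
      miss <- stats::runif(n_total) < config$ssr_missing
      calls[miss, l] <- NA_integer_
      ssr_freqs[[l]] <- do.call(rbind, pop_p)
      dimnames(ssr_freqs[[l]]) <- list(pop_names, as.character(sizes))
    }
    ssr <- ssr_matrix(calls, line_ids, line_pops,
                      data.frame(locus = loci, linkage_group = chrom,
                                 stringsAsFactors = FALSE))

    structure(list(
      alignments = stats::setNames(alignments, gene_ids),
      ssr = ssr, populations = pop_table,
      truth = list(genes = stats::setNames(gene_truth, gene_ids),
                   ssr_freqs = stats::setNames(ssr_freqs, loci),
                   # haploid gametes: the coalescent-scale recombination
                   # intensity is 2 * (haploid census) * c per bp, the
                   # analogue of Gamma = 4Nc for diploid census N
                   gamma_per_bp = 2 * P * config$census_n * config$rec_per_bp,
                   config = config)),
      class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d genes, %d lines, %d SSR loci, %d population(s)\n",
              length(x$alignments), nrow(x$populations),
              length(x$ssr$loci), length(unique(x$populations$population))))
  invisible(x)
}

#' Simulate an LD-decay scatter with known gamma
#'
#' Draws `(distance, r2)` points on the Hill-Weir sample-size-adjusted
#' expectation curve `E[r2 | C = gamma_per_bp * d, n]` plus Gaussian noise,
#' clipped to `[0, 1]`; used for fit-recovery testing of [fit_gamma()].
#'
#' @param gamma_per_bp true recombination intensity per bp (> 0).
#' @param n sample size entering the expectation.
#' @param distances vector of pair distances in bp (non-empty).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return data.frame with `distance` and `r2`.
#' @export
simulate_decay_scatter <- function(gamma_per_bp, n, distances, noise_sd = 0,
                                   seed = NULL) {
  if (!length(distances)) stopf("distances must be non-empty")
  stopifnot(gamma_per_bp > 0, noise_sd >= 0)
  with_seed(seed, {
    mu <- hill_weir_expectation(gamma_per_bp * distances, n)
    r2 <- mu + stats::rnorm(length(distances), 0, noise_sd)
    data.frame(distance = distances, r2 = pmin(pmax(r2, 0), 1))
  })
}
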