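#' Nucleotide diversity (pi)
#'
#' Average number of nucleotide differences per site between two sequences,
#' over all unordered pairs of rows. Comparisons use per-pair deletion: a
#' column contributes to a pair's numerator/denominator only when both rows
#' carry an unambiguous nucleotide there, so alignment gaps (indel states) and
#' `N`s are excluded from both. A region mask restricts the computation, e.g.
#' to exons.
#'
#' @param alignment a [haplotype_alignment()] with >= 2 rows.
#' @param region_mask `NULL` (whole fragment), a region name such as `"exon"`
#'   (resolved against the alignment's annotation), or a logical vector over
#'   alignment columns.
#' @param per_site if `FALSE`, return the mean pairwise difference count
#'   (the quantity entering Tajima's D) instead of the per-site value.
#' @return Nucleotide diversity (per site unless `per_site = FALSE`).
#' @export
nucleotide_diversity <- function(alignment, region_mask = NULL, per_site = TRUE) {
  mat <- alignment$seqs
  n <- nrow(mat)
  if (n < 2L) stopf("need at least 2 rows")
  L <- ncol(mat)
  mask <- resolve_mask(alignment, region_mask, L)
  if (!any(mask)) stopf("region mask selects no columns")
  sub <- mat[, mask, drop = FALSE]
  V <- sub %in% c("A", "C", "G", "T")
  dim(V) <- dim(sub)
  comp <- tcrossprod(V * 1)                      # comparable length per pair
  # difference counts accumulate only over polymorphic columns
  D <- matrix(0, n, n)
  for (j in seq_len(ncol(sub))) {
    col <- sub[, j]
    valid <- V[, j]
    if (length(unique(col[valid])) < 2L) next
    colv <- ifelse(valid, col, NA)
    diff <- outer(colv, colv, "!=")
    diff[is.na(diff)] <- FALSE
    D <- D + diff
  }
  ut <- upper.tri(comp)
  comp_u <- comp[ut]; d_u <- D[ut]
  ok <- comp_u > 0
  if (!any(ok)) stopf("no comparable sites for any pair")
  if (per_site) mean(d_u[ok] / comp_u[ok]) else mean(d_u[ok])
}

resolve_mask <- function(alignment, region_mask, L) {
  if (is.null(region_mask)) return(rep(TRUE, L))
  if (is.logical(region_mask)) {
    stopifnot(length(region_mask) == L)
    return(region_mask)
  }
  if (is.character(region_mask)) {
    iv <- alignment$annotation$intervals
    mask <- rep(FALSE, L)
    for (k in which(iv$region %in% region_mask)) {
      mask[(iv$start[k] + 1L):iv$end[k]] <- TRUE
    }
    return(mask)
  }
  stopf("region_mask must be NULL, logical, or region name(s)")
}

#' Haplotype inventory over polymorphic sites
#'
#' A haplotype is the allele vector over all polymorphic sites of a gene,
#' with indels contributing as binary presence/absence states. Rows missing
#' at any polymorphic site are excluded, so frequencies sum to 1 over the
#' retained lines. A monomorphic gene has a single haplotype at frequency 1.
#'
#' @param alignment a [haplotype_alignment()].
#' @param sites optional pre-computed `site_table` (default [call_sites()]).
#' @return data.frame with `haplotype` (allele string), `count`, `freq`,
#'   sorted by decreasing frequency; attributes `n` (lines retained) and
#'   `assignment` (per retained line, the haplotype row index).
#' @export
haplotype_table <- function(alignment, sites = call_sites(alignment)) {
  if (!nrow(sites)) {
    out <- data.frame(haplotype = "", count = nrow(alignment$seqs), freq = 1)
    attr(out, "n") <- nrow(alignment$seqs)
    attr(out, "assignment") <- stats::setNames(
      rep(1L, nrow(alignment$seqs)), alignment$line_ids)
    return(out)
  }
  am <- allele_matrix(alignment, sites)
  keep <- rowSums(is.na(am)) == 0L
  am <- am[keep, , drop = FALSE]
  if (!nrow(am)) stopf("no line is complete over the polymorphic sites")
  hap <- apply(am, 1L, paste, collapse = "/")
  tab <- sort(table(hap), decreasing = TRUE)
  out <- data.frame(haplotype = names(tab), count = as.integer(tab),
                    freq = as.integer(tab) / length(hap),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- length(hap)
  attr(out, "assignment") <- stats::setNames(match(hap, out$haplotype),
                                             rownames(am))
  out
}

#' Haplotype diversity (Hd) with standard deviation
#'
#' The sample-size-corrected probability that two randomly chosen haplotypes
#' differ: `Hd = n/(n-1) * (1 - sum(p_i^2))`. The standard deviation follows
#' Nei's (1987) variance of heterozygosity, the convention of standard
#' sequence-analysis software.
#'
#' @param freqs haplotype relative frequencies (must sum to 1).
#' @param n number of sequences the frequencies were estimated from (>= 2).
#' @return list with `Hd` and `sd`.
#' @export
haplotype_diversity <- function(freqs, n) {
  if (!is_count(n) || n < 2) stopf("n must be an integer >= 2")
  if (abs(sum(freqs) - 1) > 1e-8) stopf("frequencies must sum to 1")
  s2 <- sum(freqs^2); s3 <- sum(freqs^3)
  hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = hd, sd = sqrt(max(v, 0)))
}

# Tajima's (1989) a1,a2,b1,b2,c1,c2,e1,e2 constants for sample size n.
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D with beta-distribution significance
#'
#' D contrasts the mean pairwise difference count (an estimate of theta from
#' pi) with the segregating-site count `S` scaled by `1/a1`, normalised by
#' the standard error from Tajima's (1989) constants. Only SNP sites enter
#' `S` and the pairwise differences; indel sites are excluded. The two-sided
#' p-value uses Tajima's beta approximation on `[Dmin, Dmax]`.
#'
#' A gene with `S = 0` has no defined D; a flagged `NA` result is returned
#' rather than a guess.
#'
#' @param alignment a [haplotype_alignment()] with >= 4 rows.
#' @return list with `D`, `p`, `S`, `k` (mean pairwise differences), `n`,
#'   and `flagged` (`TRUE` when `S = 0`).
#' @export
tajimas_d <- function(alignment) {
  n <- nrow(alignment$seqs)
  if (n < 4L) stopf("need at least 4 sequences")
  sites <- call_sites(alignment)
  S <- sum(sites$kind == "SNP")
  if (S == 0L) {
    return(list(D = NA_real_, p = NA_real_, S = 0L, k = 0, n = n, flagged = TRUE))
  }
  k <- nucleotide_diversity(alignment, per_site = FALSE)
  cst <- tajima_constants(n)
  D <- (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  Dmin <- (2 / n - 1 / cst$a1) / sqrt(cst$e2)
  Dmax <- (n / (2 * (n - 1)) - 1 / cst$a1) / sqrt(cst$e2)
  alpha <- -(1 + Dmin * Dmax) * Dmax / (Dmax - Dmin)
  beta <- (1 + Dmin * Dmax) * Dmin / (Dmax - Dmin)
  x <- (D - Dmin) / (Dmax - Dmin)
  p <- if (x <= 0 || x >= 1) 0 else {
    cdf <- stats::pbeta(x, beta, alpha)
    2 * min(cdf, 1 - cdf)
  }
  list(D = D, p = min(max(p, .Machine$double.eps), 1), S = S, k = k, n = n,
       flagged = FALSE)
}

#' Per-gene diversity summary
#'
#' Assembles the per-gene row of the survey's summary table: fragment length,
#' line count, segregating sites, nucleotide diversity (whole fragment and
#' exon-restricted), haplotype count and diversity, Tajima's D, and the SNP
#' density expressed as base pairs per SNP.
#'
#' @param alignment a [haplotype_alignment()].
#' @param sites optional pre-computed (classified) `site_table`.
#' @return one-row data.frame.
#' @export
diversity_summary <- function(alignment, sites = NULL) {
  if (is.null(sites)) {
    sites <- classify_effects(call_sites(alignment), alignment)
  }
  L <- ncol(alignment$seqs)
  n <- nrow(alignment$seqs)
  S <- sum(sites$kind == "SNP")
  has_exon <- any(alignment$annotation$intervals$region == "exon")
  pi_all <- nucleotide_diversity(alignment)
  pi_exon <- if (has_exon) nucleotide_diversity(alignment, "exon") else NA_real_
  ht <- haplotype_table(alignment, sites)
  hd <- haplotype_diversity(ht$freq, attr(ht, "n"))
  td <- if (n >= 4L) tajimas_d(alignment) else
    list(D = NA_real_, p = NA_real_, flagged = TRUE)
  data.frame(
    gene_id = alignment$gene_id, length_bp = L, n_lines = n, S = S,
    n_snps_nonsyn = sum(sites$kind == "SNP" &
                          !is.na(sites$coding_effect) &
                          sites$coding_effect == "non-synonymous"),
    n_indels = sum(sites$kind == "indel"),
    pi = pi_all, pi_exon = pi_exon,
    n_haplotypes = nrow(ht), Hd = hd$Hd, Hd_sd = hd$sd,
    tajima_D = td$D, tajima_p = td$p, tajima_flagged = td$flagged,
    bp_per_snp = if (S > 0) L / S else NA_real_,
    stringsAsFactors = FALSE)
}
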