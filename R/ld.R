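# Pairwise linkage disequilibrium on phase-known haploid data. Because phase
# is observed (one gamete per line), D is countable directly from haplotype
# frequencies; no EM estimator is needed. The multiallelic composite
#   r2 = sum_ij D_ij^2 / [(1 - sum p_i^2)(1 - sum q_j^2)]
# reduces exactly to D^2/(pA pa pB pb) in the biallelic case, so one formula
# serves SNPs, indels and SSR alleles alike.

r2_from_table <- function(tab) {
  n <- sum(tab)
  P <- tab / n
  p <- rowSums(P); q <- colSums(P)
  D <- P - outer(p, q)
  denom <- (1 - sum(p^2)) * (1 - sum(q^2))
  if (denom <= 0) return(NA_real_)
  sum(D^2) / denom
}

#' Fisher's exact test for a biallelic site pair
#'
#' Two-sided exact hypergeometric p-value of the 2x2 table of joint haplotype
#' counts. Multiallelic pairs are not supported here and yield `NA` in
#' [ld_matrix()].
#'
#' @param tab 2x2 matrix of joint haplotype counts.
#' @return two-sided p-value.
#' @export
fisher_ld_test <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  stats::fisher.test(tab)$p.value
}

#' Pairwise LD matrix over filtered polymorphic sites
#'
#' Computes `r2` for every pair of sites (haplotype counts from
#' pairwise-complete rows), Fisher's exact p for biallelic pairs, and the
#' physical distance for pairs on the same gene. Sites must be pre-filtered
#' for minor-allele frequency ([filter_maf()]); a column that is monomorphic
#' across the supplied rows violates that contract and raises an error.
#'
#' @param am character allele matrix (lines x sites), e.g. from
#'   [allele_matrix()] or an SSR call matrix.
#' @param positions optional per-site bp positions (for distances).
#' @param genes optional per-site gene labels; distance is defined only for
#'   pairs on the same gene.
#' @return `ld_matrix` list with symmetric matrices `r2`, `p_fisher`,
#'   `distance_bp`, `n` (pairwise-complete row counts), plus `labels`,
#'   `positions`, `genes`.
#' @export
ld_matrix <- function(am, positions = NULL, genes = NULL) {
  stopifnot(is.matrix(am))
  S <- ncol(am)
  labels <- colnames(am)
  if (is.null(labels)) labels <- paste0("site", seq_len(S))
  for (j in seq_len(S)) {
    v <- am[, j]
    if (length(unique(v[!is.na(v)])) < 2L) {
      stopf("site '%s' is monomorphic: filter contract violated", labels[j])
    }
  }
  r2 <- matrix(NA_real_, S, S, dimnames = list(labels, labels))
  pf <- matrix(NA_real_, S, S, dimnames = list(labels, labels))
  nn <- matrix(NA_integer_, S, S, dimnames = list(labels, labels))
  dd <- matrix(NA_real_, S, S, dimnames = list(labels, labels))
  diag(r2) <- 1
  if (S >= 2L) for (i in 1:(S - 1L)) for (j in (i + 1L):S) {
    ok <- !is.na(am[, i]) & !is.na(am[, j])
    nn[i, j] <- nn[j, i] <- sum(ok)
    if (sum(ok) < 2L) next
    tab <- table(am[ok, i], am[ok, j])
    if (min(dim(tab)) < 2L) next   # monomorphic within complete rows: r2 undefined
    r2[i, j] <- r2[j, i] <- r2_from_table(tab)
    if (all(dim(tab) == c(2L, 2L))) {
      pf[i, j] <- pf[j, i] <- stats::fisher.test(tab)$p.value
    }
    if (!is.null(genes) && !is.null(positions) && genes[i] == genes[j]) {
      dd[i, j] <- dd[j, i] <- abs(positions[i] - positions[j])
    } else if (is.null(genes) && !is.null(positions)) {
      dd[i, j] <- dd[j, i] <- abs(positions[i] - positions[j])
    }
  }
  structure(list(labels = labels, positions = positions, genes = genes,
                 r2 = r2, p_fisher = pf, distance_bp = dd, n = nn),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d sites, mean off-diagonal r2 = %.3f\n",
              length(x$labels), mean(x$r2[upper.tri(x$r2)], na.rm = TRUE)))
  invisible(x)
}

#' Long-format pair table from an LD matrix
#'
#' @param ld an [ld_matrix()].
#' @return data.frame: `site_i`, `site_j`, `gene_i`, `gene_j`, `distance_bp`,
#'   `r2`, `p_fisher`, `n`.
#' @export
ld_pairs <- function(ld) {
  S <- length(ld$labels)
  if (S < 2L) {
    return(data.frame(site_i = character(0), site_j = character(0),
                      gene_i = character(0), gene_j = character(0),
                      distance_bp = numeric(0), r2 = numeric(0),
                      p_fisher = numeric(0), n = integer(0)))
  }
  idx <- which(upper.tri(ld$r2), arr.ind = TRUE)
  data.frame(
    site_i = ld$labels[idx[, 1L]], site_j = ld$labels[idx[, 2L]],
    gene_i = if (is.null(ld$genes)) NA_character_ else ld$genes[idx[, 1L]],
    gene_j = if (is.null(ld$genes)) NA_character_ else ld$genes[idx[, 2L]],
    distance_bp = ld$distance_bp[idx], r2 = ld$r2[idx],
    p_fisher = ld$p_fisher[idx], n = ld$n[idx],
    stringsAsFactors = FALSE)
}

#' Mean intra-genic r2
#'
#' Unweighted mean over the upper triangle of within-gene pairs. With fewer
#' than two filtered sites there is no pair and the result is `NA`
#' (reported as "n.a.").
#'
#' @param ld an [ld_matrix()].
#' @param gene optional gene label to restrict to (default: all within-gene
#'   pairs, or all pairs when the matrix carries no gene labels).
#' @return mean r2, or `NA_real_`.
#' @export
gene_mean_r2 <- function(ld, gene = NULL) {
  pr <- ld_pairs(ld)
  if (!is.null(gene)) {
    pr <- pr[!is.na(pr$gene_i) & pr$gene_i == gene & pr$gene_j == gene, ]
  } else if (!is.null(ld$genes)) {
    pr <- pr[!is.na(pr$gene_i) & pr$gene_i == pr$gene_j, ]
  }
  if (!nrow(pr) || all(is.na(pr$r2))) return(NA_real_)
  mean(pr$r2, na.rm = TRUE)
}

#' Mean inter-genic r2
#'
#' Mean r2 over all cross-gene site pairs, computed on the lines shared by
#' the genes involved (pairwise-complete within that intersection). A warning
#' is attached when fewer than 10 lines are shared.
#'
#' @param ams named list of filtered allele matrices, one per gene (rownames
#'   are line ids).
#' @return list with `mean_r2`, `n_pairs`, `n_shared_lines`, and the
#'   underlying [ld_matrix()].
#' @export
intergenic_r2 <- function(ams) {
  stopifnot(is.list(ams), length(ams) >= 2L)
  shared <- Reduce(intersect, lapply(ams, rownames))
  if (length(shared) < 2L) stopf("fewer than 2 shared lines across genes")
  if (length(shared) < 10L) warnf("only %d shared lines", length(shared))
  gene_names <- names(ams)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_along(ams))
  combined <- do.call(cbind, lapply(ams, function(m) m[shared, , drop = FALSE]))
  genes <- rep(gene_names, vapply(ams, ncol, integer(1)))
  colnames(combined) <- paste0(genes, ".", colnames(combined))
  ld <- ld_matrix(combined, genes = genes,
                  positions = rep(0, ncol(combined)))
  pr <- ld_pairs(ld)
  cross <- pr[pr$gene_i != pr$gene_j, ]
  list(mean_r2 = mean(cross$r2, na.rm = TRUE), n_pairs = nrow(cross),
       n_shared_lines = length(shared), ld = ld)
}

#' SSR pairwise r2 values
#'
#' All pairwise composite r2 values among SSR loci (pairwise-complete lines),
#' the input for the unlinked-marker LD threshold.
#'
#' @param ssr an [ssr_matrix()].
#' @param lines optional subset of line ids.
#' @return numeric vector of r2 values, one per locus pair.
#' @export
ssr_r2_values <- function(ssr, lines = NULL) {
  calls <- ssr$calls
  if (!is.null(lines)) calls <- calls[lines, , drop = FALSE]
  mode(calls) <- "character"
  poly <- vapply(seq_len(ncol(calls)), function(j) {
    length(unique(calls[!is.na(calls[, j]), j])) >= 2L
  }, logical(1))
  ld <- ld_matrix(calls[, poly, drop = FALSE])
  ld$r2[upper.tri(ld$r2)]
}
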