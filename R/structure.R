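#' DICE similarity matrix
#'
#' `s = 2a / (2a + b + c)` on binary presence/absence profiles, where `a`
#' counts shared presences and `b`, `c` one-sided presences. Self-similarity
#' is 1; a profile with no presences has undefined similarity (`NA`, with a
#' warning).
#'
#' @param X binary matrix, lines x features (SSR alleles or gene haplotypes
#'   encoded as presence/absence; see [ssr_binary()] and
#'   [haplotype_binary()]).
#' @return symmetric similarity matrix.
#' @export
dice_matrix <- function(X) {
  stopifnot(is.matrix(X))
  X <- (X > 0) * 1
  a <- tcrossprod(X)
  rs <- rowSums(X)
  denom <- outer(rs, rs, "+")
  s <- 2 * a / denom
  if (any(rs == 0)) {
    warnf("%d all-zero profile(s): similarities set to NA", sum(rs == 0))
    s[rs == 0, ] <- NA_real_
    s[, rs == 0] <- NA_real_
  }
  diag(s) <- ifelse(rs > 0, 1, NA_real_)
  dimnames(s) <- list(rownames(X), rownames(X))
  s
}

#' Binary allele-presence encoding of an SSR matrix
#'
#' One feature per (locus, allele); a line's feature is 1 when it carries
#' that allele. Missing calls leave all of a locus' features 0 for the line.
#'
#' @param ssr an [ssr_matrix()].
#' @return binary matrix, lines x features.
#' @export
ssr_binary <- function(ssr) {
  cols <- list()
  for (l in seq_along(ssr$loci)) {
    calls <- ssr$calls[, l]
    alleles <- sort(unique(calls[!is.na(calls)]))
    block <- sapply(alleles, function(a) as.integer(!is.na(calls) & calls == a))
    colnames(block) <- paste0(ssr$loci[l], ":", alleles)
    cols[[l]] <- block
  }
  out <- do.call(cbind, cols)
  rownames(out) <- ssr$line_ids
  out
}

#' Binary haplotype-presence encoding of candidate genes
#'
#' One feature per (gene, haplotype); a line's feature is 1 when it carries
#' that haplotype. Lines missing from a gene (or incomplete over its
#' polymorphic sites) have all of that gene's features 0.
#'
#' @param alignments list of [haplotype_alignment()] objects.
#' @param line_ids the full set of line ids to encode rows for.
#' @return binary matrix, lines x features.
#' @export
haplotype_binary <- function(alignments, line_ids) {
  cols <- list()
  for (aln in alignments) {
    ht <- haplotype_table(aln)
    assign <- attr(ht, "assignment")
    block <- matrix(0L, length(line_ids), nrow(ht),
                    dimnames = list(line_ids,
                                    paste0(aln$gene_id, ":h", seq_len(nrow(ht)))))
    present <- intersect(names(assign), line_ids)
    block[cbind(match(present, line_ids), assign[present])] <- 1L
    cols[[length(cols) + 1L]] <- block
  }
  do.call(cbind, cols)
}

#' Principal co-ordinate analysis
#'
#' Classical metric scaling: Gower double-centering of `-D^2/2`, followed by
#' eigendecomposition. Coordinates are eigenvectors scaled by the square root
#' of their (positive) eigenvalues; per-axis percent variance uses positive
#' eigenvalues only.
#'
#' @param D square symmetric distance matrix with zero diagonal (e.g.
#'   `1 - dice_matrix(X)`).
#' @return `pcoa_result` list: `coordinates` (lines x axes), `eigenvalues`
#'   (all), `pct_variance` (per retained axis).
#' @export
pcoa <- function(D) {
  stopifnot(is.matrix(D))
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stopf("distance matrix must be square and symmetric")
  }
  if (max(abs(diag(D))) > 1e-8) stopf("distance matrix must have zero diagonal")
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- eg$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  coords <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]),
                                                    length(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords, eigenvalues = ev,
                 pct_variance = 100 * ev[pos] / sum(ev[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3L, ncol(x$coordinates))
  cat(sprintf("pcoa_result: %d points, first axes explain %s%%\n",
              nrow(x$coordinates),
              paste(sprintf("%.1f", x$pct_variance[seq_len(k)]), collapse = "/")))
  invisible(x)
}

# squared inter-line distance for AMOVA: allele mismatch count across loci,
# scaled to the full locus count when calls are missing
ssr_sq_distance <- function(ssr) {
  calls <- ssr$calls
  n <- nrow(calls); L <- ncol(calls)
  D2 <- matrix(0, n, n, dimnames = list(ssr$line_ids, ssr$line_ids))
  ok <- !is.na(calls)
  shared <- tcrossprod(ok * 1)
  mism <- matrix(0, n, n)
  for (l in seq_len(L)) {
    v <- calls[, l]
    m <- outer(v, v, "!=")
    m[is.na(m)] <- 0
    mism <- mism + m
  }
  scale <- ifelse(shared > 0, L / shared, NA)
  D2 <- mism * scale
  D2[shared == 0] <- NA
  diag(D2) <- 0
  D2
}

#' Two-level AMOVA with permutation test
#'
#' Excoffier-style analysis of molecular variance on haploid SSR profiles:
#' squared distances are allele mismatch counts across loci, partitioned
#' among and within populations. Variance components use the unequal-sample
#' coefficient `n0`; `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`
#' is tested by permuting whole individuals among populations, with the
#' `(1 + #{Phi_perm >= Phi_obs}) / (n_perm + 1)` correction.
#'
#' @param ssr an [ssr_matrix()] (or a pre-computed squared-distance matrix).
#' @param populations population labels (default taken from `ssr`).
#' @param n_perm number of permutations (default 15000).
#' @param seed integer seed.
#' @return `amova_result` list: `table` (df, SSD, MS), `sigma2_among`,
#'   `sigma2_within`, `pct_among`, `pct_within`, `phi_st`, `p_perm`,
#'   `n_perm`.
#' @export
amova <- function(ssr, populations = NULL, n_perm = 15000, seed = NULL) {
  if (inherits(ssr, "ssr_matrix")) {
    if (is.null(populations)) populations <- ssr$populations
    D2 <- ssr_sq_distance(ssr)
  } else {
    D2 <- ssr
    if (is.null(populations)) stopf("populations required with a distance matrix")
  }
  N <- nrow(D2)
  populations <- as.character(populations)
  stopifnot(length(populations) == N)
  sizes <- table(populations)
  if (length(sizes) < 2L) stopf("need >= 2 populations")
  if (any(sizes < 2L)) {
    stopf("population '%s' has fewer than 2 lines",
          names(sizes)[which(sizes < 2L)[1L]])
  }
  pops <- names(sizes)
  ssd_within_for <- function(idx_by_pop) {
    s <- 0
    for (k in seq_along(idx_by_pop)) {
      idx <- idx_by_pop[[k]]
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ssd_total <- sum(D2) / (2 * N)
  obs_idx <- split(seq_len(N), populations)
  ssd_within <- ssd_within_for(obs_idx)
  ssd_among <- ssd_total - ssd_within
  df_among <- length(pops) - 1L
  df_within <- N - length(pops)
  ms_among <- ssd_among / df_among
  ms_within <- ssd_within / df_within
  n0 <- (N - sum(sizes^2) / N) / df_among
  s2_within <- ms_within
  s2_among <- (ms_among - ms_within) / n0
  total <- s2_among + s2_within
  phi <- s2_among / total
  phi_perm <- function(idx_by_pop) {
    ssd_w <- ssd_within_for(idx_by_pop)
    ms_a <- (ssd_total - ssd_w) / df_among
    ms_w <- ssd_w / df_within
    ((ms_a - ms_w) / n0) / (((ms_a - ms_w) / n0) + ms_w)
  }
  hits <- with_seed(seed, {
    h <- 0L
    sz <- as.integer(sizes)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(N)
      idx <- split(perm, rep(seq_along(sz), sz))
      if (phi_perm(idx) >= phi - 1e-12) h <- h + 1L
    }
    h
  })
  p <- (1 + hits) / (n_perm + 1)
  structure(list(
    table = data.frame(
      source = c("among populations", "within populations", "total"),
      df = c(df_among, df_within, N - 1L),
      SSD = c(ssd_among, ssd_within, ssd_total),
      MS = c(ms_among, ms_within, NA)),
    sigma2_among = s2_among, sigma2_within = s2_within,
    pct_among = 100 * s2_among / total, pct_within = 100 * s2_within / total,
    phi_st = phi, p_perm = p, n_perm = n_perm),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("Phi_ST = %.4f (%.1f%% among, %.1f%% within), p = %.4g (%d perms)\n",
              x$phi_st, x$pct_among, x$pct_within, x$p_perm, x$n_perm))
  invisible(x)
}
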