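#' SSR genotype matrix
#'
#' Lines x loci single-allele (haploid) microsatellite calls with population
#' labels and an optional linkage-group label per locus. Allele labels are
#' integer fragment sizes; `NA` marks a missing call.
#'
#' @param calls integer (or character) matrix, lines x loci.
#' @param line_ids unique line ids (default rownames).
#' @param populations population label per line.
#' @param loci_info optional data.frame with columns `locus` and
#'   `linkage_group` (defaults to column names, all groups `NA`).
#' @return An object of class `ssr_matrix`.
#' @export
ssr_matrix <- function(calls, line_ids = rownames(calls), populations,
                       loci_info = NULL) {
  stopifnot(is.matrix(calls))
  if (is.null(line_ids)) stopf("line_ids required")
  if (anyDuplicated(line_ids)) stopf("duplicated line ids")
  if (length(populations) != nrow(calls)) stopf("one population per line required")
  if (is.null(loci_info)) {
    loci_info <- data.frame(locus = colnames(calls),
                            linkage_group = NA_character_,
                            stringsAsFactors = FALSE)
  }
  stopifnot(nrow(loci_info) == ncol(calls))
  if (any(colSums(!is.na(calls)) == 0L)) stopf("locus with no non-missing call")
  rownames(calls) <- line_ids
  colnames(calls) <- loci_info$locus
  structure(list(calls = calls, line_ids = as.character(line_ids),
                 populations = as.character(populations),
                 loci = loci_info$locus, loci_info = loci_info),
            class = "ssr_matrix")
}

#' @export
print.ssr_matrix <- function(x, ...) {
  cat(sprintf("ssr_matrix: %d lines x %d loci, %d population(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$populations))))
  invisible(x)
}

#' Polymorphic information content (PIC)
#'
#' Botstein et al. (1980): `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#' A monomorphic locus has PIC 0.
#'
#' @param counts allele counts (or relative frequencies) at one locus.
#' @return PIC in `[0, 1)`.
#' @export
pic <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stopf("no alleles")
  p <- counts / sum(counts)
  s2 <- sum(p^2); s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4) / 2 * 2   # sum_{i<j} 2 p_i^2 p_j^2 = (s2^2 - s4)
}

# vectorised PIC over columns of a frequency matrix (alleles x replicates)
pic_cols <- function(P) {
  s2 <- colSums(P^2); s4 <- colSums(P^4)
  1 - s2 - (s2^2 - s4)
}

#' Bootstrap confidence interval for a locus PIC
#'
#' Percentile interval over `B` resamples of the non-missing calls at the
#' locus (multinomial resampling of calls, equivalent to resampling lines
#' with replacement at a single locus).
#'
#' @param ssr an [ssr_matrix()].
#' @param locus locus name or index.
#' @param B bootstrap replicates (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `estimate`, `low`, `high`, `sd`.
#' @export
pic_bootstrap_ci <- function(ssr, locus, B = 10000, level = 0.95, seed = NULL) {
  calls <- ssr$calls[, locus]
  calls <- calls[!is.na(calls)]
  if (length(calls) < 2L) stopf("need >= 2 non-missing calls")
  tab <- table(calls)
  est <- pic(as.integer(tab))
  if (length(tab) == 1L) {
    return(list(estimate = 0, low = 0, high = 0, sd = 0))
  }
  n <- length(calls)
  boot <- with_seed(seed, {
    cnt <- stats::rmultinom(B, n, as.integer(tab) / n)
    pic_cols(cnt / n)
  })
  q <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  list(estimate = est, low = q[1L], high = q[2L], sd = stats::sd(boot))
}

#' Rarefaction-based allelic richness
#'
#' Expected number of distinct alleles in a subsample of `n` of the `N`
#' sampled genotypes: `Rs = sum_i [1 - choose(N - N_i, n) / choose(N, n)]`,
#' computed with log-gamma binomials (`choose(N - N_i, n) = 0` when
#' `N - N_i < n`). `n = N` returns the observed allele count; `n = 1` returns
#' 1 for any locus.
#'
#' @param counts allele counts `N_i` (sum `N`).
#' @param n rarefaction subsample size, `1 <= n <= N`.
#' @return expected allele count `Rs`.
#' @export
allelic_richness <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (!is_count(n) || n < 1 || n > N) stopf("n must be in [1, N = %d]", N)
  miss <- ifelse(N - counts < n, 0, exp(lchoose(N - counts, n) - lchoose(N, n)))
  sum(1 - miss)
}

#' Private alleles per population
#'
#' An allele is private when observed in exactly one population. The
#' percentage denominator is the population's total count of distinct
#' observed alleles summed over loci.
#'
#' @param ssr an [ssr_matrix()] with >= 2 populations.
#' @return data.frame: `population`, `n_private`, `n_alleles_observed`,
#'   `pct_private`.
#' @export
private_alleles <- function(ssr) {
  pops <- unique(ssr$populations)
  if (length(pops) < 2L) stopf("need >= 2 populations")
  n_priv <- stats::setNames(numeric(length(pops)), pops)
  n_obs <- stats::setNames(numeric(length(pops)), pops)
  for (l in seq_along(ssr$loci)) {
    calls <- ssr$calls[, l]
    ok <- !is.na(calls)
    seen <- table(ssr$populations[ok], calls[ok]) > 0
    for (p in pops) n_obs[p] <- n_obs[p] + sum(seen[p, ])
    priv <- colSums(seen) == 1L
    for (a in which(priv)) {
      owner <- rownames(seen)[which(seen[, a])]
      n_priv[owner] <- n_priv[owner] + 1
    }
  }
  data.frame(population = pops, n_private = as.integer(n_priv[pops]),
             n_alleles_observed = as.integer(n_obs[pops]),
             pct_private = 100 * n_priv[pops] / n_obs[pops],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-population SSR diversity summary
#'
#' For each population: line count, private alleles (count and percentage),
#' mean observed alleles per locus with range, mean PIC with a bootstrap
#' standard deviation (lines resampled within the population), and mean
#' rarefaction-based allelic richness. The rarefaction size defaults, per
#' locus, to the smallest per-population count of non-missing calls.
#'
#' @param ssr an [ssr_matrix()].
#' @param rarefaction_n fixed rarefaction size, or `NULL` for the per-locus
#'   minimum across populations.
#' @param bootstrap_B bootstrap replicates for the PIC standard deviation.
#' @param seed integer seed.
#' @return data.frame, one row per population plus a `Mean` row.
#' @export
ssr_summary <- function(ssr, rarefaction_n = NULL, bootstrap_B = 10000,
                        seed = NULL) {
  pops <- unique(ssr$populations)
  priv <- private_alleles(ssr)
  L <- length(ssr$loci)
  # per-locus minimum per-population sample size (Fstat convention)
  n_by_pop_locus <- sapply(seq_len(L), function(l) {
    vapply(pops, function(p) {
      sum(!is.na(ssr$calls[ssr$populations == p, l]))
    }, numeric(1))
  })                         # pops x loci
  rows <- with_seed(seed, lapply(pops, function(p) {
    sel <- ssr$populations == p
    a_per_locus <- numeric(L); rs <- numeric(L); pic_l <- numeric(L)
    boot_means <- matrix(NA_real_, bootstrap_B, L)
    for (l in seq_len(L)) {
      calls <- ssr$calls[sel, l]
      calls <- calls[!is.na(calls)]
      tab <- as.integer(table(calls))
      a_per_locus[l] <- length(tab)
      pic_l[l] <- pic(tab)
      rn <- if (is.null(rarefaction_n)) max(1L, min(n_by_pop_locus[, l]))
            else min(rarefaction_n, sum(tab))
      rs[l] <- allelic_richness(tab, rn)
      if (length(tab) > 1L) {
        cnt <- stats::rmultinom(bootstrap_B, sum(tab), tab / sum(tab))
        boot_means[, l] <- pic_cols(cnt / sum(tab))
      } else boot_means[, l] <- 0
    }
    data.frame(population = p, n_lines = sum(sel),
               n_private = priv$n_private[priv$population == p],
               pct_private = priv$pct_private[priv$population == p],
               mean_alleles = mean(a_per_locus),
               min_alleles = min(a_per_locus),
               max_alleles = max(a_per_locus),
               PIC = mean(pic_l),
               PIC_sd = stats::sd(rowMeans(boot_means)),
               allelic_richness = mean(rs),
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  mean_row <- data.frame(population = "Mean", n_lines = NA_integer_,
                         n_private = mean(out$n_private),
                         pct_private = NA_real_,
                         mean_alleles = mean(out$mean_alleles),
                         min_alleles = NA_integer_, max_alleles = NA_integer_,
                         PIC = mean(out$PIC), PIC_sd = NA_real_,
                         allelic_richness = mean(out$allelic_richness),
                         stringsAsFactors = FALSE)
  rbind(out, mean_row)
}

#' Per-locus SSR detail table
#'
#' Pooled-sample statistics per locus: observed alleles, PIC with bootstrap
#' CI, and allelic richness at the smallest per-population sample size.
#'
#' @inheritParams ssr_summary
#' @param bootstrap_B bootstrap replicates for the PIC interval.
#' @return data.frame, one row per locus.
#' @export
ssr_locus_table <- function(ssr, rarefaction_n = NULL, bootstrap_B = 10000,
                            seed = NULL) {
  pops <- unique(ssr$populations)
  rows <- lapply(seq_along(ssr$loci), function(l) {
    calls <- ssr$calls[, l]
    tab <- as.integer(table(calls[!is.na(calls)]))
    rn <- if (is.null(rarefaction_n)) {
      max(1L, min(vapply(pops, function(p) {
        sum(!is.na(ssr$calls[ssr$populations == p, l]))
      }, numeric(1))))
    } else min(rarefaction_n, sum(tab))
    ci <- pic_bootstrap_ci(ssr, l, B = bootstrap_B,
                           seed = if (is.null(seed)) NULL else seed + l)
    data.frame(locus = ssr$loci[l],
               linkage_group = ssr$loci_info$linkage_group[l],
               n_calls = sum(tab), n_alleles = length(tab),
               PIC = ci$estimate, PIC_low = ci$low, PIC_high = ci$high,
               Rs = allelic_richness(tab, rn),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
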