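# Counting-based dN/dS (Nei & Gojobori 1986) with Jukes-Cantor correction.
#
# Synonymous/non-synonymous site counts are fractional per codon (share of the
# three possible changes at each position that are synonymous); substitutions
# between codons differing at several positions are averaged over all mutational
# pathways with equal weight, excluding pathways through stop codons when any
# stop-free pathway exists. Changes to or from stop codons count as
# non-synonymous.

codon_universe <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# per-codon fractional synonymous site count
.codon_syn_sites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    out <- numeric(64)
    names(out) <- codon_universe()
    for (cod in names(out)) {
      if (gc[cod] == "*") { out[cod] <- NA_real_; next }
      s <- 0
      sp <- strsplit(cod, "")[[1L]]
      for (pos in 1:3) {
        for (alt in setdiff(bases, sp[pos])) {
          mut <- sp; mut[pos] <- alt
          mutc <- paste(mut, collapse = "")
          if (gc[mutc] != "*" && gc[mutc] == gc[cod]) s <- s + 1 / 3
        }
      }
      out[cod] <- s
    }
    cache <<- out
    cache
  }
})

# pathway-averaged (syn, nonsyn) substitution counts between two codons
.codon_path_cache <- new.env(parent = emptyenv())
codon_path_stats <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- if (c1 < c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- .codon_path_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- Biostrings::GENETIC_CODE
  s1 <- strsplit(c1, "")[[1L]]; s2 <- strsplit(c2, "")[[1L]]
  diff_pos <- which(s1 != s2)
  perms <- if (length(diff_pos) == 1L) list(diff_pos) else {
    if (length(diff_pos) == 2L) {
      list(diff_pos, rev(diff_pos))
    } else {
      idx <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
      idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 3L), ]
      lapply(seq_len(nrow(idx)), function(i) diff_pos[unlist(idx[i, ])])
    }
  }
  eval_path <- function(order_pos) {
    cur <- s1; sd <- 0; nd <- 0; through_stop <- FALSE
    for (pos in order_pos) {
      nxt <- cur; nxt[pos] <- s2[pos]
      aa1 <- gc[paste(cur, collapse = "")]
      aa2 <- gc[paste(nxt, collapse = "")]
      if (aa2 == "*" || aa1 == "*") through_stop <- TRUE
      if (aa1 == aa2 && aa1 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, through_stop = through_stop)
  }
  res <- lapply(perms, eval_path)
  # "through stop" means an intermediate codon is a stop; endpoints are
  # handled by the caller (stop endpoints are rejected upstream)
  ok <- !vapply(res, `[[`, logical(1), "through_stop")
  if (any(ok)) res <- res[ok]
  out <- c(sd = mean(vapply(res, `[[`, numeric(1), "sd")),
           nd = mean(vapply(res, `[[`, numeric(1), "nd")))
  .codon_path_cache[[key]] <- out
  out
}

# Split the spliced, frame-trimmed coding sequence into codon strings per row;
# codons containing gaps or Ns become NA (skipped pairwise).
cds_codon_matrix <- function(alignment, annotation = alignment$annotation) {
  idx <- cds_index_map(annotation, ncol(alignment$seqs))
  cds_cols <- order(idx, na.last = NA)
  n_codon <- length(cds_cols) %/% 3L
  if (n_codon == 0L) return(matrix(character(0), nrow(alignment$seqs), 0))
  cds_cols <- cds_cols[seq_len(n_codon * 3L)]
  sub <- alignment$seqs[, cds_cols, drop = FALSE]
  n <- nrow(sub)
  out <- matrix(NA_character_, n, n_codon,
                dimnames = list(alignment$line_ids, NULL))
  for (k in seq_len(n_codon)) {
    cols <- (3L * (k - 1L) + 1L):(3L * k)
    trip <- sub[, cols, drop = FALSE]
    ok <- rowSums(matrix(trip %in% c("A", "C", "G", "T"), n)) == 3L
    out[ok, k] <- paste0(trip[ok, 1L], trip[ok, 2L], trip[ok, 3L])
  }
  out
}

# Unique codon-haplotype patterns with multiplicities, plus the pair table
# (pattern i, pattern j, number of sequence pairs). Identical-sequence pairs
# are retained: they contribute zero differences but enter the pairwise means.
unique_pair_table <- function(codons) {
  key <- apply(codons, 1L, paste, collapse = "|")
  tab <- table(key)
  pat <- match(names(tab), key)
  cnt <- as.integer(tab)
  H <- length(pat)
  pairs <- list()
  for (i in seq_len(H)) {
    if (cnt[i] >= 2L) {
      pairs[[length(pairs) + 1L]] <- c(i, i, choose(cnt[i], 2L))
    }
    if (i < H) for (j in (i + 1L):H) {
      pairs[[length(pairs) + 1L]] <- c(i, j, cnt[i] * cnt[j])
    }
  }
  list(rows = pat, weights = do.call(rbind, pairs))
}

# Jukes-Cantor multiple-hit correction. The transform is undefined for
# proportions >= 3/4, which cannot occur for realistic within-species data
# but does for degenerate toys (e.g. a single codon with one synonymous
# substitution and half a synonymous site); those fall back to the capped
# uncorrected proportion so ratios such as omega = 0 stay well defined.
jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * pmax(p, 0) / 3), pmin(p, 1))
}

#' Counting-based dN/dS for a gene fragment
#'
#' Nei-Gojobori (1986) pathway counting over all unordered sequence pairs on
#' the spliced coding sequence, with Jukes-Cantor correction of the
#' substitution proportions. Gene-level `dN` and `dS` are means over pairs
#' and `omega = dN/dS` (ratio of means). Codons containing gaps or `N`s are
#' skipped for the pairs concerned (pairwise deletion at codon level).
#'
#' Observed codons translating to a stop are a data-integrity failure and
#' raise an error by default; `on_stop = "skip"` masks them (per row) with a
#' warning instead, which the pipeline uses to survive rare nonsense variants
#' in simulated data.
#'
#' @param alignment a [haplotype_alignment()] with exonic sequence.
#' @param annotation optional [gene_annotation()] override.
#' @param on_stop `"error"` (default) or `"skip"`.
#' @return list: `N_sites`, `S_sites` (mean fractional site counts), `dN`,
#'   `dS`, `omega` (`NA` when there is no exonic polymorphism or `dS = 0`),
#'   `n_pairs`, `polymorphic_codons`, and internals used by
#'   [test_neutrality()].
#' @export
dnds <- function(alignment, annotation = alignment$annotation,
                 on_stop = c("error", "skip")) {
  on_stop <- match.arg(on_stop)
  codons <- cds_codon_matrix(alignment, annotation)
  if (ncol(codons) == 0L || nrow(codons) < 2L) {
    stopf("dN/dS requires >= 2 rows with exonic sequence and a known frame")
  }
  gc <- Biostrings::GENETIC_CODE
  is_stop <- !is.na(codons) & gc[codons] == "*"
  if (any(is_stop)) {
    if (on_stop == "error") {
      w <- which(is_stop, arr.ind = TRUE)
      stopf("stop codon in row '%s' at codon %d: data-integrity failure",
            rownames(codons)[w[1, 1]], w[1, 2])
    }
    warnf("masking %d stop codon occurrence(s)", sum(is_stop))
    codons[is_stop] <- NA_character_
  }
  syn_sites <- .codon_syn_sites()
  upt <- unique_pair_table(codons)
  pat <- codons[upt$rows, , drop = FALSE]
  W <- upt$weights                    # columns: i, j, n_pairs
  P <- nrow(W); C <- ncol(codons)
  nd <- matrix(0, P, C); sd_ <- matrix(0, P, C)
  ns <- matrix(0, P, C); ss <- matrix(0, P, C)
  for (p in seq_len(P)) {
    ci <- pat[W[p, 1L], ]; cj <- pat[W[p, 2L], ]
    ok <- !is.na(ci) & !is.na(cj)
    for (k in which(ok)) {
      s_i <- syn_sites[ci[k]]; s_j <- syn_sites[cj[k]]
      ss[p, k] <- (s_i + s_j) / 2
      ns[p, k] <- 3 - ss[p, k]
      if (ci[k] != cj[k]) {
        st <- codon_path_stats(ci[k], cj[k])
        sd_[p, k] <- st["sd"]; nd[p, k] <- st["nd"]
      }
    }
  }
  wts <- W[, 3L]
  Np <- rowSums(ns); Sp <- rowSums(ss)
  Ndp <- rowSums(nd); Sdp <- rowSums(sd_)
  usable <- Np > 0 & Sp > 0
  dN_pair <- jc_correct(Ndp[usable] / Np[usable])
  dS_pair <- jc_correct(Sdp[usable] / Sp[usable])
  wu <- wts[usable]
  dN <- stats::weighted.mean(dN_pair, wu, na.rm = TRUE)
  dS <- stats::weighted.mean(dS_pair, wu, na.rm = TRUE)
  poly <- sum(colSums((nd + sd_) * wts) > 0)
  omega <- if (poly == 0L || !is.finite(dS) || dS <= 0) NA_real_ else dN / dS
  structure(list(
    gene_id = alignment$gene_id,
    N_sites = stats::weighted.mean(Np[usable], wu),
    S_sites = stats::weighted.mean(Sp[usable], wu),
    dN = dN, dS = dS, omega = omega,
    n_pairs = sum(wts), polymorphic_codons = poly,
    .pair = list(nd = nd, sd = sd_, ns = ns, ss = ss, weights = wts)),
    class = "dnds_summary")
}

#' @export
print.dnds_summary <- function(x, ...) {
  cat(sprintf("dN/dS (%s): dN = %.4g, dS = %.4g, omega = %s (%d polymorphic codons)\n",
              x$gene_id, x$dN, x$dS,
              ifelse(is.na(x$omega), "n.a.", sprintf("%.3f", x$omega)),
              x$polymorphic_codons))
  invisible(x)
}

#' Codon-bootstrap test of dN/dS = 1
#'
#' Resamples codons with replacement `B` times, recomputes the gene-level
#' `dN - dS` in each replicate, and reports the two-sided normal-tail p-value
#' of the observed difference scaled by the bootstrap standard deviation.
#' With fewer than 10 polymorphic codons the p-value is flagged unreliable.
#'
#' @param summary a `dnds_summary` from [dnds()].
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed for reproducibility.
#' @return list with `p`, `z`, `sd_boot`, `B`, `unreliable`.
#' @export
test_neutrality <- function(summary, B = 1000, seed = NULL) {
  stopifnot(inherits(summary, "dnds_summary"))
  if (is.na(summary$omega) && (!is.finite(summary$dS) || summary$dS > 0)) {
    stopf("omega undefined: nothing to test")
  }
  pr <- summary$.pair
  C <- ncol(pr$nd)
  wts <- pr$weights
  boot <- with_seed(seed, {
    Wb <- stats::rmultinom(B, C, rep(1 / C, C))     # codon resample counts
    NdB <- pr$nd %*% Wb; SdB <- pr$sd %*% Wb
    NsB <- pr$ns %*% Wb; SsB <- pr$ss %*% Wb
    pdB <- ifelse(NsB > 0, NdB / NsB, NA)
    psB <- ifelse(SsB > 0, SdB / SsB, NA)
    dNb <- jc_correct(pdB); dSb <- jc_correct(psB)
    apply(dNb - dSb, 2L, function(v) stats::weighted.mean(v, wts, na.rm = TRUE))
  })
  sd_boot <- stats::sd(boot, na.rm = TRUE)
  obs <- summary$dN - summary$dS
  z <- if (is.finite(sd_boot) && sd_boot > 0) obs / sd_boot else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  list(p = p, z = z, sd_boot = sd_boot, B = B,
       unreliable = summary$polymorphic_codons < 10L)
}
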