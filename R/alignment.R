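#' Gene-fragment annotation
#'
#' Describes a sequenced gene fragment as a set of disjoint, sorted intervals
#' (0-based, half-open) classified as 5'UTR, exon, intron or 3'UTR, plus the
#' reading-frame offset of the first exonic base. Fragments are stored in
#' coding orientation by convention; no strand handling is performed.
#'
#' @param intervals data.frame with columns `start`, `end` (0-based half-open)
#'   and `region` (one of `"5UTR"`, `"exon"`, `"intron"`, `"3UTR"`).
#' @param frame_offset 0, 1 or 2: number of bases of the first exon that
#'   complete an upstream codon and are skipped before translation starts.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(intervals, frame_offset = 0L) {
  stopifnot(is.data.frame(intervals),
            all(c("start", "end", "region") %in% names(intervals)))
  intervals <- intervals[order(intervals$start), c("start", "end", "region")]
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  intervals$region <- as.character(intervals$region)
  bad <- setdiff(unique(intervals$region), c("5UTR", "exon", "intron", "3UTR"))
  if (length(bad)) stopf("unknown region type(s): %s", paste(bad, collapse = ", "))
  if (any(intervals$end <= intervals$start)) stopf("empty or inverted interval")
  if (nrow(intervals) > 1 &&
      any(intervals$start[-1] < intervals$end[-nrow(intervals)])) {
    stopf("annotation intervals overlap")
  }
  if (!frame_offset %in% 0:2) stopf("frame_offset must be 0, 1 or 2")
  structure(list(intervals = intervals, frame_offset = as.integer(frame_offset)),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$intervals), "intervals, frame_offset",
      x$frame_offset, "\n")
  print(x$intervals)
  invisible(x)
}

# Region label at a 0-based alignment column; NA when uncovered.
region_at <- function(annotation, pos) {
  iv <- annotation$intervals
  hit <- which(iv$start <= pos & pos < iv$end)
  if (length(hit)) iv$region[hit[1L]] else NA_character_
}

#' Phased haploid gene-fragment alignment
#'
#' One row per line (one captured gamete per plant), equal-length rows over
#' the alphabet `A,C,G,T,-,N`, with population labels and a region annotation.
#'
#' @param gene_id gene label.
#' @param seqs character matrix (lines x alignment columns) over
#'   `A,C,G,T,-,N`, or a character vector of equal-length strings.
#' @param line_ids unique line identifiers (defaults to rownames/names).
#' @param populations population label per line.
#' @param annotation a [gene_annotation()].
#' @return An object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(gene_id, seqs, line_ids = NULL,
                                populations, annotation) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(line_ids)) line_ids <- names(seqs)
    w <- unique(nchar(seqs))
    if (length(w) != 1L) {
      stopf("ragged alignment in gene %s: records %s differ in length", gene_id,
            paste(utils::head(line_ids[nchar(seqs) != w[1]], 5), collapse = ", "))
    }
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (is.null(line_ids)) line_ids <- rownames(seqs)
  if (is.null(line_ids)) stopf("line_ids required")
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids)) stopf("duplicated line ids")
  if (length(populations) != nrow(seqs)) stopf("one population label per row required")
  bad <- setdiff(unique(as.vector(seqs)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) stopf("invalid residues: %s", paste(bad, collapse = ","))
  if (!inherits(annotation, "gene_annotation")) stopf("annotation must be a gene_annotation")
  if (max(annotation$intervals$end) > ncol(seqs)) {
    stopf("annotation extends beyond alignment (%d > %d)",
          max(annotation$intervals$end), ncol(seqs))
  }
  rownames(seqs) <- line_ids
  structure(list(gene_id = as.character(gene_id), seqs = seqs,
                 line_ids = line_ids, populations = as.character(populations),
                 annotation = annotation),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("haplotype_alignment '%s': %d lines x %d bp, %d population(s)\n",
              x$gene_id, nrow(x$seqs), ncol(x$seqs),
              length(unique(x$populations))))
  invisible(x)
}

#' Read a phased gene-fragment alignment from disk
#'
#' Reads a gapped FASTA alignment, a BED-like annotation file (tab separated,
#' 0-based half-open: start, end, region, frame) and a population-assignment
#' table (CSV: line_id, population). Records whose line id is missing from the
#' population table raise an error; rows with more than `max_n_frac` ambiguous
#' (`N`) residues are dropped with a warning, mirroring per-gene amplification
#' failures in real surveys.
#'
#' @param fasta_path path to the aligned FASTA (all records equal length).
#' @param annotation_path path to the annotation table.
#' @param populations_path path to the population CSV.
#' @param gene_id gene label; defaults to the FASTA file name.
#' @param max_n_frac maximum tolerated fraction of `N`s per row (default 0.2).
#' @return A [haplotype_alignment()].
#' @export
read_alignment <- function(fasta_path, annotation_path, populations_path,
                           gene_id = NULL, max_n_frac = 0.2) {
  for (p in c(fasta_path, annotation_path, populations_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  ss <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) {
    stopf("ragged alignment in %s: %s", fasta_path,
          paste(ids[w != stats::median(w)], collapse = ", "))
  }
  seqs <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  rownames(seqs) <- ids
  pops <- utils::read.csv(populations_path, stringsAsFactors = FALSE)
  if (!all(c("line_id", "population") %in% names(pops))) {
    stopf("population table must have columns line_id, population")
  }
  unknown <- setdiff(ids, pops$line_id)
  if (length(unknown)) {
    stopf("line(s) absent from population table: %s",
          paste(utils::head(unknown, 10), collapse = ", "))
  }
  popmap <- stats::setNames(pops$population, pops$line_id)
  n_frac <- rowMeans(seqs == "N")
  if (any(n_frac > max_n_frac)) {
    drop <- which(n_frac > max_n_frac)
    warnf("dropping %d row(s) with > %.0f%% N: %s", length(drop),
          100 * max_n_frac, paste(utils::head(ids[drop], 10), collapse = ", "))
    seqs <- seqs[-drop, , drop = FALSE]
    ids <- ids[-drop]
  }
  if (is.null(gene_id)) {
    gene_id <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))
  }
  haplotype_alignment(gene_id, seqs, ids, unname(popmap[ids]),
                      read_annotation(annotation_path))
}

#' Read a BED-like gene annotation
#'
#' Tab-separated, no header, columns: start, end, region, frame. Coordinates
#' are 0-based half-open. The frame column is used only on the first exon row
#' (the frame offset of translation); other rows may carry `.`.
#'
#' @param path annotation file.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("start", "end", "region", "frame"),
                          colClasses = c("integer", "integer", "character",
                                         "character"))
  first_exon <- which(df$region == "exon")[1L]
  fo <- if (!is.na(first_exon) && df$frame[first_exon] != ".") {
    as.integer(df$frame[first_exon])
  } else 0L
  gene_annotation(df[, c("start", "end", "region")], fo)
}

#' Call polymorphic sites in a haploid alignment
#'
#' SNP sites are alignment columns with at least two non-`N` residues and at
#' least two distinct nucleotides (gaps excluded from allele counts).
#' Insertion-deletion polymorphisms are treated as single binary sites: a
#' maximal run of `-` with identical start and end across its carriers is one
#' indel anchored at its first column; carriers with a different gap extent
#' form a distinct indel site. Missing data are handled by per-site deletion:
#' allele counts use all rows non-missing at that site.
#'
#' The minor-allele frequency (MAF) is the frequency of the second most common
#' allele (hence always in \[0, 0.5\], also for triallelic sites, which are
#' supported and flagged in the `triallelic` column).
#'
#' @param alignment a [haplotype_alignment()] with at least 2 rows.
#' @return A `site_table` data.frame with one row per polymorphic site:
#'   `pos` (0-based anchor column), `kind` (`"SNP"`/`"indel"`), list columns
#'   `alleles` and `counts` (sorted by decreasing count; indel alleles are
#'   `"del"`/`"ref"`), `n_valid`, `maf`, `indel_length`, `triallelic`,
#'   `region`, `coding_effect`, `polarity_change`, `flag`.
#' @export
call_sites <- function(alignment) {
  mat <- alignment$seqs
  if (nrow(mat) < 2L) stopf("need at least 2 rows to call sites")
  L <- ncol(mat)
  sites <- list()

  # --- indels: group maximal '-' runs by exact extent --------------------
  runs <- list()
  for (i in seq_len(nrow(mat))) {
    g <- mat[i, ] == "-"
    if (!any(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      key <- paste0(starts[k], ":", ends[k])
      runs[[key]] <- c(runs[[key]], i)
    }
  }
  for (key in names(runs)) {
    se <- as.integer(strsplit(key, ":")[[1L]])
    anchor <- se[1L] - 1L              # 0-based
    carriers <- runs[[key]]
    missing_rows <- which(mat[, se[1L]] == "N")
    n_valid <- nrow(mat) - length(missing_rows)
    n_del <- length(carriers)
    n_ref <- n_valid - n_del
    if (n_del == 0L || n_ref == 0L || n_valid < 2L) next
    al <- c("del", "ref"); cn <- c(n_del, n_ref)
    o <- order(cn, decreasing = TRUE)
    sites[[length(sites) + 1L]] <- list(
      pos = anchor, kind = "indel", alleles = al[o], counts = cn[o],
      n_valid = n_valid, maf = min(cn) / n_valid,
      indel_length = se[2L] - se[1L] + 1L, triallelic = FALSE)
  }

  # --- SNPs --------------------------------------------------------------
  for (j in seq_len(L)) {
    col <- mat[, j]
    res <- col[col %in% c("A", "C", "G", "T")]
    if (length(res) < 2L) next
    tab <- sort(table(res), decreasing = TRUE)
    if (length(tab) < 2L) next
    sites[[length(sites) + 1L]] <- list(
      pos = j - 1L, kind = "SNP",
      alleles = names(tab), counts = as.integer(tab),
      n_valid = length(res), maf = as.integer(tab)[2L] / length(res),
      indel_length = NA_integer_, triallelic = length(tab) > 2L)
  }

  if (!length(sites)) return(empty_site_table())
  df <- data.frame(
    pos = vapply(sites, `[[`, integer(1), "pos"),
    kind = vapply(sites, `[[`, character(1), "kind"),
    n_valid = vapply(sites, `[[`, integer(1), "n_valid"),
    maf = vapply(sites, `[[`, numeric(1), "maf"),
    indel_length = vapply(sites, `[[`, integer(1), "indel_length"),
    triallelic = vapply(sites, `[[`, logical(1), "triallelic"),
    stringsAsFactors = FALSE)
  df$alleles <- lapply(sites, `[[`, "alleles")
  df$counts <- lapply(sites, `[[`, "counts")
  df$region <- vapply(df$pos, function(p) region_at(alignment$annotation, p),
                      character(1))
  df$coding_effect <- NA_character_
  df$polarity_change <- NA
  df$flag <- NA_character_
  df <- df[order(df$pos, df$kind), ]
  rownames(df) <- NULL
  class(df) <- c("site_table", "data.frame")
  df
}

empty_site_table <- function() {
  df <- data.frame(pos = integer(0), kind = character(0),
                   n_valid = integer(0), maf = numeric(0),
                   indel_length = integer(0), triallelic = logical(0),
                   stringsAsFactors = FALSE)
  df$alleles <- list(); df$counts <- list()
  df$region <- character(0); df$coding_effect <- character(0)
  df$polarity_change <- logical(0); df$flag <- character(0)
  class(df) <- c("site_table", "data.frame")
  df
}

# Amino-acid polarity in three classes; used to flag replacements that move a
# residue between classes.
aa_polarity_class <- function(aa) {
  classes <- c(A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
               P = "nonpolar", F = "nonpolar", W = "nonpolar", M = "nonpolar",
               G = "nonpolar", C = "nonpolar",
               S = "polar", T = "polar", Y = "polar", N = "polar", Q = "polar",
               D = "charged", E = "charged", K = "charged", R = "charged",
               H = "charged")
  unname(classes[aa])
}

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

# Map 0-based alignment columns to coding-sequence indices (1-based within the
# spliced, frame-trimmed CDS). Returns NA for non-CDS columns.
cds_index_map <- function(annotation, L) {
  iv <- annotation$intervals
  exon_cols <- integer(0)
  for (k in which(iv$region == "exon")) {
    exon_cols <- c(exon_cols, seq.int(iv$start[k], iv$end[k] - 1L))
  }
  if (annotation$frame_offset > 0L && length(exon_cols) >= annotation$frame_offset) {
    exon_cols <- exon_cols[-seq_len(annotation$frame_offset)]
  }
  idx <- rep(NA_integer_, L)
  idx[exon_cols + 1L] <- seq_along(exon_cols)
  idx
}

#' Classify coding effects of polymorphic sites
#'
#' Exonic SNPs are classified by translating both alleles' codons (standard
#' genetic code): identical amino acids are synonymous, otherwise
#' non-synonymous, in which case `polarity_change` records whether the two
#' residues belong to different polarity classes (nonpolar / polar uncharged /
#' charged). The codon background is the per-column majority base; a codon
#' truncated by the fragment boundary yields `NA`. Exonic indels whose length
#' is a multiple of 3 are `frameshift-free-indel`; other exonic indels are
#' flagged (`flag = "frameshift"`) and left unclassified. Non-exonic sites are
#' `non-coding`.
#'
#' @param sites a `site_table` from [call_sites()].
#' @param alignment the [haplotype_alignment()] the sites were called on.
#' @param annotation optional [gene_annotation()] (defaults to the alignment's).
#' @return The site table with `coding_effect`, `polarity_change` and `flag`
#'   filled in.
#' @export
classify_effects <- function(sites, alignment, annotation = alignment$annotation) {
  if (!nrow(sites)) return(sites)
  mat <- alignment$seqs
  L <- ncol(mat)
  idx_map <- cds_index_map(annotation, L)
  cds_cols <- order(idx_map, na.last = NA)       # alignment cols by CDS index
  # majority (consensus) base per alignment column, ignoring '-' and 'N'
  consensus <- apply(mat, 2L, function(col) {
    res <- col[col %in% c("A", "C", "G", "T")]
    if (!length(res)) NA_character_ else names(sort(table(res), decreasing = TRUE))[1L]
  })
  for (i in seq_len(nrow(sites))) {
    region <- sites$region[i]
    if (is.na(region) || region != "exon") {
      sites$coding_effect[i] <- "non-coding"
      next
    }
    if (sites$kind[i] == "indel") {
      if (sites$indel_length[i] %% 3L == 0L) {
        sites$coding_effect[i] <- "frameshift-free-indel"
      } else {
        sites$flag[i] <- "frameshift"
      }
      next
    }
    cds_i <- idx_map[sites$pos[i] + 1L]
    if (is.na(cds_i)) { sites$coding_effect[i] <- "non-coding"; next }
    codon_start <- ((cds_i - 1L) %/% 3L) * 3L + 1L
    codon_idx <- codon_start:(codon_start + 2L)
    if (max(codon_idx) > length(cds_cols)) { # truncated terminal codon
      sites$coding_effect[i] <- NA_character_
      sites$flag[i] <- "truncated-codon"
      next
    }
    codon_cols <- cds_cols[codon_idx]
    background <- consensus[codon_cols]
    if (anyNA(background)) {
      sites$coding_effect[i] <- NA_character_
      sites$flag[i] <- "ambiguous-codon"
      next
    }
    within <- (cds_i - 1L) %% 3L + 1L
    a <- sites$alleles[[i]][1L]; b <- sites$alleles[[i]][2L]
    cod_a <- background; cod_a[within] <- a
    cod_b <- background; cod_b[within] <- b
    aa_a <- translate_codon(paste(cod_a, collapse = ""))
    aa_b <- translate_codon(paste(cod_b, collapse = ""))
    if (aa_a == aa_b) {
      sites$coding_effect[i] <- "synonymous"
    } else {
      sites$coding_effect[i] <- "non-synonymous"
      pa <- aa_polarity_class(aa_a); pb <- aa_polarity_class(aa_b)
      sites$polarity_change[i] <- if (is.na(pa) || is.na(pb)) NA else pa != pb
    }
  }
  sites
}

#' Filter sites by minor-allele frequency
#'
#' Sites with MAF strictly below the threshold are removed (a site at exactly
#' the threshold is kept). The conventional threshold of 0.05 removes rare
#' variants whose linkage-disequilibrium estimates are unstable.
#'
#' @param sites a `site_table`.
#' @param threshold minimum MAF (default 0.05).
#' @return The filtered `site_table`.
#' @export
filter_maf <- function(sites, threshold = 0.05) {
  stopifnot(is_prob(threshold))
  out <- sites[sites$maf >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-line allele matrix over polymorphic sites
#'
#' Encodes each line's allele at each polymorphic site: the nucleotide at SNP
#' sites (NA when gapped or `N`), and `"del"`/`"ref"` at indel sites (carrier
#' means a gap run of exactly the site's extent). This is the working matrix
#' for haplotype inventories and linkage disequilibrium.
#'
#' @param alignment a [haplotype_alignment()].
#' @param sites a `site_table` for that alignment.
#' @return character matrix, lines x sites; column names `<kind>@<pos>`.
#' @export
allele_matrix <- function(alignment, sites) {
  mat <- alignment$seqs
  n <- nrow(mat)
  out <- matrix(NA_character_, n, nrow(sites),
                dimnames = list(alignment$line_ids,
                                paste0(sites$kind, "@", sites$pos)))
  if (!nrow(sites)) return(out)
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i] + 1L
    if (sites$kind[i] == "SNP") {
      col <- mat[, p]
      col[!col %in% c("A", "C", "G", "T")] <- NA_character_
      out[, i] <- col
    } else {
      len <- sites$indel_length[i]
      span <- p:(p + len - 1L)
      is_del <- rowSums(mat[, span, drop = FALSE] == "-") == len
      # exact extent: flanking columns must not also be gaps
      if (p > 1L) is_del <- is_del & mat[, p - 1L] != "-"
      if (p + len <= ncol(mat)) is_del <- is_del & mat[, p + len] != "-"
      v <- ifelse(is_del, "del", "ref")
      v[mat[, p] == "N" & !is_del] <- NA_character_
      out[, i] <- v
    }
  }
  out
}
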