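#' Write a synthetic study to disk as plain-text fixtures
#'
#' Emits one gapped FASTA and one BED-like annotation file per gene (under
#' `genes/`), the SSR table and population table as CSV, the locus linkage
#' groups as TSV, and the ground truth as JSON. Everything round-trips
#' through [read_study()].
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param directory output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_fixtures <- function(study, directory) {
  stopifnot(inherits(study, "synthetic_study"))
  gdir <- file.path(directory, "genes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(gdir)) stopf("cannot create directory: %s", gdir)
  written <- character(0)
  for (aln in study$alignments) {
    fa <- file.path(gdir, paste0(aln$gene_id, ".fasta"))
    seqs <- apply(aln$seqs, 1L, paste, collapse = "")
    ss <- Biostrings::BStringSet(seqs)
    names(ss) <- paste0(aln$line_ids, " pop=", aln$populations)
    Biostrings::writeXStringSet(ss, fa, width = 80L)
    ann <- file.path(gdir, paste0(aln$gene_id, ".annotation.tsv"))
    iv <- aln$annotation$intervals
    frame <- rep(".", nrow(iv))
    first_exon <- which(iv$region == "exon")[1L]
    if (!is.na(first_exon)) frame[first_exon] <- aln$annotation$frame_offset
    utils::write.table(cbind(iv, frame), ann, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, fa, ann)
  }
  ssr_df <- data.frame(line_id = study$ssr$line_ids,
                       population = study$ssr$populations,
                       study$ssr$calls, check.names = FALSE,
                       stringsAsFactors = FALSE)
  f_ssr <- file.path(directory, "ssr.csv")
  utils::write.csv(ssr_df, f_ssr, row.names = FALSE, na = "")
  f_loci <- file.path(directory, "loci.tsv")
  utils::write.table(study$ssr$loci_info, f_loci, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_pop <- file.path(directory, "populations.csv")
  utils::write.csv(study$populations, f_pop, row.names = FALSE)
  f_truth <- file.path(directory, "truth.json")
  truth <- study$truth
  truth$genes <- lapply(truth$genes, function(g) {
    g$annotation <- list(intervals = g$annotation$intervals,
                         frame_offset = g$annotation$frame_offset)
    g
  })
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(written, f_ssr, f_loci, f_pop, f_truth))
}

#' Read study fixtures from disk
#'
#' Counterpart of [write_fixtures()]; also reads externally prepared inputs
#' laid out the same way (truth file optional).
#'
#' @param directory fixture directory.
#' @param max_n_frac per-row ambiguity tolerance passed to [read_alignment()].
#' @return list with `alignments`, `ssr`, `populations` and (when present)
#'   `truth`.
#' @export
read_study <- function(directory, max_n_frac = 0.2) {
  gdir <- file.path(directory, "genes")
  f_pop <- file.path(directory, "populations.csv")
  f_ssr <- file.path(directory, "ssr.csv")
  if (!dir.exists(gdir)) stopf("no genes/ directory under %s", directory)
  if (!file.exists(f_pop)) stopf("missing populations.csv under %s", directory)
  fastas <- sort(list.files(gdir, pattern = "\\.fasta$", full.names = TRUE))
  alignments <- list()
  for (fa in fastas) {
    gene <- sub("\\.fasta$", "", basename(fa))
    ann <- file.path(gdir, paste0(gene, ".annotation.tsv"))
    if (!file.exists(ann)) stopf("missing annotation for gene %s", gene)
    alignments[[gene]] <- read_alignment(fa, ann, f_pop, gene_id = gene,
                                         max_n_frac = max_n_frac)
  }
  ssr <- NULL
  if (file.exists(f_ssr)) {
    df <- utils::read.csv(f_ssr, check.names = FALSE, stringsAsFactors = FALSE)
    loci_cols <- setdiff(names(df), c("line_id", "population"))
    calls <- as.matrix(df[, loci_cols, drop = FALSE])
    mode(calls) <- "integer"
    rownames(calls) <- df$line_id
    f_loci <- file.path(directory, "loci.tsv")
    loci_info <- if (file.exists(f_loci)) {
      utils::read.table(f_loci, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    } else NULL
    ssr <- ssr_matrix(calls, df$line_id, df$population, loci_info)
  }
  out <- list(alignments = alignments, ssr = ssr,
              populations = utils::read.csv(f_pop, stringsAsFactors = FALSE))
  f_truth <- file.path(directory, "truth.json")
  if (file.exists(f_truth)) out$truth <- jsonlite::read_json(f_truth)
  out
}
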