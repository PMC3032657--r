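test_that("read_alignment parses FASTA, drops high-N rows, enforces contracts", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  writeLines(c(">L01 pop=pop1", "ACGTACGTAC",
               ">L02 pop=pop1", "ACGTACGTAC",
               ">L03 pop=pop2", "ACGAACGTAC"), fa)
  ann <- file.path(dir, "g.annotation.tsv")
  writeLines("0\t10\texon\t0", ann)
  pops <- file.path(dir, "populations.csv")
  writeLines(c("line_id,population", "L01,pop1", "L02,pop1", "L03,pop2"), pops)
  aln <- read_alignment(fa, ann, pops)
  expect_s3_class(aln, "haplotype_alignment")
  expect_equal(nrow(aln$seqs), 3L)
  expect_equal(aln$populations, c("pop1", "pop1", "pop2"))

  # unknown line id -> error
  writeLines(c(">LX pop=pop1", "ACGTACGTAC"), fa)
  expect_error(read_alignment(fa, ann, pops), "absent from population table")

  # ragged alignment -> error
  writeLines(c(">L01", "ACGTACGTAC", ">L02", "ACGTA"), fa)
  expect_error(read_alignment(fa, ann, pops), "ragged")

  # high-N rows dropped with warning
  writeLines(c(">L01", "ACGTACGTAC", ">L02", "NNNNNNNNAC",
               ">L03", "ACGAACGTAC"), fa)
  expect_warning(aln2 <- read_alignment(fa, ann, pops), "dropping 1 row")
  expect_equal(aln2$line_ids, c("L01", "L03"))
})

test_that("gene_annotation validates intervals and frame", {
  expect_error(gene_annotation(data.frame(start = 0, end = 10, region = "cds")),
               "unknown region")
  expect_error(gene_annotation(data.frame(start = c(0, 5), end = c(6, 10),
                                          region = c("exon", "intron"))),
               "overlap")
  expect_error(gene_annotation(data.frame(start = 0, end = 10,
                                          region = "exon"), 3), "frame_offset")
  ann <- gene_annotation(data.frame(start = c(0, 4), end = c(4, 10),
                                    region = c("5UTR", "exon")), 1)
  expect_equal(ann$frame_offset, 1L)
})

test_that("call_sites implements the SNP and atomic-indel definitions", {
  # monomorphic -> empty table
  aln <- toy_alignment(c("ACGT", "ACGT", "ACGT"))
  expect_equal(nrow(call_sites(aln)), 0L)

  # definition case: one A/A/G/G column plus a shared 2-column gap in 1 row
  aln <- toy_alignment(c("AACGTT", "AACGTT", "GACGTT", "GA--TT"))
  st <- call_sites(aln)
  expect_equal(sum(st$kind == "SNP"), 1L)
  expect_equal(sum(st$kind == "indel"), 1L)
  snp <- st[st$kind == "SNP", ]
  expect_equal(snp$pos, 0L)
  expect_setequal(unlist(snp$alleles), c("A", "G"))
  ind <- st[st$kind == "indel", ]
  expect_equal(ind$pos, 2L)          # anchored at first gap column
  expect_equal(ind$indel_length, 2L)
  expect_equal(ind$maf, 0.25)

  # carriers with different gap extents form distinct indel sites
  aln <- toy_alignment(c("ACGTGT", "A--TGT", "A---GT", "ACGTGT"))
  st <- call_sites(aln)
  expect_equal(sum(st$kind == "indel"), 2L)
  expect_setequal(st$indel_length[st$kind == "indel"], c(2L, 3L))

  # triallelic SNPs supported and flagged; MAF is the 2nd-commonest frequency
  aln <- toy_alignment(c("AT", "AT", "CT", "CT", "GT", "AT"))
  st <- call_sites(aln)
  expect_true(st$triallelic)
  expect_equal(st$maf, 2 / 6)

  # N excluded from counts
  aln <- toy_alignment(c("AT", "GT", "NT", "AT"))
  st <- call_sites(aln)
  expect_equal(st$n_valid, 3L)
  expect_equal(st$maf, 1 / 3)
})

test_that("call_sites is invariant to row order", {
  seqs <- c("AACGTT", "AACGTT", "GACGTT", "GA--TT", "GACGAT")
  st1 <- call_sites(toy_alignment(seqs))
  st2 <- call_sites(toy_alignment(rev(seqs)))
  expect_equal(st1$pos, st2$pos)
  expect_equal(st1$kind, st2$kind)
  expect_equal(st1$maf, st2$maf)
})

test_that("classify_effects translates codons, polarity and indels correctly", {
  # exon GGA|GGG...: site 2 A/G -> Gly/Gly synonymous
  aln <- toy_alignment(c("GGAGGG", "GGGGGG", "GGAGGG", "GGGGGG"))
  st <- classify_effects(call_sites(aln), aln)
  expect_equal(st$coding_effect, "synonymous")
  expect_equal(st$polarity_change, NA)

  # AAA -> GAA: Lys -> Glu, both charged: non-synonymous, no polarity change
  aln <- toy_alignment(c("AAATTT", "GAATTT", "AAATTT", "GAATTT"))
  st <- classify_effects(call_sites(aln), aln)
  expect_equal(st$coding_effect, "non-synonymous")
  expect_false(st$polarity_change)

  # AAA -> AAT: Lys (charged) -> Asn (polar): polarity change
  aln <- toy_alignment(c("AAATTT", "AATTTT", "AAATTT", "AATTTT"))
  st <- classify_effects(call_sites(aln), aln)
  expect_equal(st$coding_effect, "non-synonymous")
  expect_true(st$polarity_change)

  # SNP in annotated intron -> non-coding
  ann <- gene_annotation(data.frame(start = c(0, 3), end = c(3, 6),
                                    region = c("exon", "intron")), 0)
  aln <- toy_alignment(c("AAATTT", "AAATAT", "AAATTT", "AAATAT"),
                       annotation = ann)
  st <- classify_effects(call_sites(aln), aln)
  expect_equal(st$coding_effect, "non-coding")

  # exonic indel: length 3 frame-free, length 2 flagged
  aln <- toy_alignment(c("AAATTTGGG", "AAA---GGG", "AAATTTGGG", "AAATTTGGG"))
  st <- classify_effects(call_sites(aln), aln)
  expect_equal(st$coding_effect[st$kind == "indel"], "frameshift-free-indel")
  aln <- toy_alignment(c("AAATTTGGG", "AAAT--GGG", "AAATTTGGG", "AAATTTGGG"))
  st <- classify_effects(call_sites(aln), aln)
  expect_true(is.na(st$coding_effect[st$kind == "indel"]))
  expect_equal(st$flag[st$kind == "indel"], "frameshift")
})

test_that("classify_effects agrees with brute-force exon translation", {
  # frame offset 1 and an intron: reverse-engineered codon must match
  # translating the whole spliced exon for both alleles
  ann <- gene_annotation(data.frame(start = c(0, 7, 10), end = c(7, 10, 16),
                                    region = c("exon", "intron", "exon")), 1)
  base <- "TGCTGCAgtaTCGCAT"
  alt <- "TGCTGCGgtaTCGCAT"   # SNP at 0-based pos 6, last base of codon 2
  aln <- toy_alignment(toupper(c(base, alt, base, alt)), annotation = ann)
  st <- classify_effects(call_sites(aln), aln)
  splice <- function(s) {
    ex <- paste0(substr(s, 1, 7), substr(s, 11, 16))
    substr(ex, 2, nchar(ex))  # frame offset 1
  }
  trans <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(s, 1, (nchar(s) %/% 3) * 3))))
  }
  aa1 <- trans(splice(toupper(base))); aa2 <- trans(splice(toupper(alt)))
  expect_equal(st$coding_effect,
               ifelse(aa1 == aa2, "synonymous", "non-synonymous"))
})

test_that("filter_maf keeps sites at exactly the threshold", {
  aln <- toy_alignment(c(rep("AT", 19), "GT"))   # MAF 0.05 exactly
  st <- call_sites(aln)
  expect_equal(nrow(filter_maf(st, 0.05)), 1L)
  expect_equal(nrow(filter_maf(st, 0.051)), 0L)
  # threshold 0 is the identity
  expect_equal(nrow(filter_maf(st, 0)), nrow(st))
  # one rare site among several is removed
  seqs <- c("AAG", "AAG", "AAG", rep("AAT", 7), rep("CAT", 10), "CCT")
  st <- call_sites(toy_alignment(seqs))
  expect_equal(nrow(st), 3L)
  kept <- filter_maf(st, 0.05)
  expect_equal(nrow(kept), 2L)
})
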