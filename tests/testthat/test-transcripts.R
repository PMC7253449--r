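writeFixtureFiles <- function(fasta, table) {
  fa <- tempfile(fileext = ".fa")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(fasta, fa)
  writeLines(c("gene_id\ttranscript_id\tutr_length\tcds_prefix_length", table), tsv)
  list(fa = fa, tsv = tsv)
}

test_that("loadTranscripts splits FASTA records into UTR and CDS prefix", {
  f <- writeFixtureFiles(c(">T1", "ACGTTTGATGGCT"), "G1\tT1\t7\t6")
  ts <- loadTranscripts(f$fa, f$tsv)
  expect_equal(as.character(utrSeq(ts)), c(T1 = "ACGTTTG"))
  expect_equal(as.character(cdsPrefix(ts)), c(T1 = "ATGGCT"))
  expect_equal(unname(utrLength(ts)), 7L)
})

test_that("zero-length UTRs are retained and flagged", {
  f <- writeFixtureFiles(c(">T1", "ATGGCT"), "G1\tT1\t0\t6")
  ts <- loadTranscripts(f$fa, f$tsv)
  expect_equal(as.character(utrSeq(ts)), c(T1 = ""))
  expect_false(unname(hasUtr(ts)))
})

test_that("loader validation errors are specific", {
  f <- writeFixtureFiles(c(">T1", "ACGTTTGAT"), "G1\tT1\t10\t6")
  expect_error(loadTranscripts(f$fa, f$tsv), "shorter than annotation")
  f2 <- writeFixtureFiles(c(">T2", "ACGT"), "G1\tT1\t2\t2")
  expect_error(loadTranscripts(f2$fa, f2$tsv), "missing FASTA record")
  f3 <- writeFixtureFiles(c(">T1", "ACRTTTGATGGCT"), "G1\tT1\t7\t6")
  expect_error(loadTranscripts(f3$fa, f3$tsv), "outside A/C/G/T/N")
})

test_that("applyVariant substitutes, inserts and validates", {
  ts <- TranscriptSet("G1", "T1", "ACGTTTG", "ATGGCT")
  expect_equal(as.character(utrSeq(applyVariant(ts, "T1", 2, "C", "T"))),
               c(T1 = "ATGTTTG"))
  ts16 <- TranscriptSet("G1", "T1", "ACGTACGTACGTACGT", "ATGGCT")
  ins <- applyVariant(ts16, "T1", 10, "", "T")
  expect_equal(unname(utrLength(ins)), 17L)
  expect_equal(as.character(cdsPrefix(ins)), c(T1 = "ATGGCT"))
  expect_error(applyVariant(ts, "T1", 2, "G", "A"), "ref mismatch")
  expect_error(applyVariant(ts, "T1", 7, "GA", "TT"), "UTR/CDS junction")
})

test_that("variant application round-trips and obeys length arithmetic", {
  set.seed(42)
  for (rep in 1:20) {
    utr <- randomUtr(sample(20:80, 1))
    ts <- TranscriptSet("G", "T", utr, "ATGGCTAAA")
    L <- unname(utrLength(ts))
    pos <- sample(L, 1)
    ref <- substr(utr, pos, pos)
    alt <- sample(setdiff(BASES, ref), 1)
    snv <- applyVariant(ts, "T", pos, ref, alt)
    expect_equal(unname(utrLength(snv)), L)
    back <- applyVariant(snv, "T", pos, alt, ref)
    expect_identical(as.character(utrSeq(back)), as.character(utrSeq(ts)))
    len <- sample(1:3, 1)
    dpos <- sample(L - len, 1)
    dref <- substr(utr, dpos, dpos + len - 1)
    del <- applyVariant(ts, "T", dpos, dref, "")
    expect_equal(unname(utrLength(del)), L - len)
    undel <- applyVariant(del, "T", dpos, "", dref)
    expect_identical(as.character(utrSeq(undel)), as.character(utrSeq(ts)))
  }
})

test_that("writeTranscripts / loadTranscripts round-trip byte-for-byte", {
  cfg <- simulationConfig(seed = 5, nGenes = 20)
  ts <- generateTranscripts(cfg)$transcripts
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  writeTranscripts(ts, fa, tsv)
  back <- loadTranscripts(fa, tsv)
  expect_identical(as.character(utrSeq(back)), as.character(utrSeq(ts)))
  expect_identical(as.character(cdsPrefix(back)), as.character(cdsPrefix(ts)))
})

test_that("GFF3 + genome reader handles both strands and splicing", {
  gff <- tempfile(fileext = ".gff3")
  genome <- tempfile(fileext = ".fa")
  # plus-strand transcript with the UTR split across two exons;
  # minus-strand transcript whose sense sequence must be the reverse
  # complement of the reference slice
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tfive_prime_UTR\t11\t14\t.\t+\t.\tID=u1;Parent=transcript:TX1;gene_id=GA",
    "chr1\ttest\tfive_prime_UTR\t21\t23\t.\t+\t.\tID=u2;Parent=transcript:TX1;gene_id=GA",
    "chr1\ttest\tCDS\t24\t40\t.\t+\t.\tID=c1;Parent=transcript:TX1;gene_id=GA",
    "chr1\ttest\tfive_prime_UTR\t61\t66\t.\t-\t.\tID=u3;Parent=transcript:TX2;gene_id=GB",
    "chr1\ttest\tCDS\t45\t60\t.\t-\t.\tID=c2;Parent=transcript:TX2;gene_id=GB"
  ), gff)
  ref <- paste0("AAAAAAAAAA", "ACGT", "AAAAAA", "GGG", "ATGCCCGGGTTTACGCA",
                "AAAA", "TTTTTTTTTTTTTCAT", "CCCCCC", "AAAAAAAAAAAAAA")
  writeLines(c(">chr1", ref), genome)
  ts <- readGff3Transcripts(gff, genome, cdsPrefixLength = 6)
  expect_setequal(txIds(ts), c("TX1", "TX2"))
  expect_equal(as.character(utrSeq(ts))[["TX1"]], "ACGTGGG")
  expect_equal(as.character(cdsPrefix(ts))[["TX1"]], "ATGCCC")
  # minus strand: sense UTR = revcomp(genomic 61..66 "CCCCCC") = "GGGGGG",
  # sense CDS = revcomp of the 3' end of the genomic CDS block
  expect_equal(as.character(utrSeq(ts))[["TX2"]], "GGGGGG")
  expect_equal(as.character(cdsPrefix(ts))[["TX2"]], "ATGAAA")
})

test_that("VCF variants map through exon blocks to transcript space", {
  gff <- tempfile(fileext = ".gff3")
  genome <- tempfile(fileext = ".fa")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tfive_prime_UTR\t11\t17\t.\t+\t.\tParent=transcript:TX1",
    "chr1\ttest\tCDS\t18\t30\t.\t+\t.\tParent=transcript:TX1"
  ), gff)
  writeLines(c(">chr1", paste0("AAAAAAAAAA", "ACGTTTG", "ATGGCTAAAGGGC",
                               "AAAAAAAAAA")), genome)
  ts <- readGff3Transcripts(gff, genome, cdsPrefixLength = 6)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t12\t.\tC\tT\t.\tPASS\t.",
    "chr1\t500\t.\tA\tG\t.\tPASS\t."
  ), vcf)
  v <- readVcfVariants(vcf, ts)
  expect_equal(nrow(v), 1L)  # the second record is outside every exon
  expect_equal(v$pos, 2L)
  expect_equal(v$ref, "C")
  # and the mapped variant creates the documented uAUG
  rec <- annotateVariant(ts, v$transcript_id, v$pos, v$ref, v$alt)
  expect_equal(rec$kind, "uAUG_created")
})

test_that("transcript-space variant TSV reader validates refs", {
  ts <- TranscriptSet("G1", "T1", "ACGTTTG", "ATGGCT")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tpos\tref\talt", "T1\t2\tC\tT"), tsv)
  v <- readVariantsTsv(tsv, ts)
  expect_equal(v$pos, 2L)
  writeLines(c("transcript_id\tpos\tref\talt", "T1\t2\tG\tT"), tsv)
  expect_error(readVariantsTsv(tsv, ts), "ref mismatch")
})
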