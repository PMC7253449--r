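test_that("Kozak strength follows the -3/+3 rule, absent -3 non-matching", {
  expect_equal(classifyKozak("AAGATGGCC", 4)$value, "strong")
  expect_equal(classifyKozak("GCCATGTTT", 4)$value, "moderate")
  kz <- classifyKozak("ATGGTTCCC", 1)  # -3 absent, +3 = G
  expect_equal(kz$value, "moderate")
  expect_true(is.na(kz$minus3))
  expect_equal(classifyKozak("CCCATGTAA", 4)$value, "weak")
  expect_error(classifyKozak("CCCATG", 4), "too short")
  # trichotomy over every -3/+3 combination
  for (m3 in BASES) for (p3 in BASES) {
    v <- classifyKozak(paste0(m3, "CCATG", p3, "CC"), 4)$value
    expect_equal(v, if (m3 %in% c("A", "G") && p3 == "G") "strong"
                    else if (m3 %in% c("A", "G") || p3 == "G") "moderate"
                    else "weak")
  }
})

test_that("findUorfs reports uORFs, existing oORFs and shared-stop Kozak", {
  u <- findUorfs(TranscriptSet("G1", "T1", "ATGAAATGACC", "ATGGCT"))
  expect_equal(nrow(u), 2L)
  uorf <- u[!u$is_oorf, ]
  expect_equal(uorf$start, 1L)
  expect_equal(uorf$stop_start, 7L)     # TGA
  expect_equal(uorf$kozak, "weak")      # -3 absent, +3 = A
  oorf <- u[u$is_oorf, ]
  expect_equal(oorf$start, 6L)
  expect_equal(oorf$frame_vs_cds, 0L)   # CDS-elongation type
  expect_equal(oorf$kozak, "moderate")  # -3 = G, +3 = A

  u2 <- findUorfs(TranscriptSet("G1", "T1", "AAGGATGGACTAGCCC", "ATGGCT"))
  expect_equal(u2$start, 5L)
  expect_equal(u2$stop_start, 11L)      # TAG
  expect_equal(u2$kozak, "strong")

  expect_equal(nrow(findUorfs(TranscriptSet("G1", "T1", "", "ATGGCT"))), 0L)

  # two uAUGs converging on one stop: strongest Kozak wins the group
  ts <- TranscriptSet("G1", "T1", "CATGATGCCCTAAC", "ATGGCT")
  u3 <- findUorfs(ts)
  shared <- u3[!is.na(u3$stop_start) & u3$stop_start == 11L, ]
  expect_equal(nrow(shared), 2L)
  expect_setequal(shared$start, c(2L, 5L))
  expect_setequal(shared$kozak, c("weak", "moderate"))
  expect_true(all(shared$kozak_group == "moderate"))
})

test_that("translation evidence is matched by stop coordinate", {
  ts <- TranscriptSet("G1", "T1", "ATGAAATGACC", "ATGGCT")
  ev <- data.frame(transcript_id = "T1", stop_start = 7L)
  u <- findUorfs(ts, evidence = ev)
  expect_true(u$evidence[!u$is_oorf])
  u0 <- findUorfs(ts, evidence = data.frame(transcript_id = "T1",
                                            stop_start = 4L))
  expect_false(any(u0$evidence))
})

test_that("uAUG SNV enumeration matches the worked fixture exactly", {
  rec <- enumerateUaugSnvs(TranscriptSet("G1", "T1", "ACGTTTG", "ATGGCT"))
  expect_equal(nrow(rec), 2L)
  r1 <- rec[rec$pos == 2L, ]
  expect_equal(r1$ref, "C"); expect_equal(r1$alt, "T")
  expect_equal(r1$distance_to_cds, 7L)
  expect_equal(r1$frame, 1L)
  expect_equal(r1$consequence, "oORF_out_of_frame")
  expect_equal(r1$kozak, "weak")
  r2 <- rec[rec$pos == 5L, ]
  expect_equal(r2$ref, "T"); expect_equal(r2$alt, "A")
  expect_equal(r2$distance_to_cds, 3L)
  expect_equal(r2$frame, 0L)
  expect_equal(r2$consequence, "CDS_elongation")
  # a lone ATG UTR offers no creatable ATG
  expect_equal(nrow(enumerateUaugSnvs(TranscriptSet("G", "T", "ATG", "ATGGCT"))), 0L)
  # windows containing N are skipped
  expect_equal(nrow(enumerateUaugSnvs(TranscriptSet("G", "T", "ANGCCC", "ATGGCT"))), 0L)
})

test_that("stop-removing SNV counts obey the 7/8/8 law per stop codon", {
  byBrute <- function(codon) {
    n <- 0L
    for (j in 1:3) for (alt in setdiff(BASES, substr(codon, j, j))) {
      post <- codon
      substr(post, j, j) <- alt
      if (!post %in% STOPS) n <- n + 1L
    }
    n
  }
  expect_equal(byBrute("TAA"), 7L)
  expect_equal(byBrute("TGA"), 8L)
  expect_equal(byBrute("TAG"), 8L)
  for (codon in c("TAA", "TGA", "TAG")) {
    ts <- TranscriptSet("G", "T", paste0("CCATGCCC", codon, "CC"), "ATGGCT")
    rec <- enumerateStopRemovingSnvs(ts)
    expect_equal(nrow(rec), byBrute(codon))
    expect_true(all(rec$kind == "uSTOP_removed"))
  }
})

test_that("stop removal on the fixture gives an out-of-frame oORF", {
  ts <- TranscriptSet("G1", "T1", "ATGAAATGACC", "ATGGCT")
  rec <- enumerateStopRemovingSnvs(ts)
  expect_equal(nrow(rec), 8L)  # TGA
  expect_true(all(rec$consequence == "oORF_out_of_frame"))
  expect_true(all(rec$frame == 2L))    # (11 - 0) mod 3, 0-based form
  expect_true(all(rec$distance_to_cds == 11L))
})

test_that("converging uAUGs yield one stop-removal record set, not two", {
  ts <- TranscriptSet("G1", "T1", "CATGATGCCCTAAC", "ATGGCT")
  rec <- enumerateStopRemovingSnvs(ts)
  expect_equal(nrow(rec), 7L)  # TAA, counted once despite two converging starts
  expect_equal(unique(rec$distance_to_cds), 14L - 2L + 1L)  # 5'-most start
  expect_true(all(rec$kozak == "moderate"))                 # strongest Kozak
})

test_that("deletion enumeration finds junction uAUGs and excludes shifts", {
  # CCCCCC cannot form an ATG by any deletion
  expect_equal(nrow(enumerateUaugDeletions(
    TranscriptSet("G", "T", "CCCCCC", "ATGGCT"))), 0L)
  # A|xxx|TG: deleting the xxx creates ATG at the junction
  ts <- TranscriptSet("G", "T", "CCACCCTGCC", "ATGGCT")
  rec <- enumerateUaugDeletions(ts)
  expect_true(any(rec$pos == 4L & nchar(rec$ref) == 3L))
  hit <- rec[rec$pos == 4L & nchar(rec$ref) == 3L, ]
  expect_equal(hit$ref, "CCC")
  expect_equal(hit$alt, "")
  # deleting just upstream of an existing ATG merely shifts it: excluded
  ts2 <- TranscriptSet("G", "T", "CCCATGCCC", "ATGGCT")
  rec2 <- enumerateUaugDeletions(ts2)
  ora2 <- oracleUaugDeletions("CCCATGCCC")
  expect_equal(nrow(rec2), nrow(ora2))
})

test_that("deletion enumeration equals the apply-and-rescan oracle", {
  set.seed(101)
  for (rep in 1:40) {
    utr <- randomUtr(sample(10:60, 1))
    ts <- TranscriptSet("G", "T", utr, "ATGGCTAAA")
    rec <- enumerateUaugDeletions(ts)
    got <- unique(data.frame(pos = rec$pos, len = nchar(rec$ref),
                             distance_to_cds = rec$distance_to_cds))
    ora <- oracleUaugDeletions(utr)
    got <- got[order(got$pos, got$len), ]
    ora <- ora[order(ora$pos, ora$len), ]
    rownames(got) <- rownames(ora) <- NULL
    expect_equal(got, ora, info = utr)
  }
})

test_that("annotateVariant reproduces the uORF-frameshift mechanism", {
  ts <- TranscriptSet("G1", "T1", "AAGGATGGACTAGCCC", "ATGGCT")
  rec <- annotateVariant(ts, "T1", 10, "", "T")  # insert T after base 9
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$kind, "uORF_frameshifted")
  expect_equal(rec$consequence, "oORF_out_of_frame")
  expect_equal(rec$kozak, "strong")
  expect_equal(rec$distance_to_cds, 13L)
  expect_equal(rec$frame, 1L)
  expect_true(rec$high_impact)
})

test_that("annotateVariant agrees with the enumerators and ignores inert SNVs", {
  set.seed(11)
  for (rep in 1:10) {
    utr <- randomUtr(sample(20:80, 1))
    ts <- TranscriptSet("G", "T", utr, "ATGGCTAAA")
    snvs <- rbind(enumerateUaugSnvs(ts), enumerateStopRemovingSnvs(ts))
    for (i in seq_len(nrow(snvs))) {
      rec <- annotateVariant(ts, "T", snvs$pos[i], snvs$ref[i], snvs$alt[i])
      same <- rec[rec$kind == snvs$kind[i], ]
      expect_gte(nrow(same), 1L)
      j <- which(same$distance_to_cds == snvs$distance_to_cds[i])
      expect_length(j, 1L)
      expect_equal(same$consequence[j], snvs$consequence[i])
      expect_equal(same$kozak[j], snvs$kozak[i])
      expect_equal(same$high_impact[j], snvs$high_impact[i])
    }
  }
  # an SNV touching no ATG or stop emits nothing
  ts <- TranscriptSet("G", "T", "CCCCCCCCC", "ATGGCT")
  expect_equal(nrow(annotateVariant(ts, "T", 5, "C", "A")), 0L)
})

test_that("high-impact rule distinguishes created vs perturbed uORFs", {
  mk <- function(kind, kozak, consequence, evidence = FALSE) {
    data.frame(kind = kind, kozak = kozak, consequence = consequence,
               evidence = evidence)
  }
  expect_true(isHighImpact(mk("uAUG_created", "strong", "oORF_out_of_frame")))
  expect_false(isHighImpact(mk("uAUG_created", "weak", "oORF_out_of_frame")))
  expect_false(isHighImpact(mk("uAUG_created", "strong", "uORF_created")))
  # weak Kozak but documented translation evidence still high-impact for
  # stop-loss when the result runs into the CDS
  expect_true(isHighImpact(mk("uSTOP_removed", "weak", "oORF_out_of_frame", TRUE)))
  expect_false(isHighImpact(mk("uSTOP_removed", "weak", "oORF_out_of_frame", FALSE)))
  expect_true(isHighImpact(mk("uORF_frameshifted", "moderate", "CDS_elongation")))
  expect_false(isHighImpact(mk("uSTOP_removed", "strong", "uORF_elongated")))
})

test_that("every record carries exactly one consequence and Kozak level", {
  set.seed(3)
  for (rep in 1:10) {
    ts <- TranscriptSet("G", "T", randomUtr(sample(30:120, 1)), "ATGGCTAAA")
    rec <- rbind(enumerateUaugSnvs(ts), enumerateStopRemovingSnvs(ts),
                 enumerateUaugDeletions(ts))
    if (!nrow(rec)) next
    expect_true(all(rec$consequence %in%
      c("uORF_created", "uORF_elongated", "oORF_out_of_frame", "CDS_elongation")))
    expect_true(all(rec$kozak %in% c("strong", "moderate", "weak")))
    # CDS_elongation <=> frame 0 and no UTR stop
    noStop <- rec$consequence %in% c("oORF_out_of_frame", "CDS_elongation")
    expect_true(all((rec$consequence == "CDS_elongation") ==
                    (noStop & rec$frame == 0L)))
  }
})

test_that("consequence TSV export has the stable column contract", {
  ts <- TranscriptSet("G1", "T1", "ACGTTTG", "ATGGCT")
  path <- tempfile(fileext = ".tsv")
  writeConsequences(enumerateUaugSnvs(ts), path)
  got <- read.delim(path)
  expect_identical(names(got),
    c("transcript_id", "pos", "ref", "alt", "kind", "consequence", "kozak",
      "minus3", "plus3", "distance_to_cds", "frame", "evidence", "high_impact"))
  expect_equal(nrow(got), 2L)
})
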