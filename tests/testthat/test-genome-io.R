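# Annotation I/O, coordinate conversion, translation and interval services.

test_that("GFF3 coordinates convert to 0-based half-open, with phase trimming", {
  seq <- rand_dna(60, seed = 1)
  p <- write_fixture_gff(seq, c(
    "sx\t.\tCDS\t1\t6\t.\t+\t0\tID=c1",
    "sx\t.\tCDS\t10\t18\t.\t+\t2\tID=c2"
  ))
  ann <- suppressWarnings(read_strain_annotation(p$fasta, p$gff))
  f <- ann$features
  expect_equal(f$start[f$feature_id == "c1"], 0L)
  expect_equal(f$end[f$feature_id == "c1"], 6L)
  # phase 2 trims two bases off the coding 5' end: [9,18) -> [11,18)... not
  # a multiple of 3 would be flagged; here 18-11 = 7 -> pseudogene flag
  expect_equal(f$start[f$feature_id == "c2"], 11L)
  expect_equal(f$end[f$feature_id == "c2"], 18L)
})

test_that("phase-trimmed CDS with broken frame is kept but flagged", {
  seq <- rand_dna(60, seed = 2)
  p <- write_fixture_gff(seq, "sx\t.\tCDS\t10\t18\t.\t+\t2\tID=c2")
  expect_warning(ann <- read_strain_annotation(p$fasta, p$gff),
                 "pseudogenized")
  expect_true(ann$features$pseudogene[1])
})

test_that("empty GFF yields a valid annotation with zero features", {
  seq <- rand_dna(30, seed = 3)
  p <- write_fixture_gff(seq, character(0))
  ann <- read_strain_annotation(p$fasta, p$gff)
  expect_s3_class(ann$features, "tbl_df")
  expect_equal(nrow(ann$features), 0L)
  expect_equal(ann$length, 30L)
})

test_that("duplicate feature ids are rejected", {
  seq <- rand_dna(60, seed = 4)
  p <- write_fixture_gff(seq, c(
    "sx\t.\tCDS\t1\t6\t.\t+\t0\tID=c1",
    "sx\t.\tCDS\t10\t15\t.\t+\t0\tID=c1"
  ))
  expect_error(read_strain_annotation(p$fasta, p$gff), "duplicate")
})

test_that("write then read round-trips sequence and features", {
  seq <- rand_dna(300, seed = 5)
  ann <- make_ann("s1", seq,
                  feat("a", "CDS", 30, 90, "+", cov = 12),
                  feat("b", "CDS", 120, 180, "-"),
                  feat("n", "ncRNA", 200, 260, "-", cov = 44.5),
                  feat("u", "UTR5", 20, 30, "+"))
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_strain_annotation(ann, fa, gff)
  back <- read_strain_annotation(fa, gff)
  expect_equal(back$sequence, ann$sequence)
  cols <- c("feature_id", "kind", "start", "end", "strand", "median_coverage")
  expect_equal(as.data.frame(back$features[order(back$features$feature_id), cols]),
               as.data.frame(ann$features[order(ann$features$feature_id), cols]))
})

test_that("six-frame translation matches hand cases and the ambiguity rule", {
  sf <- six_frame_translate("ATGAAA")
  expect_equal(sf$peptide[sf$frame == 1L], "MK")
  expect_equal(sf$peptide[sf$frame == -1L], "FH")  # revcomp = TTTCAT
  sf2 <- six_frame_translate("ATGNAA")
  expect_equal(sf2$peptide[sf2$frame == 1L], "MX")
})

test_that("reverse frames equal forward frames of the reverse complement", {
  set.seed(42)
  for (i in 1:25) {
    s <- rand_dna(sample(10:200, 1))
    sf <- six_frame_translate(s)
    rc <- six_frame_translate(revcomp(s))
    for (k in 1:3) {
      expect_equal(sf$peptide[sf$frame == -k], rc$peptide[rc$frame == k])
    }
  }
})

test_that("noncoding intervals complement the CDS union and tile the genome", {
  ann <- make_ann("s1", rand_dna(100, seed = 6),
                  feat("a", "CDS", 10, 40))
  expect_equal(as.data.frame(noncoding_intervals(ann)),
               data.frame(start = c(0L, 40L), end = c(10L, 100L)))
  # overlapping CDS merge before complementing (pseudogene flag keeps the
  # frame check out of the way for interval arithmetic)
  ann2 <- strain_annotation("s2", rand_dna(100, seed = 7), tibble::tibble(
    feature_id = c("a", "b"), kind = "CDS", start = c(10L, 30L),
    end = c(40L, 60L), strand = "+", pseudogene = c(FALSE, TRUE)))
  expect_equal(as.data.frame(noncoding_intervals(ann2)),
               data.frame(start = c(0L, 60L), end = c(10L, 100L)))
  ann3 <- make_ann("s3", rand_dna(50, seed = 8))
  expect_equal(as.data.frame(noncoding_intervals(ann3)),
               data.frame(start = 0L, end = 50L))
})

test_that("noncoding + coding lengths account for the whole genome", {
  set.seed(9)
  for (i in 1:20) {
    L <- 500L
    n_cds <- sample(0:6, 1)
    starts <- sort(sample(0:(L - 30L), n_cds))
    feats <- if (n_cds > 0) tibble::tibble(
      feature_id = paste0("c", seq_len(n_cds)), kind = "CDS",
      start = starts, end = pmin(starts + sample(c(30L, 60L, 90L), n_cds,
                                                 replace = TRUE), L),
      strand = "+", pseudogene = TRUE) else NULL
    ann <- strain_annotation("s", rand_dna(L), feats)
    nc <- noncoding_intervals(ann)
    cds_union <- microevo:::merge_intervals(ann$features$start,
                                            ann$features$end)
    expect_equal(sum(nc$end - nc$start) + sum(cds_union$end - cds_union$start),
                 L)
    expect_true(all(nc$start < nc$end))
    if (nrow(nc) > 1) expect_true(all(diff(nc$start) > 0))
  }
})

test_that("the bundled unique-gene table parses into 30 typed records", {
  t1 <- read_table1_fixture()
  expect_equal(nrow(t1), 30L)
  r11 <- t1[t1$gene_id == "pclt_cds_11", ]
  expect_equal(r11$length_aa, 69L)
  expect_equal(r11$most_ancestral_detection, 5L)
  expect_true(r11$predicted_dna_binding)
  expect_true(is.na(t1$most_ancestral_detection[t1$gene_id == "pqer_cds_350"]))
  expect_equal(t1$median_coverage[t1$gene_id == "pclt_cds_1081"], 12090)
  expect_equal(t1$homolog_context[t1$gene_id == "pclt_cds_308"], "ncRNA")
  expect_equal(t1$homolog_context[t1$gene_id == "pqer_cds_685"],
               "alternative_frame")
  expect_equal(t1$homolog_context[t1$gene_id == "pqer_cds_143"],
               "antisense_utr5")
})
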