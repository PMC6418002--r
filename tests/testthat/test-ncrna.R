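# Expression validation, ncRNA calling/classification, cross-strain
# matching.

test_that("expression validation applies a strict > threshold", {
  f <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                      median_coverage = c(5, 5.01, 12, NA))
  v <- validate_gene_expression(f, threshold = 5)
  expect_equal(v$kept$feature_id, c("b", "c"))
  expect_equal(v$rejected$feature_id, "a")
  expect_equal(v$unevaluated$feature_id, "d")
})

test_that("all 30 published unique genes clear the expression threshold", {
  t1 <- read_table1_fixture()
  v <- validate_gene_expression(t1)
  expect_equal(nrow(v$kept), 30L)
  expect_equal(min(v$kept$median_coverage), 13)
})

track_for <- function(intervals, strand, depth) {
  purrr::pmap_dfr(intervals, function(start, end) {
    tibble::tibble(pos = seq.int(start, end - 1L), strand = strand,
                   depth = depth)
  })
}

test_that("zero coverage yields no ncRNA calls", {
  ann <- make_ann("s", rand_dna(2000, seed = 100))
  empty <- tibble::tibble(pos = integer(0), strand = character(0),
                          depth = numeric(0))
  expect_equal(nrow(call_ncrna_regions(empty, ann)), 0L)
})

test_that("a high-coverage block opposite a CDS is called antisense", {
  ann <- make_ann("s", rand_dna(3000, seed = 101),
                  feat("c1", "CDS", 500, 1100, "+"))
  track <- dplyr::bind_rows(
    track_for(tibble::tibble(start = 500L, end = 1100L), "+", 80),
    track_for(tibble::tibble(start = 550L, end = 1050L), "-", 40))
  calls <- call_ncrna_regions(track, ann, min_len = 200)
  # the plus-strand run contains a same-strand CDS -> only minus survives
  expect_equal(calls$strand, "-")
  expect_equal(calls$start, 550L)
  cls <- classify_ncrna(calls, ann)
  expect_equal(cls$class, "antisense")
})

test_that("runs below min_len or threshold are dropped", {
  ann <- make_ann("s", rand_dna(2000, seed = 102))
  track <- dplyr::bind_rows(
    track_for(tibble::tibble(start = 0L, end = 150L), "+", 50),    # short
    track_for(tibble::tibble(start = 300L, end = 700L), "+", 4))   # weak
  expect_equal(nrow(call_ncrna_regions(track, ann, min_len = 200)), 0L)
})

test_that("the antisense rule is strictly more than half", {
  ann <- make_ann("s", rand_dna(2000, seed = 103),
                  feat("c1", "CDS", 0, 300, "+"))
  call <- tibble::tibble(call_id = "n1", start = 0L, end = 600L,
                         strand = "-", median_coverage = 50)
  expect_equal(classify_ncrna(call, ann)$class, "intergenic")  # exactly 50%
  call2 <- dplyr::mutate(call, end = 598L)                     # > 50%
  expect_equal(classify_ncrna(call2, ann)$class, "antisense")
  call3 <- dplyr::mutate(call, end = 750L)                     # 40%
  expect_equal(classify_ncrna(call3, ann)$class, "intergenic")
})

test_that("planted transcribed ncRNAs are all recalled when fully on", {
  tr <- pandoravirus_tree()
  sim <- simulate_family(tr, sim_params(seed = 104, n_ancestral_genes = 4L,
                                        birth_rate = 0, death_rate = 0,
                                        n_ncrna = 5L, ncrna_on_prob = 1))
  ann <- sim$annotations[["p_celtis"]]
  ann <- simulate_coverage(ann, on_fraction = 1, seed = 105)
  track <- simulate_coverage_track(ann)
  calls <- call_ncrna_regions(track, ann, min_len = 150)
  planted <- ann$features[ann$features$kind == "ncRNA", ]
  expect_equal(nrow(planted), 5L)
  recalled <- vapply(seq_len(nrow(planted)), function(i) {
    any(calls$strand == planted$strand[i] &
          calls$start <= planted$start[i] & calls$end >= planted$end[i])
  }, logical(1))
  expect_true(all(recalled))
})

test_that("identical ncRNA sets match fully, disjoint ones not at all", {
  set.seed(106)
  g <- rand_dna(6000)
  calls <- tibble::tibble(call_id = paste0("n", 1:3),
                          start = c(100L, 2000L, 4000L),
                          end = c(600L, 2600L, 4700L), strand = "+")
  m <- match_ncrna_across_strains(calls, calls, g, g)
  expect_equal(nrow(m$pairs), 3L)
  expect_equal(m$pairs$call_a, m$pairs$call_b)
  expect_length(m$unmatched_a, 0L)
  g2 <- rand_dna(6000)
  m2 <- match_ncrna_across_strains(calls, calls, g, g2)
  expect_equal(nrow(m2$pairs), 0L)
  expect_length(m2$unmatched_a, 3L)
})

test_that("matching is symmetric between the strains", {
  set.seed(107)
  g1 <- rand_dna(6000)
  # strain 2 shares two of three loci (with light mutation), third differs
  mut <- function(s) {
    ch <- strsplit(s, "")[[1]]
    k <- sample(length(ch), round(length(ch) * 0.05))
    ch[k] <- sapply(ch[k], function(b) sample(setdiff(c("A","C","G","T"), b), 1))
    paste(ch, collapse = "")
  }
  g2 <- paste0(mut(substr(g1, 1, 3000)), rand_dna(3000))
  ca <- tibble::tibble(call_id = paste0("a", 1:3),
                       start = c(100L, 1500L, 4000L),
                       end = c(700L, 2100L, 4600L), strand = "+")
  cb <- tibble::tibble(call_id = paste0("b", 1:3),
                       start = c(100L, 1500L, 4000L),
                       end = c(700L, 2100L, 4600L), strand = "+")
  m_ab <- match_ncrna_across_strains(ca, cb, g1, g2)
  m_ba <- match_ncrna_across_strains(cb, ca, g2, g1)
  expect_equal(nrow(m_ab$pairs), 2L)
  expect_equal(sort(paste(m_ab$pairs$call_a, m_ab$pairs$call_b)),
               sort(paste(m_ba$pairs$call_b, m_ba$pairs$call_a)))
})

test_that("every call gets exactly one class and the counts add up", {
  ann <- make_ann("s", rand_dna(5000, seed = 108),
                  feat("c1", "CDS", 1000, 1600, "+"))
  calls <- tibble::tibble(call_id = paste0("n", 1:4),
                          start = c(0L, 1000L, 2000L, 3000L),
                          end = c(400L, 1600L, 2400L, 3500L),
                          strand = c("+", "-", "-", "+"),
                          median_coverage = 50)
  cls <- classify_ncrna(calls, ann)
  expect_equal(nrow(cls), 4L)
  expect_true(all(cls$class %in% c("antisense", "intergenic")))
  expect_equal(sum(cls$class == "antisense") + sum(cls$class == "intergenic"),
               4L)
})
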