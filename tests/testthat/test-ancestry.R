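# Translated non-coding search, E-value statistics, node assignment and
# hit-context classification.

test_that("Karlin-Altschul closed forms hold", {
  expect_equal(karlin_altschul_evalue(0, 100, 1000), 0.13 * 100 * 1000)
  expect_equal(karlin_altschul_evalue(30, 50, 2e6),
               2 * karlin_altschul_evalue(30, 50, 1e6))
  expect_equal(karlin_altschul_evalue(50, 100, 1e6),
               0.13 * 1e8 * exp(-0.318 * 50) / 100 * 100)
})

test_that("a planted back-translated query is found at its location", {
  set.seed(50)
  prot <- rand_protein(80)
  bt <- back_translate(prot)
  genome <- paste0(rand_dna(8000, 0.57), bt, rand_dna(8000, 0.57))
  ann <- make_ann("s1", genome)
  hits <- translated_noncoding_search(prot, ann)
  expect_gt(nrow(hits), 0L)
  expect_equal(hits$start[1], 8000L)
  expect_equal(hits$end[1], 8000L + nchar(bt))
  expect_lt(hits$evalue[1], 1e-20)
})

test_that("hits inside a same-strand in-frame CDS are masked out", {
  set.seed(51)
  prot <- rand_protein(80)
  bt <- back_translate(prot)
  genome <- paste0(rand_dna(6000, 0.57), bt, rand_dna(6000, 0.57))
  cds <- feat("c1", "CDS", 6000L, 6000L + nchar(bt), "+")
  ann <- make_ann("s1", genome, cds)
  expect_equal(nrow(translated_noncoding_search(prot, ann)), 0L)
  # but an antisense overlap is kept: same plant, CDS on the minus strand
  ann2 <- make_ann("s2", genome, feat("c1", "CDS", 6000L,
                                      6000L + nchar(bt), "-"))
  expect_gt(nrow(translated_noncoding_search(prot, ann2)), 0L)
})

test_that("false-positive rate on random subjects is near the E budget", {
  set.seed(52)
  subj <- make_ann("r", rand_dna(100000, 0.5))
  idx <- subject_frame_index(subj)
  n_q <- 60
  fp <- sum(vapply(seq_len(n_q), function(i) {
    nrow(translated_noncoding_search(rand_protein(100), subj, index = idx))
  }, numeric(1)))
  # ungapped Karlin-Altschul regime: within 3x of E_max * queries, plus an
  # allowance of 1 for discreteness at tiny expected counts
  expect_lte(fp, 3 * 1e-3 * n_q + 1)
})

test_that("MRCA assignment matches Table-1 semantics on the fixture tree", {
  tr <- pandoravirus_tree()
  none <- assign_creation_node(tr, "p_celtis", character(0))
  expect_true(is.na(none$node))
  expect_equal(assign_creation_node(tr, "p_celtis", "p_quercus")$node, "9")
  expect_equal(assign_creation_node(tr, "p_celtis",
                                    c("p_quercus", "p_inopinatum"))$node, "8")
  expect_equal(assign_creation_node(tr, "p_celtis", "p_salinus")$node, "2")
  expect_error(assign_creation_node(tr, "p_celtis", "p_bogus"), "not in tree")
})

test_that("adding evidence never moves the assignment tip-ward", {
  tr <- pandoravirus_tree()
  phy <- tr$phylo
  depth <- setNames(ape::node.depth.edgelength(phy),
                    c(phy$tip.label, phy$node.label))
  others <- setdiff(tree_leaves(tr), "p_celtis")
  set.seed(53)
  for (i in 1:20) {
    ev <- sample(others, sample(1:8, 1))
    extra <- sample(setdiff(others, ev), 1)
    n1 <- assign_creation_node(tr, "p_celtis", ev)$node
    n2 <- assign_creation_node(tr, "p_celtis", c(ev, extra))$node
    expect_lte(depth[[n2]], depth[[n1]])
  }
})

test_that("MRCA equals a path-intersection oracle on 100 random trees", {
  for (i in 1:100) {
    tr <- rand_labeled_tree(10, seed = 1000 + i)
    phy <- tr$phylo
    set.seed(2000 + i)
    leaves <- sample(phy$tip.label, sample(2:6, 1))
    expect_equal(mrca_label(tr, leaves), oracle_mrca(phy, leaves))
  }
})

test_that("hit contexts follow the priority rules", {
  genome <- rand_dna(3000, seed = 54)
  ann <- make_ann("s", genome,
                  feat("c1", "CDS", 300, 600, "+"),
                  feat("c2", "CDS", 900, 1200, "-"),
                  feat("u1", "UTR5", 1500, 1600, "+"),
                  feat("n1", "ncRNA", 1800, 2100, "+"))
  hit <- function(s, e, frame) list(start = s, end = e, frame = frame)
  # wholly between genes
  expect_equal(classify_hit_context(hit(2500, 2600, 1L), ann), "intergenic")
  # inside plus-strand CDS, opposite strand hit
  expect_equal(classify_hit_context(hit(360, 480, -1L), ann), "antisense_cds")
  # same strand as c1 but shifted frame: start 301 vs CDS start 300
  expect_equal(classify_hit_context(hit(301, 421, 1L), ann),
               "alternative_frame")
  expect_equal(classify_hit_context(hit(1500, 1590, 1L), ann), "utr5")
  expect_equal(classify_hit_context(hit(1850, 2000, 1L), ann),
               "ncRNA_overlap")
})

test_that("node distribution counting is exact on the published table", {
  t1 <- read_table1_fixture()
  nd <- summarize_node_distribution(
    tibble::tibble(node = as.character(t1$most_ancestral_detection)))
  want <- c("2" = 6L, "5" = 4L, "8" = 8L, "9" = 5L, None = 7L)
  expect_equal(setNames(nd$n, nd$node), want)
  empty <- summarize_node_distribution(tibble::tibble(node = character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("strict assignment requires the whole clade to carry evidence", {
  tr <- pandoravirus_tree()
  # evidence in p_quercus only: plain MRCA says node 9, strict agrees
  expect_equal(assign_creation_node(tr, "p_celtis", "p_quercus",
                                    strict = TRUE)$node, "9")
  # evidence in salinus but NOT in the intermediate clade members: plain
  # MRCA jumps to node 2, strict refuses to go past node 9
  loose <- assign_creation_node(tr, "p_celtis",
                                c("p_quercus", "p_salinus"))$node
  strict <- assign_creation_node(tr, "p_celtis",
                                 c("p_quercus", "p_salinus"),
                                 strict = TRUE)$node
  expect_equal(loose, "2")
  expect_equal(strict, "9")
})
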