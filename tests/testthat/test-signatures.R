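# CAI, G+C, amino-acid composition chi-square, Wilcoxon signature report,
# unique-gene table summary.

test_that("relative adaptiveness follows the Sharp-Li definition", {
  uniform <- setNames(rep(10L, 64), microevo:::ALL_CODONS)
  w <- relative_adaptiveness(uniform)
  expect_true(all(w == 1))
  usage <- setNames(rep(0L, 64), microevo:::ALL_CODONS)
  usage["TTT"] <- 30L; usage["TTC"] <- 10L
  usage["ATG"] <- 5L; usage["TGG"] <- 5L   # keep totals positive elsewhere
  w2 <- relative_adaptiveness(usage)
  expect_equal(w2[["TTT"]], 1)
  expect_equal(w2[["TTC"]], 1 / 3)
  expect_equal(w2[["GGG"]], 0.01)          # zero-count floor
  expect_equal(w2[["ATG"]], 1)             # single-codon family
})

test_that("CAI is a geometric mean over codons with stop handling", {
  w <- setNames(rep(1, 61), microevo:::SENSE_CODONS)
  expect_equal(cai("ATGAAATAA", w), 1)     # terminal stop dropped
  w2 <- w; w2["AAA"] <- 0.25
  expect_equal(cai("AAAATG", w2), 0.5)     # sqrt(0.25 * 1)
  expect_error(cai("ATGTAAAAA", w), "internal stop")
  expect_error(cai("ATGAA", w), "multiple of 3")
})

test_that("CAI is invariant under codon permutation and composes as a
           weighted geometric mean", {
  set.seed(80)
  usage <- codon_usage(replicate(20, rand_cds(100)))
  w <- relative_adaptiveness(usage)
  cods <- sample(microevo:::SENSE_CODONS, 60, replace = TRUE)
  g1 <- paste(cods, collapse = "")
  g2 <- paste(sample(cods), collapse = "")
  expect_equal(cai(g1, w), cai(g2, w))
  h <- paste(sample(microevo:::SENSE_CODONS, 30, replace = TRUE),
             collapse = "")
  combo <- cai(paste0(g1, h), w)
  expect_equal(combo, exp((60 * log(cai(g1, w)) + 30 * log(cai(h, w))) / 90))
})

test_that("the modal-codon gene of the reference set has CAI exactly 1", {
  set.seed(81)
  usage <- codon_usage(replicate(30, rand_cds(120)))
  w <- relative_adaptiveness(usage)
  modal <- vapply(microevo:::synonymous_families(), function(fam) {
    fam[which.max(usage[fam])]
  }, character(1))
  expect_equal(cai(paste(modal, collapse = ""), w), 1)
})

test_that("G+C content handles ambiguity and is revcomp-invariant", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ATGCNN"), 0.5)  # N excluded from denominator
  expect_error(gc_content("NNN"), "unambiguous")
  set.seed(82)
  for (i in 1:100) {
    s <- rand_dna(sample(10:300, 1), gc = runif(1, 0.2, 0.8))
    expect_equal(gc_content(s), gc_content(revcomp(s)))
  }
})

test_that("identical sets give a zero chi-square statistic", {
  set.seed(83)
  prots <- replicate(10, rand_protein(100))
  r <- composition_chi_square(prots, prots)
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 19L)
  expect_equal(r$p_value, 1)
})

test_that("null-drawn sets give statistic near df", {
  set.seed(84)
  freq <- runif(20, 0.5, 2); freq <- freq / sum(freq)
  ref <- paste(sample(AA20, 50000, TRUE, prob = freq), collapse = "")
  ref_f <- microevo:::residue_counts(ref); ref_f <- ref_f / sum(ref_f)
  stats <- replicate(60, {
    a <- paste(sample(names(ref_f), 4000, TRUE, prob = ref_f), collapse = "")
    composition_chi_square(a, ref)$statistic
  })
  expect_lt(abs(mean(stats) - 19), 3)
})

test_that("a lysine enrichment like the observed one is detected", {
  set.seed(85)
  base <- c(rep(1, 20)); names(base) <- AA20
  base["K"] <- 2; base <- base / sum(base)        # background: K at 2%
  shifted <- base; shifted["K"] <- shifted["K"] * 2.6 # novel: K to ~5%
  shifted <- shifted / sum(shifted)
  ref <- paste(sample(AA20, 60000, TRUE, prob = base), collapse = "")
  novel <- paste(sample(AA20, 3800, TRUE, prob = shifted), collapse = "")
  null_q99 <- qchisq(0.99, df = 19)
  expect_gt(composition_chi_square(novel, ref)$statistic, null_q99)
})

test_that("signature report separates shifted length distributions", {
  set.seed(86)
  novel <- tibble::tibble(gene_id = paste0("n", 1:30),
                          nt = replicate(30, rand_cds(
                            max(30, round(rlnorm(1, log(126), 0.35))))))
  backg <- tibble::tibble(gene_id = paste0("b", 1:200),
                          nt = replicate(200, rand_cds(
                            max(30, round(rlnorm(1, log(387), 0.35))))))
  rep <- signature_report(novel, backg)
  lenrow <- rep[rep$metric == "length_aa", ]
  expect_lt(lenrow$p_value, 1e-6)
  expect_lt(lenrow$mean_novel, lenrow$mean_background)
})

test_that("identical gene sets give no separation in the report", {
  set.seed(87)
  genes <- tibble::tibble(gene_id = paste0("g", 1:20),
                          nt = replicate(20, rand_cds(100)))
  rep <- signature_report(genes, genes)
  expect_true(all(abs(rep$mean_novel - rep$mean_background) < 1e-12))
  expect_true(all(rep$p_value > 0.9))
})

test_that("simulated newborn genes show the lower-GC signature", {
  tr <- pandoravirus_tree()
  phy <- tr$phylo; phy$edge.length <- phy$edge.length * 0.1
  sim <- simulate_family(labeled_tree(phy),
                         sim_params(seed = 88, n_ancestral_genes = 12L,
                                    birth_rate = 1.5, death_rate = 0,
                                    intergenic_len = 150L, n_ncrna = 0L))
  leaf <- sim$annotations[["p_celtis"]]
  newborn_ids <- sim$truth$gene_id[sim$truth$origin == "protogene_birth"]
  f <- leaf$features[leaf$features$kind == "CDS", ]
  nt <- vapply(f$feature_id, function(g) microevo:::feature_nt(leaf, g),
               character(1))
  is_new <- f$feature_id %in% newborn_ids
  expect_gt(sum(is_new), 0L)
  rep <- signature_report(
    tibble::tibble(gene_id = f$feature_id[is_new], nt = nt[is_new]),
    tibble::tibble(gene_id = f$feature_id[!is_new], nt = nt[!is_new]))
  gcrow <- rep[rep$metric == "gc", ]
  expect_lt(gcrow$mean_novel, gcrow$mean_background)
})

test_that("unique-gene table summary does exact arithmetic", {
  t1 <- read_table1_fixture()
  s <- summarize_unique_gene_table(t1)
  expect_equal(s$n_total, 30L)
  expect_equal(unname(s$n_per_strain[c("p_celtis", "p_quercus")]), c(9L, 21L))
  expect_equal(s$mean_length_aa, 126.7)  # rounded display value
  expect_equal(s$n_dna_binding, 25L)
  expect_equal(s$n_no_trace, 7L)
  empty <- summarize_unique_gene_table(t1[0, ])
  expect_equal(empty$n_total, 0L)
})
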