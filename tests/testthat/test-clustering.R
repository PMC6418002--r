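# Protein clustering, accumulation curves, pan increment, RBH pairing.

test_that("identity and coverage behave on identical and near pairs", {
  r <- pairwise_protein_identity("MKVLQW", "MKVLQW")
  expect_equal(r$identity, 1)
  expect_equal(r$coverage, 1)
  r2 <- pairwise_protein_identity("MKV", "MRV")
  expect_equal(r2$identity, 2 / 3)
})

test_that("random 100-aa pairs score well below the clustering threshold", {
  set.seed(30)
  ids <- replicate(40, {
    pairwise_protein_identity(rand_protein(100), rand_protein(100))$identity
  })
  expect_lt(mean(ids), 0.3)
})

test_that("three identical proteins across strains form one core cluster", {
  p <- rand_protein(80, seed = 31)
  prot <- tibble::tibble(strain = c("s1", "s2", "s3"),
                         gene_id = c("g1", "g1", "g1"), protein = p)
  pcs <- cluster_proteins(prot)
  expect_equal(nrow(pcs$presence), 1L)
  expect_true(all(pcs$presence))
  expect_equal(glance(pcs)$n_core, 1L)
})

test_that("single linkage chains A~B~C into one cluster even when A !~ C", {
  # two mutation ladders: B shares half its length with each of A and C;
  # A and C share nothing
  set.seed(32)
  half1 <- rand_protein(60); half2 <- rand_protein(60)
  a <- paste0(half1, rand_protein(60))
  b <- paste0(half1, half2)
  cc <- paste0(rand_protein(60), half2)
  prot <- tibble::tibble(strain = c("s1", "s2", "s3"),
                         gene_id = c("a", "b", "c"),
                         protein = c(a, b, cc))
  ac <- pairwise_protein_identity(a, cc)
  expect_lt(ac$identity * ac$coverage, 0.3)  # no A-C edge
  pcs <- cluster_proteins(prot, min_identity = 0.30, min_coverage = 0.50)
  expect_equal(nrow(pcs$presence), 1L)
})

test_that("clustering is invariant to input order", {
  set.seed(33)
  base <- replicate(5, rand_protein(70))
  prot <- tibble::tibble(
    strain = rep(c("s1", "s2"), each = 5),
    gene_id = rep(paste0("g", 1:5), 2),
    protein = c(base, base))
  pcs1 <- cluster_proteins(prot)
  pcs2 <- cluster_proteins(prot[sample(nrow(prot)), ])
  expect_equal(pcs1$members, pcs2$members)
})

test_that("exhaustive accumulation equals brute-force set arithmetic", {
  set.seed(34)
  for (rep in 1:5) {
    G <- sample(3:5, 1)
    universe <- paste0("cl", 1:12)
    sets <- replicate(G, sample(universe, sample(4:9, 1)), simplify = FALSE)
    curve <- accumulation_curves(presence_from_sets(sets))
    oc <- oracle_curve(sets)
    got <- dplyr::arrange(tibble::as_tibble(curve), g, pan, core)
    want <- dplyr::arrange(tibble::as_tibble(oc), g, pan, core)
    expect_equal(got[c("g", "pan", "core")], want)
  }
})

test_that("pan is monotone non-decreasing and core non-increasing in g", {
  set.seed(35)
  sets <- replicate(5, sample(paste0("cl", 1:15), sample(5:10, 1)),
                    simplify = FALSE)
  s <- summarize_accumulation(accumulation_curves(presence_from_sets(sets)))
  expect_true(all(diff(s$pan_median) >= 0))
  expect_true(all(diff(s$core_median) <= 0))
  # stronger: means over combinations are monotone too
  expect_true(all(diff(s$pan_min) >= 0))
  expect_true(all(diff(s$core_max) <= 0))
})

test_that("identical strains give flat curves and zero increment", {
  sets <- replicate(4, paste0("cl", 1:7), simplify = FALSE)
  curve <- accumulation_curves(presence_from_sets(sets))
  expect_true(all(curve$pan == 7))
  expect_true(all(curve$core == 7))
  expect_equal(pan_increment(curve), 0)
})

test_that("shared + private clusters give the closed-form pan increment", {
  # each strain: 5 shared clusters + 3 private ones -> increment 3
  sets <- lapply(1:4, function(i) c(paste0("sh", 1:5), paste0("pr", i, 1:3)))
  curve <- accumulation_curves(presence_from_sets(sets))
  expect_equal(pan_increment(curve), 3)
})

test_that("reciprocal best pairing recovers identity mapping and leaves extras", {
  set.seed(36)
  base <- replicate(3, rand_protein(90))
  a <- tibble::tibble(gene_id = paste0("a", 1:4),
                      protein = c(base, rand_protein(90)))
  b <- tibble::tibble(gene_id = paste0("b", 1:3), protein = base)
  pairs <- reciprocal_best_pairs(a, b)
  expect_equal(pairs$gene_b[match(paste0("a", 1:3), pairs$gene_a)],
               paste0("b", 1:3))
  expect_true(is.na(pairs$gene_b[pairs$gene_a == "a4"]))
})

test_that("simulated families cluster back to their true gene count", {
  tr <- pandoravirus_tree()
  phy <- tr$phylo; phy$edge.length <- phy$edge.length * 0.2  # low divergence
  tr <- labeled_tree(phy)
  sim <- simulate_family(tr, sim_params(seed = 40, n_ancestral_genes = 5L,
                                        birth_rate = 0, death_rate = 0,
                                        ancestral_length_meanlog = log(150),
                                        intergenic_len = 100L, n_ncrna = 0L))
  prot <- dplyr::bind_rows(lapply(sim$annotations, annotation_proteins))
  # iid-composition simulated proteins have a higher chance-identity floor
  # than real proteomes (measured effective-identity ceiling ~0.37 for
  # unrelated pairs), so truth recovery runs above it
  pcs <- cluster_proteins(prot, min_identity = 0.4)
  expect_equal(nrow(pcs$presence), nrow(sim$truth))
  expect_true(all(rowSums(pcs$presence) == length(sim$annotations)))
})
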