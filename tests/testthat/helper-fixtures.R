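# Shared fixture builders: everything is generated in code at test time.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

rand_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

rand_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  microevo:::random_dna(n, gc)
}

# back-translate a protein with uniformly chosen synonymous codons
back_translate <- function(prot, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- microevo:::GENETIC_CODE_VEC
  vap <- vapply(strsplit(prot, "")[[1]], function(a) {
    sample(names(code)[code == a], 1L)
  }, character(1))
  paste(vap, collapse = "")
}

# a random stop-free coding sequence (with ATG start, terminal stop)
rand_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- microevo:::SENSE_CODONS
  paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE), "TAA"),
        collapse = "")
}

# minimal annotation: one genome string + feature rows given as lists
make_ann <- function(sid, seq, ...) {
  rows <- list(...)
  feats <- if (length(rows) > 0L) dplyr::bind_rows(rows) else NULL
  strain_annotation(sid, seq, feats)
}

feat <- function(id, kind, start, end, strand = "+", cov = NA_real_) {
  tibble::tibble(feature_id = id, kind = kind, start = start, end = end,
                 strand = strand, median_coverage = cov)
}

# random labeled rooted tree with n leaves, labels N1..N(n-1)
rand_labeled_tree <- function(n_leaves, seed) {
  set.seed(seed)
  phy <- ape::rtree(n_leaves)
  phy$node.label <- paste0("N", seq_len(phy$Nnode))
  labeled_tree(phy)
}

# write a small FASTA + GFF3 pair into tempdir, return the two paths
write_fixture_gff <- function(seq, gff_rows, sid = "sx") {
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(paste0(">", sid), seq), fa)
  writeLines(c("##gff-version 3", gff_rows), gff)
  list(fasta = fa, gff = gff)
}
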