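# Compositional statistics separating newborn genes from the established
# proteome: Codon Adaptation Index (Sharp & Li relative adaptiveness), G+C
# content, protein length, and pooled amino-acid composition chi-square,
# with Wilcoxon rank-sum contrasts.

#' Codon usage counts of a gene set
#'
#' @param genes character vector of in-frame coding sequences.
#' @return named integer vector of 64 codon counts.
#' @export
codon_usage <- function(genes) {
  counts <- setNames(integer(64), ALL_CODONS)
  for (g in genes) {
    cods <- split_codons(toupper(g))
    cods <- cods[cods %in% ALL_CODONS]
    t <- table(cods)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  counts
}

# synonymous families over the sense codons
synonymous_families <- function() {
  split(SENSE_CODONS, GENETIC_CODE_VEC[SENSE_CODONS])
}

#' Relative adaptiveness of codons (Sharp & Li w)
#'
#' Within each synonymous family, `w(c) = count(c) / max count`; unused
#' codons are floored so the geometric mean stays defined. Single-codon
#' families (Met, Trp) get w = 1. Stop codons are excluded.
#'
#' @param usage named codon counts (as from [codon_usage()]).
#' @param floor value assigned to zero-count codons (and whole all-zero
#'   families).
#' @return named numeric vector over the 61 sense codons, in (0, 1].
#' @export
relative_adaptiveness <- function(usage, floor = 0.01) {
  stopifnot(sum(usage) > 0)
  w <- setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  for (fam in synonymous_families()) {
    cnt <- usage[fam]
    cnt[is.na(cnt)] <- 0
    mx <- max(cnt)
    if (mx == 0) {
      w[fam] <- floor
    } else {
      wf <- cnt / mx
      wf[wf == 0] <- floor
      w[fam] <- wf
    }
  }
  w
}

#' Codon Adaptation Index of a gene
#'
#' Geometric mean of the relative adaptiveness over the gene's codons; the
#' terminal stop is dropped and Met/Trp are included with their neutral
#' w = 1. An internal stop is rejected (pseudogene guard).
#'
#' @param gene in-frame coding sequence (length a multiple of 3).
#' @param w relative adaptiveness from [relative_adaptiveness()].
#' @return CAI in (0, 1].
#' @export
cai <- function(gene, w) {
  gene <- toupper(gene)
  if (nchar(gene) %% 3L != 0L) stop("gene length not a multiple of 3")
  cods <- drop_terminal_stop(split_codons(gene))
  if (any(cods %in% STOP_CODONS)) stop("internal stop codon")
  cods <- cods[cods %in% SENSE_CODONS]
  if (length(cods) == 0L) stop("no sense codons")
  exp(mean(log(w[cods])))
}

#' G+C content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; ambiguity characters are excluded from the
#' denominator.
#'
#' @param seq nucleotide sequence.
#' @return fraction in [0, 1].
#' @export
#' @examples
#' gc_content("ATGC")
gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  acgt <- chars[chars %in% NUCS]
  if (length(acgt) == 0L) stop("no unambiguous bases")
  sum(acgt %in% c("G", "C")) / length(acgt)
}

# pooled amino-acid counts over the 20 residues
residue_counts <- function(proteins) {
  chars <- unlist(strsplit(toupper(paste(proteins, collapse = "")), ""))
  chars <- chars[chars %in% AMINO_ACIDS]
  counts <- setNames(integer(length(AMINO_ACIDS)), AMINO_ACIDS)
  t <- table(chars)
  counts[names(t)] <- as.integer(t)
  counts
}

#' Amino-acid composition chi-square between two protein sets
#'
#' Pearson chi-square of set A's pooled residue counts against expected
#' counts from set B's residue frequencies scaled to A's total; df = 19
#' for the 20 amino-acid categories. A residue absent from set B gets a
#' 0.5 pseudocount in both sets.
#'
#' @param set_a,set_b character vectors of peptide sequences.
#' @return tibble `statistic`, `df`, `p_value`.
#' @export
composition_chi_square <- function(set_a, set_b) {
  stopifnot(length(set_a) > 0, length(set_b) > 0)
  obs <- residue_counts(set_a)
  ref <- residue_counts(set_b)
  zero <- ref == 0
  if (any(zero)) {
    obs <- obs + ifelse(zero, 0.5, 0)
    ref <- ref + ifelse(zero, 0.5, 0)
  }
  expd <- ref / sum(ref) * sum(obs)
  stat <- sum((obs - expd)^2 / expd)
  tibble::tibble(statistic = stat, df = 19L,
                 p_value = pchisq(stat, df = 19L, lower.tail = FALSE))
}

#' Signature report: CAI, G+C and length contrasts with Wilcoxon tests
#'
#' Per-set means and two-sided Wilcoxon rank-sum p-values (normal
#' approximation with tie correction) for the three statistics that
#' separate newborn genes from the established proteome. Gene tibbles
#' need `gene_id` and `nt` (coding sequence) columns.
#'
#' @param novel,background tibbles with `gene_id` and `nt`.
#' @param w relative adaptiveness for CAI; defaults to usage of the
#'   background set (the proxy for the strain's established genes).
#' @return tibble `metric`, `mean_novel`, `mean_background`, `p_value`
#'   (p omitted, NA, when either set has fewer than 2 genes).
#' @export
signature_report <- function(novel, background, w = NULL) {
  novel <- tibble::as_tibble(novel); background <- tibble::as_tibble(background)
  stopifnot(nrow(novel) > 0, nrow(background) > 0)
  if (is.null(w)) w <- relative_adaptiveness(codon_usage(background$nt))
  vals <- function(df) {
    tibble::tibble(
      cai = vapply(df$nt, cai, numeric(1), w = w),
      gc = vapply(df$nt, gc_content, numeric(1)),
      length_aa = nchar(df$nt) / 3 -
        vapply(df$nt, function(x) {
          cods <- split_codons(toupper(x))
          as.numeric(cods[length(cods)] %in% STOP_CODONS)
        }, numeric(1))
    )
  }
  a <- vals(novel); b <- vals(background)
  small <- nrow(a) < 2L || nrow(b) < 2L
  purrr::map_dfr(c(cai = "cai", gc = "gc", length_aa = "length_aa"),
                 function(col) {
    p <- if (small) NA_real_ else
      suppressWarnings(wilcox.test(a[[col]], b[[col]], exact = FALSE)$p.value)
    if (isTRUE(is.nan(p))) p <- 1   # fully tied data: no separation
    tibble::tibble(metric = col, mean_novel = mean(a[[col]]),
                   mean_background = mean(b[[col]]), p_value = p)
  })
}

#' Summarize a table of strain-unique gene records
#'
#' Exact arithmetic over the unique-gene table: totals per strain, mean
#' protein length, DNA-binding count, distribution of most-ancestral
#' detection nodes, and the count of genes without any detected trace.
#'
#' @param records tibble from [read_table1_fixture()] (or equivalent).
#' @return list `n_total`, `n_per_strain` (named vector),
#'   `mean_length_aa` (1 decimal), `n_dna_binding`, `node_distribution`
#'   (tibble), `n_no_trace`.
#' @export
summarize_unique_gene_table <- function(records) {
  r <- tibble::as_tibble(records)
  if (nrow(r) == 0L) {
    return(list(n_total = 0L, n_per_strain = integer(0),
                mean_length_aa = NaN, n_dna_binding = 0L,
                node_distribution = tibble::tibble(node = character(0),
                                                   n = integer(0)),
                n_no_trace = 0L))
  }
  nd <- summarize_node_distribution(
    tibble::tibble(node = as.character(r$most_ancestral_detection)))
  list(
    n_total = nrow(r),
    n_per_strain = vapply(split(r$gene_id, r$strain), length, integer(1)),
    mean_length_aa = round(mean(r$length_aa), 1),
    n_dna_binding = sum(r$predicted_dna_binding),
    node_distribution = nd,
    n_no_trace = sum(is.na(r$most_ancestral_detection))
  )
}
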