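# Protein clustering across strains and pan/core-genome accumulation
# curves over all genome combinations, with the per-genome pan increment.
# Clustering is thresholded single-linkage over global-alignment identity:
# transparent, deterministic and checkable against brute-force set
# arithmetic.

#' Global identity and coverage between two proteins
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11 / extend 1).
#' Identity is identical columns over aligned (gap-free) columns; coverage
#' is aligned gap-free columns over the shorter sequence length.
#'
#' @param a,b peptide sequences (non-empty strings).
#' @return tibble with `identity` and `coverage` fractions.
#' @export
#' @examples
#' pairwise_protein_identity("MKV", "MRV")
pairwise_protein_identity <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  m <- align_identity_batch(a, b)
  tibble::tibble(identity = unname(m[1, "identity"]),
                 coverage = unname(m[1, "coverage"]))
}

# batched global alignment of many queries against one subject; identity
# (identical / aligned gap-free columns) and coverage (aligned columns /
# shorter length) from the alignment match counts
align_identity_batch <- function(queries, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    substitutionMatrix = blosum62_matrix(), gapOpening = 11,
    gapExtension = 1, type = "global")
  aligned <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  identity <- ifelse(aligned > 0, Biostrings::nmatch(aln) / aligned, 0)
  coverage <- aligned / pmin(nchar(queries), nchar(subject))
  cbind(identity = identity, coverage = coverage)
}

# all-vs-all identity/coverage for a protein table (strain, gene_id, protein)
all_vs_all_identity <- function(proteins) {
  n <- nrow(proteins)
  if (n < 2L) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          identity = numeric(0), coverage = numeric(0)))
  }
  res <- purrr::map_dfr(seq_len(n - 1L), function(i) {
    js <- (i + 1L):n
    m <- align_identity_batch(proteins$protein[js], proteins$protein[i])
    tibble::tibble(i = i, j = js,
                   identity = m[, "identity"], coverage = m[, "coverage"])
  })
  res
}

#' Cluster proteins across strains by single-linkage homology
#'
#' Builds the graph whose edges join protein pairs meeting both the
#' identity and the coverage threshold, and takes connected components
#' (single linkage, so homology is transitive across intermediates).
#' For the edge decision the identity is measured over the shorter
#' sequence (identical columns / shorter length, i.e. identity x
#' coverage): unrelated compositionally biased proteins can exceed 30%
#' per-column identity in gap-fragmented global alignments, and a
#' full-length normalization keeps such chance edges from percolating
#' through single linkage. Cluster ids are deterministic: named after the
#' lexicographically smallest `strain:gene_id` member.
#'
#' @param proteins tibble with columns `strain`, `gene_id`, `protein`.
#' @param min_identity,min_coverage edge thresholds (defaults 0.30 / 0.50).
#' @return a `protein_cluster_set`: list with `members` (tibble `cluster`,
#'   `strain`, `gene_id`) and `presence` (logical matrix clusters x
#'   strains).
#' @export
cluster_proteins <- function(proteins, min_identity = 0.30,
                             min_coverage = 0.50) {
  proteins <- tibble::as_tibble(proteins)
  stopifnot(nrow(proteins) > 0L,
            all(c("strain", "gene_id", "protein") %in% names(proteins)))
  n <- nrow(proteins)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1L) {
    ev <- all_vs_all_identity(proteins)
    keep <- ev$identity * ev$coverage >= min_identity &
      ev$coverage >= min_coverage
    for (k in which(keep)) {
      ri <- find(ev$i[k]); rj <- find(ev$j[k])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  key <- paste0(proteins$strain, ":", proteins$gene_id)
  cluster_id <- stats::ave(key, comp, FUN = min)
  members <- tibble::tibble(cluster = cluster_id,
                            strain = proteins$strain,
                            gene_id = proteins$gene_id) |>
    dplyr::arrange(.data$cluster, .data$strain, .data$gene_id)
  strains <- sort(unique(proteins$strain))
  clusters <- sort(unique(cluster_id))
  presence <- matrix(FALSE, length(clusters), length(strains),
                     dimnames = list(clusters, strains))
  presence[cbind(match(members$cluster, clusters),
                 match(members$strain, strains))] <- TRUE
  structure(list(members = members, presence = presence),
            class = "protein_cluster_set")
}

#' @export
print.protein_cluster_set <- function(x, ...) {
  cat("<protein_cluster_set> ", nrow(x$presence), " clusters, ",
      ncol(x$presence), " strains, ", nrow(x$members), " proteins\n", sep = "")
  invisible(x)
}

#' Pan/core-genome accumulation curves over all genome combinations
#'
#' For every subset size g and every combination of g strains, the pan size
#' is the number of clusters present in at least one member and the core
#' size the number present in all members -- the accumulation boxplot of
#' comparative genomics. Exhaustive up to 12 strains; beyond that a seeded
#' random sample of combinations must be requested explicitly.
#'
#' @param pcs a `protein_cluster_set` (or a logical presence matrix
#'   clusters x strains).
#' @param sample_combinations number of random combinations per g when the
#'   strain count exceeds `max_exhaustive` (requires `seed`).
#' @param max_exhaustive largest strain count for exhaustive enumeration.
#' @param seed seed for sampling mode.
#' @return tibble of class `accumulation_curve`: `g`, `combination`,
#'   `pan`, `core`.
#' @export
accumulation_curves <- function(pcs, sample_combinations = NULL,
                                max_exhaustive = 12L, seed = NULL) {
  pres <- if (inherits(pcs, "protein_cluster_set")) pcs$presence else pcs
  G <- ncol(pres)
  stopifnot(G >= 1L)
  exhaustive <- G <= max_exhaustive
  if (!exhaustive && is.null(sample_combinations)) {
    stop("more than ", max_exhaustive,
         " strains: use sampling (set sample_combinations, e.g. 1000, and seed)")
  }
  if (!exhaustive) set.seed(seed %||% stop("sampling mode needs a seed"))
  rows <- list()
  for (g in seq_len(G)) {
    combos <- if (exhaustive) {
      utils::combn(G, g, simplify = FALSE)
    } else {
      n_all <- choose(G, g)
      n_take <- min(sample_combinations, n_all)
      unique(replicate(n_take, sort(sample.int(G, g)), simplify = FALSE))
    }
    pan <- vapply(combos, function(idx) {
      sum(rowSums(pres[, idx, drop = FALSE]) > 0L)
    }, numeric(1))
    core <- vapply(combos, function(idx) {
      sum(rowSums(pres[, idx, drop = FALSE]) == length(idx))
    }, numeric(1))
    rows[[g]] <- tibble::tibble(g = g, combination = seq_along(combos),
                                pan = pan, core = core)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("accumulation_curve", class(out))
  out
}

#' Summarize an accumulation curve per subset size
#'
#' @param curve output of [accumulation_curves()].
#' @return tibble per g: median/quartiles/extremes of pan and core sizes.
#' @export
summarize_accumulation <- function(curve) {
  tibble::as_tibble(curve) |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(
      dplyr::across(c("pan", "core"),
                    list(median = median,
                         q1 = ~quantile(.x, 0.25, names = FALSE),
                         q3 = ~quantile(.x, 0.75, names = FALSE),
                         min = min, max = max)),
      n_combinations = dplyr::n(), .groups = "drop")
}

#' Mean pan-genome increment contributed by the last added genome
#'
#' Mean pan size over the full strain set minus the mean pan size over all
#' (G-1)-subsets: the expected number of new clusters a further isolate
#' contributes.
#'
#' @param curve output of [accumulation_curves()] (needs g = G and G-1).
#' @return a single number.
#' @export
pan_increment <- function(curve) {
  G <- max(curve$g)
  if (G < 2L) stop("need at least 2 strains")
  mean(curve$pan[curve$g == G]) - mean(curve$pan[curve$g == G - 1L])
}

#' Reciprocal-best-hit ortholog pairs between two strains
#'
#' Pairs (a, b) where b is a's highest-identity partner and vice versa;
#' identity ties are broken by lexicographic gene id. Unpaired proteins
#' are reported with an `NA` partner.
#'
#' @param proteins_a,proteins_b tibbles `gene_id`, `protein` for each
#'   strain.
#' @return tibble `gene_a`, `gene_b`, `identity` (`gene_b` NA when
#'   unpaired).
#' @export
reciprocal_best_pairs <- function(proteins_a, proteins_b) {
  a <- tibble::as_tibble(proteins_a); b <- tibble::as_tibble(proteins_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble::tibble(gene_a = a$gene_id, gene_b = NA_character_,
                          identity = NA_real_))
  }
  idm <- matrix(0, nrow(a), nrow(b), dimnames = list(a$gene_id, b$gene_id))
  for (j in seq_len(nrow(b))) {
    idm[, j] <- align_identity_batch(a$protein, b$protein[j])[, "identity"]
  }
  best_of <- function(v, names) names[order(-v, names)][1]
  best_a <- vapply(seq_len(nrow(a)),
                   function(i) best_of(idm[i, ], colnames(idm)), character(1))
  best_b <- vapply(seq_len(nrow(b)),
                   function(j) best_of(idm[, j], rownames(idm)), character(1))
  names(best_b) <- colnames(idm)
  paired <- best_b[best_a] == rownames(idm)
  tibble::tibble(
    gene_a = rownames(idm),
    gene_b = dplyr::if_else(paired, best_a, NA_character_),
    identity = dplyr::if_else(paired, idm[cbind(seq_len(nrow(a)),
                                                match(best_a, colnames(idm)))],
                              NA_real_)
  ) |> dplyr::arrange(.data$gene_a)
}

#' Extract CDS protein sequences from a strain annotation
#'
#' Translates every non-pseudogenized CDS (minus-strand CDS are reverse
#' complemented first; the terminal stop is dropped).
#'
#' @param ann a [strain_annotation()] object.
#' @return tibble `strain`, `gene_id`, `protein`.
#' @export
annotation_proteins <- function(ann) {
  f <- ann$features[ann$features$kind == "CDS" & !ann$features$pseudogene, ]
  if (nrow(f) == 0L) {
    return(tibble::tibble(strain = character(0), gene_id = character(0),
                          protein = character(0)))
  }
  nt <- substring(ann$sequence, f$start + 1L, f$end)
  nt[f$strand == "-"] <- revcomp(nt[f$strand == "-"])
  prot <- sub("\\*$", "", translate_dna(nt))
  tibble::tibble(strain = ann$strain_id, gene_id = f$feature_id,
                 protein = prot)
}
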