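# Dating the creation of strain-unique genes: a tblastn-like translated
# search of a protein query against the six-frame translation of another
# strain's genome, masked to the non-coding moiety, with ungapped
# Karlin-Altschul statistics; then assignment of the most ancestral node
# with evidence on the labeled tree.
#
# The search is seeded with exact 4-mer peptide matches and extended
# ungapped with BLOSUM62 under an X-drop; ungapped extensions keep the
# Karlin-Altschul parameters analytic. E < 1e-3 is a screening threshold.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Karlin-Altschul E-value for an ungapped local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the classic ungapped BLOSUM62
#' parameters as defaults.
#'
#' @param score raw alignment score (>= 0).
#' @param query_len query length (aa).
#' @param subject_len subject search-space length (nt).
#' @param lambda,K Karlin-Altschul parameters.
#' @return expected number of chance hits at or above `score`.
#' @export
#' @examples
#' karlin_altschul_evalue(50, 100, 1e6)
karlin_altschul_evalue <- function(score, query_len, subject_len,
                                   lambda = 0.318, K = 0.13) {
  stopifnot(all(score >= 0))
  K * query_len * subject_len * exp(-lambda * score)
}

# genome 0-based half-open interval of aa span [p1, p2] (1-based, inclusive)
# in frame k (+1..+3 forward, -1..-3 on the reverse complement)
frame_span_to_genome <- function(frame, p1, p2, genome_len) {
  k <- abs(frame)
  if (frame > 0) {
    c(start = (k - 1L) + 3L * (p1 - 1L), end = (k - 1L) + 3L * p2)
  } else {
    c(start = genome_len - ((k - 1L) + 3L * p2),
      end = genome_len - ((k - 1L) + 3L * (p1 - 1L)))
  }
}

#' Translated search of a protein against a genome's non-coding moiety
#'
#' Finds remote protein-level similarity between a query peptide and the
#' six-frame translation of a subject genome: exact 4-mer seeds, ungapped
#' BLOSUM62 extension with an X-drop, Karlin-Altschul E-values, and a mask
#' that discards hits lying mostly in a same-strand, same-frame CDS (hits
#' in intergenic DNA, UTRs, antisense or alternative-frame overlaps are
#' kept -- those are exactly the contexts in which traces of newborn genes
#' are expected).
#'
#' @param query peptide sequence (>= 20 aa).
#' @param subject a [strain_annotation()] object.
#' @param E_max E-value cutoff (default 1e-3).
#' @param seed_len exact peptide seed length.
#' @param x_drop extension drop-off threshold (raw score).
#' @param lambda,K Karlin-Altschul parameters.
#' @param index optional prebuilt [subject_frame_index()]; reuse it when
#'   searching many queries against the same genome.
#' @return tibble of hits sorted by E-value: `subject_strain`, `start`,
#'   `end` (genome, 0-based half-open), `frame`, `query_start`,
#'   `query_end`, `score`, `evalue`.
#' @export
translated_noncoding_search <- function(query, subject, E_max = 1e-3,
                                        seed_len = 4L, x_drop = 20,
                                        lambda = 0.318, K = 0.13,
                                        index = NULL) {
  if (nchar(query) < 20L) stop("query shorter than 20 aa")
  if (subject$length < 3L) stop("subject shorter than one codon")
  if (is.null(index)) index <- subject_frame_index(subject, seed_len)
  stopifnot(index$seed_len == seed_len)
  b62 <- blosum62_matrix()
  qc <- strsplit(query, "")[[1]]
  m <- length(qc)
  qmers <- substring(query, seq_len(m - seed_len + 1L),
                     seq_len(m - seed_len + 1L) + seed_len - 1L)
  qpos_of <- split(seq_along(qmers), qmers)
  hits <- list()
  for (r in seq_along(index$frames)) {
    fr <- index$frames[r]
    fc <- index$chars[[r]]
    fmers <- index$mers[[r]]
    if (length(fmers) == 0L) next
    hit_pos <- which(fmers %in% qmers)
    if (length(hit_pos) == 0L) next
    seeds <- purrr::map_dfr(hit_pos, function(fp) {
      tibble::tibble(qi = qpos_of[[fmers[fp]]], fi = fp)
    })
    seeds$diag <- seeds$fi - seeds$qi
    seeds <- seeds[order(seeds$diag, seeds$fi), ]
    covered_end <- -Inf; covered_diag <- NA
    for (s in seq_len(nrow(seeds))) {
      qi <- seeds$qi[s]; fi <- seeds$fi[s]; dg <- seeds$diag[s]
      if (!is.na(covered_diag) && dg == covered_diag && fi <= covered_end) next
      ext <- ungapped_extend(qc, fc, qi, fi, seed_len, b62, x_drop)
      covered_end <- ext$f2; covered_diag <- dg
      hits[[length(hits) + 1L]] <- tibble::tibble(
        frame = fr, q1 = ext$q1, q2 = ext$q2, f1 = ext$f1, f2 = ext$f2,
        score = ext$score)
    }
  }
  empty <- tibble::tibble(subject_strain = character(0), start = integer(0),
                          end = integer(0), frame = integer(0),
                          query_start = integer(0), query_end = integer(0),
                          score = numeric(0), evalue = numeric(0))
  if (length(hits) == 0L) return(empty)
  h <- dplyr::bind_rows(hits) |> dplyr::distinct()
  # best hit per (frame, subject span) family: drop hits nested in a
  # higher-scoring overlapping hit on the same frame
  h <- h |> dplyr::arrange(dplyr::desc(.data$score))
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    if (i < nrow(h)) {
      later <- (i + 1L):nrow(h)
      ov <- h$frame[later] == h$frame[i] &
        h$f1[later] <= h$f2[i] & h$f2[later] >= h$f1[i]
      keep[later][ov] <- FALSE
    }
  }
  h <- h[keep, ]
  span <- t(mapply(frame_span_to_genome, h$frame, h$f1, h$f2,
                   MoreArgs = list(genome_len = subject$length)))
  h$start <- as.integer(span[, "start"]); h$end <- as.integer(span[, "end"])
  h$evalue <- karlin_altschul_evalue(h$score, m, subject$length, lambda, K)
  h <- h[h$evalue <= E_max, ]
  if (nrow(h) == 0L) return(empty)
  h <- h[!masked_by_same_frame_cds(h, subject), ]
  if (nrow(h) == 0L) return(empty)
  tibble::tibble(subject_strain = subject$strain_id,
                 start = h$start, end = h$end, frame = h$frame,
                 query_start = h$q1, query_end = h$q2,
                 score = h$score, evalue = h$evalue) |>
    dplyr::arrange(.data$evalue)
}

#' Precompute the six-frame index of a subject genome
#'
#' Translates the genome in all six frames and extracts the peptide
#' character vectors and exact seed words once, so that many queries can
#' be searched against the same subject without repeating the work.
#'
#' @param subject a [strain_annotation()] object.
#' @param seed_len seed word length (must match the search call).
#' @return an opaque list consumed by [translated_noncoding_search()].
#' @export
subject_frame_index <- function(subject, seed_len = 4L) {
  frames <- six_frame_translate(subject$sequence)
  chars <- lapply(frames$peptide, function(p) strsplit(p, "")[[1]])
  mers <- lapply(frames$peptide, function(p) {
    np <- nchar(p) - seed_len + 1L
    if (np < 1L) return(character(0))
    substring(p, seq_len(np), seq_len(np) + seed_len - 1L)
  })
  list(frames = frames$frame, chars = chars, mers = mers,
       seed_len = seed_len)
}

# ungapped X-drop extension around a seed; returns 1-based inclusive spans
ungapped_extend <- function(qc, fc, qi, fi, seed_len, b62, x_drop) {
  seed_score <- sum(b62[cbind(qc[qi:(qi + seed_len - 1L)],
                              fc[fi:(fi + seed_len - 1L)])])
  m <- length(qc); Fn <- length(fc)
  right <- extend_dir(qc, fc, qi + seed_len, fi + seed_len, 1L, m, Fn, b62, x_drop)
  left <- extend_dir(qc, fc, qi - 1L, fi - 1L, -1L, m, Fn, b62, x_drop)
  list(q1 = qi - left$steps, q2 = qi + seed_len - 1L + right$steps,
       f1 = fi - left$steps, f2 = fi + seed_len - 1L + right$steps,
       score = seed_score + right$gain + left$gain)
}

extend_dir <- function(qc, fc, q0, f0, dir, m, Fn, b62, x_drop) {
  len <- if (dir > 0) min(m - q0, Fn - f0) + 1L else min(q0, f0)
  if (len <= 0L) return(list(steps = 0L, gain = 0))
  qidx <- q0 + dir * (seq_len(len) - 1L)
  fidx <- f0 + dir * (seq_len(len) - 1L)
  sc <- cumsum(b62[cbind(qc[qidx], fc[fidx])])
  run_max <- cummax(sc)
  stop_at <- which(run_max - sc > x_drop)[1]
  upto <- if (is.na(stop_at)) len else stop_at - 1L
  if (upto == 0L) return(list(steps = 0L, gain = 0))
  best <- which.max(sc[seq_len(upto)])
  if (sc[best] <= 0) return(list(steps = 0L, gain = 0))
  list(steps = best, gain = sc[best])
}

# TRUE for hits lying mostly (> 50%) inside a CDS on the same strand and in
# the same reading frame -- those would just re-find the gene itself
masked_by_same_frame_cds <- function(h, subject) {
  cds <- subject$features[subject$features$kind == "CDS", ]
  L <- subject$length
  vapply(seq_len(nrow(h)), function(i) {
    s <- h$start[i]; e <- h$end[i]
    strand <- if (h$frame[i] > 0) "+" else "-"
    cc <- cds[cds$strand == strand, ]
    if (nrow(cc) == 0L) return(FALSE)
    inframe <- if (strand == "+") {
      cc$start %% 3L == s %% 3L
    } else {
      (L - cc$end) %% 3L == (L - e) %% 3L
    }
    cc <- cc[inframe, ]
    if (nrow(cc) == 0L) return(FALSE)
    overlap_len(s, e, cc$start, cc$end) > 0.5 * (e - s)
  }, logical(1))
}

#' Classify the genomic context of a trace hit
#'
#' Priority: alternative frame (same-strand CDS overlap in a different
#' frame) > antisense CDS > 5'/3' UTR > ncRNA overlap > intergenic. A
#' category applies when it covers at least half of the hit.
#'
#' @param hit one hit row (list or one-row tibble with `start`, `end`,
#'   `frame`).
#' @param subject the subject [strain_annotation()].
#' @return one of `"alternative_frame"`, `"antisense_cds"`, `"utr5"`,
#'   `"utr3"`, `"ncRNA_overlap"`, `"intergenic"`.
#' @export
classify_hit_context <- function(hit, subject) {
  s <- hit$start; e <- hit$end
  strand <- if (hit$frame > 0) "+" else "-"
  f <- subject$features
  L <- subject$length
  frac <- function(sub) {
    if (nrow(sub) == 0L) return(0)
    overlap_len(s, e, sub$start, sub$end) / (e - s)
  }
  cds_same <- f[f$kind == "CDS" & f$strand == strand, ]
  if (nrow(cds_same) > 0L) {
    inframe <- if (strand == "+") cds_same$start %% 3L == s %% 3L
               else (L - cds_same$end) %% 3L == (L - e) %% 3L
    if (frac(cds_same[!inframe, ]) >= 0.5) return("alternative_frame")
  }
  if (frac(f[f$kind == "CDS" & f$strand != strand, ]) >= 0.5) {
    return("antisense_cds")
  }
  if (frac(f[f$kind == "UTR5", ]) >= 0.5) return("utr5")
  if (frac(f[f$kind == "UTR3", ]) >= 0.5) return("utr3")
  if (frac(f[f$kind == "ncRNA", ]) >= 0.5) return("ncRNA_overlap")
  "intergenic"
}

#' Assign the creation node of a gene from its evidence leaves
#'
#' The creation node is the most recent common ancestor of the focal
#' strain and every strain showing evidence (an annotated homolog or a
#' non-coding trace). No evidence yields no assignment. The strict variant
#' instead returns the most rootward ancestor of the focal leaf all of
#' whose other descendant leaves carry evidence.
#'
#' @param tree a `labeled_tree`.
#' @param focal focal leaf name.
#' @param evidence_leaves character vector of leaves with evidence (may be
#'   empty; must not contain unknown leaves).
#' @param strict require evidence in every descendant leaf of the assigned
#'   node rather than taking the plain MRCA.
#' @return one-row tibble `node` (label or NA) and `supporting_strains`
#'   (list column).
#' @export
assign_creation_node <- function(tree, focal, evidence_leaves,
                                 strict = FALSE) {
  leaves <- tree_leaves(tree)
  stopifnot(focal %in% leaves)
  bad <- setdiff(evidence_leaves, leaves)
  if (length(bad) > 0L) stop("evidence leaves not in tree: ",
                             paste(bad, collapse = ", "))
  evidence_leaves <- setdiff(unique(evidence_leaves), focal)
  if (length(evidence_leaves) == 0L) {
    return(tibble::tibble(node = NA_character_,
                          supporting_strains = list(character(0))))
  }
  node <- if (!strict) {
    mrca_label(tree, c(focal, evidence_leaves))
  } else {
    strict_creation_node(tree, focal, evidence_leaves)
  }
  tibble::tibble(node = node, supporting_strains = list(evidence_leaves))
}

strict_creation_node <- function(tree, focal, evidence_leaves) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  tipnum <- match(focal, phy$tip.label)
  root <- ntip + 1L
  parent_of <- function(n) phy$edge[phy$edge[, 2] == n, 1]
  best <- NA_character_
  n <- tipnum
  while (n != root) {
    n <- parent_of(n)
    below <- setdiff(phy$tip.label[descendant_tips(phy, n)], focal)
    if (all(below %in% evidence_leaves)) {
      best <- node_label_of(tree, n)
    } else {
      break
    }
    if (n == root) break
  }
  best
}

#' Distribution of creation-node assignments
#'
#' @param assignments tibble with a `node` column (labels, NA = no trace).
#' @return tibble `node` (label or `"None"`), `n`, sorted by label.
#' @export
summarize_node_distribution <- function(assignments) {
  a <- tibble::as_tibble(assignments)
  if (nrow(a) == 0L) return(tibble::tibble(node = character(0), n = integer(0)))
  a |>
    dplyr::mutate(node = dplyr::if_else(is.na(.data$node), "None",
                                        as.character(.data$node))) |>
    dplyr::count(.data$node) |>
    dplyr::arrange(.data$node)
}
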