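# Expression validation, ncRNA calling from stranded coverage, the
# antisense/intergenic classification rule, and cross-strain ncRNA
# homology matching. One expression floor (median coverage strictly
# greater than 5) is applied to genes and ncRNAs alike.

#' Validate gene expression against the coverage threshold
#'
#' A feature is kept iff its median read coverage is strictly greater than
#' the threshold (a median of exactly 5 is rejected). Features without
#' coverage are routed to `unevaluated`.
#'
#' @param features tibble with `feature_id` and `median_coverage`.
#' @param threshold expression floor (default 5).
#' @return list of tibbles `kept`, `rejected`, `unevaluated`.
#' @export
validate_gene_expression <- function(features, threshold = 5) {
  f <- tibble::as_tibble(features)
  miss <- is.na(f$median_coverage)
  list(kept = f[!miss & f$median_coverage > threshold, ],
       rejected = f[!miss & f$median_coverage <= threshold, ],
       unevaluated = f[miss, ])
}

#' Call ncRNA regions from a stranded coverage track
#'
#' Maximal runs of per-base coverage above the threshold on each strand
#' that do not contain a same-strand CDS are annotated as non-coding RNA;
#' runs shorter than `min_len` are dropped. (Runs overlapping CDS only on
#' the opposite strand are kept -- those become the antisense class.)
#'
#' @param track tibble `pos` (0-based), `strand`, `depth`; positions not
#'   listed count as zero.
#' @param ann the strain's [strain_annotation()] (for the CDS exclusion).
#' @param threshold per-base depth floor (strict, as for genes).
#' @param min_len minimum call length (nt).
#' @return tibble `call_id`, `start`, `end`, `strand`, `median_coverage`.
#' @export
call_ncrna_regions <- function(track, ann, threshold = 5, min_len = 200L) {
  track <- tibble::as_tibble(track)
  cds <- ann$features[ann$features$kind == "CDS", ]
  out <- list()
  for (st in c("+", "-")) {
    tr <- track[track$strand == st & track$depth > threshold, ]
    if (nrow(tr) == 0L) next
    pos <- sort(unique(tr$pos))
    brk <- c(TRUE, diff(pos) != 1L)
    grp <- cumsum(brk)
    runs <- tibble::tibble(pos = pos, grp = grp) |>
      dplyr::group_by(.data$grp) |>
      dplyr::summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
                       .groups = "drop")
    runs <- runs[runs$end - runs$start >= min_len, ]
    if (nrow(runs) == 0L) next
    same_cds <- cds[cds$strand == st, ]
    contains_cds <- vapply(seq_len(nrow(runs)), function(i) {
      any(same_cds$start >= runs$start[i] & same_cds$end <= runs$end[i]) ||
        overlap_len(runs$start[i], runs$end[i],
                    same_cds$start, same_cds$end) > 0L
    }, logical(1))
    runs <- runs[!contains_cds, ]
    if (nrow(runs) == 0L) next
    med <- vapply(seq_len(nrow(runs)), function(i) {
      d <- tr$depth[tr$pos >= runs$start[i] & tr$pos < runs$end[i]]
      median(d)
    }, numeric(1))
    out[[st]] <- tibble::tibble(start = runs$start, end = runs$end,
                                strand = st, median_coverage = med)
  }
  calls <- dplyr::bind_rows(out)
  if (nrow(calls) == 0L) {
    return(tibble::tibble(call_id = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          median_coverage = numeric(0)))
  }
  calls <- dplyr::arrange(calls, .data$start, .data$strand)
  calls$call_id <- sprintf("%s_ncRNA_%d", ann$strain_id, seq_len(nrow(calls)))
  dplyr::relocate(calls, "call_id")
}

#' Classify an ncRNA call as antisense or intergenic
#'
#' Antisense iff the call overlaps opposite-strand CDS by strictly more
#' than half of its own length; otherwise intergenic (an exactly-half
#' overlap is intergenic).
#'
#' @param calls tibble from [call_ncrna_regions()] (needs `start`, `end`,
#'   `strand`).
#' @param ann the strain's [strain_annotation()].
#' @return `calls` with a `class` column (`antisense` / `intergenic`).
#' @export
classify_ncrna <- function(calls, ann) {
  calls <- tibble::as_tibble(calls)
  cds <- ann$features[ann$features$kind == "CDS", ]
  cls <- vapply(seq_len(nrow(calls)), function(i) {
    opp <- cds[cds$strand != calls$strand[i], ]
    ov <- overlap_len(calls$start[i], calls$end[i], opp$start, opp$end)
    if (ov > 0.5 * (calls$end[i] - calls$start[i])) "antisense" else "intergenic"
  }, character(1))
  calls$class <- cls
  calls
}

#' Match ncRNAs across two strains
#'
#' Reciprocal-best local nucleotide alignment between ncRNA sequences;
#' pairs above the identity and coverage thresholds are reported along
#' with the unmatched calls of each strain. A position-based mode pairs
#' calls whose genomic intervals reciprocally overlap best instead.
#'
#' @param calls_a,calls_b call tibbles (`call_id`, `start`, `end`,
#'   `strand`).
#' @param seq_a,seq_b the two genome sequences.
#' @param min_identity,min_coverage alignment thresholds (defaults 0.8 /
#'   0.5; the homology criterion is an explicit assumption of the
#'   pipeline, not a published value).
#' @param mode `"sequence"` (default) or `"position"`.
#' @return list `pairs` (tibble `call_a`, `call_b`, `identity`),
#'   `unmatched_a`, `unmatched_b` (character vectors).
#' @export
match_ncrna_across_strains <- function(calls_a, calls_b, seq_a, seq_b,
                                       min_identity = 0.8,
                                       min_coverage = 0.5,
                                       mode = c("sequence", "position")) {
  mode <- match.arg(mode)
  calls_a <- tibble::as_tibble(calls_a); calls_b <- tibble::as_tibble(calls_b)
  empty <- list(pairs = tibble::tibble(call_a = character(0),
                                       call_b = character(0),
                                       identity = numeric(0)),
                unmatched_a = calls_a$call_id, unmatched_b = calls_b$call_id)
  if (nrow(calls_a) == 0L || nrow(calls_b) == 0L) return(empty)
  if (mode == "position") {
    score <- outer(seq_len(nrow(calls_a)), seq_len(nrow(calls_b)),
                   Vectorize(function(i, j) {
                     overlap_len(calls_a$start[i], calls_a$end[i],
                                 calls_b$start[j], calls_b$end[j])
                   }))
  } else {
    sa <- substring(seq_a, calls_a$start + 1L, calls_a$end)
    sb <- substring(seq_b, calls_b$start + 1L, calls_b$end)
    score <- matrix(0, nrow(calls_a), nrow(calls_b))
    ident <- matrix(0, nrow(calls_a), nrow(calls_b))
    for (i in seq_len(nrow(calls_a))) {
      for (j in seq_len(nrow(calls_b))) {
        r <- nucleotide_local_identity(sa[i], sb[j])
        ident[i, j] <- r$identity
        score[i, j] <- ifelse(r$identity >= min_identity &
                                r$coverage >= min_coverage, r$identity, 0)
      }
    }
  }
  best_a <- apply(score, 1, which.max)
  best_b <- apply(score, 2, which.max)
  pairs <- list()
  for (i in seq_len(nrow(calls_a))) {
    j <- best_a[i]
    if (score[i, j] > 0 && best_b[j] == i) {
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        call_a = calls_a$call_id[i], call_b = calls_b$call_id[j],
        identity = if (mode == "sequence") ident[i, j] else NA_real_)
    }
  }
  pairs <- if (length(pairs) > 0L) dplyr::bind_rows(pairs) else empty$pairs
  list(pairs = pairs,
       unmatched_a = setdiff(calls_a$call_id, pairs$call_a),
       unmatched_b = setdiff(calls_b$call_id, pairs$call_b))
}

# local nucleotide alignment identity/coverage (coverage over the shorter)
nucleotide_local_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1)
  aligned <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  list(identity = if (aligned > 0) Biostrings::nmatch(aln) / aligned else 0,
       coverage = aligned / min(nchar(a), nchar(b)))
}
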