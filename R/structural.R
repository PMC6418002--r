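# Large-scale structural features: exact-word dotplot segments (direct and
# inverted), the terminal palindrome, and terminal-inverted-repeat (TIR)
# transposon candidates in the size range of hAT elements.

# word-position index: all words of length w and their 1-based start
word_starts <- function(seq, w) {
  n <- nchar(seq) - w + 1L
  if (n < 1L) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + w - 1L)
}

#' Exact-word dotplot between two sequences
#'
#' Finds all shared exact words of length `word` in both orientations and
#' merges runs on the same diagonal into maximal collinear segments --
#' the machine-readable form of a nucleotide dotplot.
#'
#' @param seq_a,seq_b nucleotide sequences.
#' @param word word length (>= 8).
#' @return tibble of class `dotplot_matches`: `start_a`, `end_a`,
#'   `start_b`, `end_b` (0-based half-open; for inverted segments the B
#'   interval is given on the forward strand of B), `orientation`
#'   (`direct`/`inverted`), `length`.
#' @export
dotplot_matches <- function(seq_a, seq_b, word = 15L) {
  stopifnot(word >= 8L)
  wa <- word_starts(seq_a, word)
  match_one <- function(wb, orientation, len_b) {
    map_b <- split(seq_along(wb), wb)
    slot <- match(wa, names(map_b))
    pa <- which(!is.na(slot))
    rows <- purrr::map_dfr(pa, function(i) {
      tibble::tibble(a = i, b = map_b[[slot[i]]])
    })
    if (nrow(rows) == 0L) return(NULL)
    # merge consecutive word matches on the same diagonal
    rows$diag <- rows$b - rows$a
    rows <- rows[order(rows$diag, rows$a), ]
    brk <- c(TRUE, diff(rows$diag) != 0 | diff(rows$a) != 1L)
    grp <- cumsum(brk)
    segs <- rows |>
      dplyr::mutate(grp = grp) |>
      dplyr::group_by(.data$grp) |>
      dplyr::summarise(a1 = min(.data$a), a2 = max(.data$a) + word - 1L,
                       b1 = min(.data$b), b2 = max(.data$b) + word - 1L,
                       .groups = "drop")
    if (orientation == "direct") {
      tibble::tibble(start_a = segs$a1 - 1L, end_a = segs$a2,
                     start_b = segs$b1 - 1L, end_b = segs$b2,
                     orientation = "direct", length = segs$a2 - segs$a1 + 1L)
    } else {
      # positions were found on revcomp(B); map back to forward coordinates
      tibble::tibble(start_a = segs$a1 - 1L, end_a = segs$a2,
                     start_b = len_b - segs$b2, end_b = len_b - segs$b1 + 1L,
                     orientation = "inverted", length = segs$a2 - segs$a1 + 1L)
    }
  }
  out <- dplyr::bind_rows(
    match_one(word_starts(seq_b, word), "direct", nchar(seq_b)),
    match_one(word_starts(revcomp(seq_b), word), "inverted", nchar(seq_b))
  )
  if (nrow(out) == 0L) {
    out <- tibble::tibble(start_a = integer(0), end_a = integer(0),
                          start_b = integer(0), end_b = integer(0),
                          orientation = character(0), length = integer(0))
  }
  out <- dplyr::arrange(out, .data$start_a, .data$start_b)
  class(out) <- c("dotplot_matches", class(out))
  out
}

#' Find a terminal palindrome at the start of a genome
#'
#' Looks for the longest prefix `[0, 2k)` whose first half equals the
#' reverse complement of its second half within a mismatch budget -- the
#' hallmark of the near-perfect palindrome opening the pandoravirus
#' genomes. Mismatch counts for every candidate half-length are obtained
#' in one pass from an FFT cross-correlation of the nucleotide indicator
#' vectors, so the longest qualifying prefix palindrome is exact.
#'
#' @param seq nucleotide sequence.
#' @param search_window how far from the start to search (nt).
#' @param min_len minimum palindrome length (total, nt).
#' @param max_mismatch_frac tolerated mismatch fraction over the half.
#' @return one-row tibble `start`, `end`, `length`, `mismatches`, or a
#'   zero-row tibble when nothing qualifies.
#' @export
find_terminal_palindrome <- function(seq, search_window = 50000L,
                                     min_len = 1000L,
                                     max_mismatch_frac = 0.05) {
  n <- min(nchar(seq), search_window)
  kmax <- n %/% 2L
  kmin <- max(1L, ceiling(min_len / 2))
  none <- tibble::tibble(start = integer(0), end = integer(0),
                         length = integer(0), mismatches = integer(0))
  if (kmax < kmin) return(none)
  chars <- strsplit(substr(seq, 1L, n), "")[[1]]
  # complementary-match counts for every pairing i + j = s via FFT
  # cross-correlation of the nucleotide indicator vectors: a prefix
  # palindrome of length 2k pairs positions summing to 2k + 1
  comp_of <- c(A = "T", C = "G", G = "C", T = "A")
  m <- numeric(2L * n - 1L)
  for (X in NUCS) {
    a <- as.numeric(chars == X)
    b <- as.numeric(chars == comp_of[[X]])
    m <- m + convolve(a, rev(b), type = "open")
  }
  ks <- kmin:kmax
  matches <- round(m[2L * ks]) / 2          # ordered pairs counted twice
  mismatches <- ks - matches
  ok <- mismatches <= max_mismatch_frac * ks
  if (!any(ok)) return(none)
  kbest <- max(ks[ok])
  tibble::tibble(start = 0L, end = 2L * kbest, length = 2L * kbest,
                 mismatches = as.integer(mismatches[match(kbest, ks)]))
}

#' Find TIR-flanked transposon candidates
#'
#' Scans for intervals `[i, j)` whose terminal `L`-mers are reverse
#' complements of each other within a mismatch budget (terminal inverted
#' repeats), with the interval length inside configured bounds -- the
#' structure of hAT-family DNA transposons. Discovery requires an exact
#' inverted core of `tir_min` bases; the TIR is then extended outward as
#' long as the total mismatch count stays within budget. Overlapping
#' candidates are resolved by longest TIR, then leftmost.
#'
#' @param seq nucleotide sequence.
#' @param tir_min minimum (and seed) TIR length, bp.
#' @param tir_max_mismatch mismatch budget for the extended TIR.
#' @param seg_min,seg_max candidate length bounds, bp.
#' @param annotation optional [strain_annotation()]; when given, CDS ids
#'   inside each candidate are reported as cargo.
#' @return tibble `start`, `end`, `length`, `tir_len`, `tir_mismatches`,
#'   `cargo` (list column of gene ids).
#' @export
find_tir_segments <- function(seq, tir_min = 15L, tir_max_mismatch = 2L,
                              seg_min = 2000L, seg_max = 15000L,
                              annotation = NULL) {
  n <- nchar(seq)
  none <- tibble::tibble(start = integer(0), end = integer(0),
                         length = integer(0), tir_len = integer(0),
                         tir_mismatches = integer(0), cargo = list())
  if (n < seg_min) return(none)
  fw <- word_starts(seq, tir_min)                 # word starting at i (1-based)
  rcseq <- revcomp(seq)
  rw <- word_starts(rcseq, tir_min)
  # rw[p] is revcomp of the word *ending* at n - p + 1 in seq
  map_r <- split(seq_along(rw), rw)
  chars <- strsplit(seq, "")[[1]]
  comp <- chartr("ACGTN", "TGCAN", chars)
  cands <- list()
  slot <- match(fw, names(map_r))
  for (i in which(!is.na(slot))) {
    ps <- map_r[[slot[i]]]
    jend <- n - ps + 1L                          # 1-based inclusive end of TIR2
    dist <- jend - i + 1L                        # candidate length j - i (bp)
    ps_ok <- which(dist >= seg_min & dist <= seg_max)
    for (q in ps_ok) {
      j1 <- jend[q]                              # inclusive end position
      # extend the inverted repeat inward from the exact core
      L <- tir_min; mm <- 0L
      while (mm <= tir_max_mismatch) {
        a <- i + L; b <- j1 - L
        if (a >= b - tir_min) break              # keep TIRs apart
        if (chars[a] != comp[b]) mm <- mm + 1L
        if (mm > tir_max_mismatch) break
        L <- L + 1L
      }
      cands[[length(cands) + 1L]] <- tibble::tibble(
        start = i - 1L, end = j1, length = j1 - i + 1L,
        tir_len = L, tir_mismatches = min(mm, tir_max_mismatch))
    }
  }
  if (length(cands) == 0L) return(none)
  cand <- dplyr::bind_rows(cands) |>
    dplyr::distinct() |>
    dplyr::arrange(dplyr::desc(.data$tir_len), .data$start)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1L):nrow(cand)
      ov <- cand$start[later] < cand$end[i] & cand$end[later] > cand$start[i]
      keep[later][ov] <- FALSE
    }
  }
  cand <- cand[keep, ] |> dplyr::arrange(.data$start)
  cand$cargo <- purrr::map2(cand$start, cand$end, function(s, e) {
    if (is.null(annotation)) return(character(0))
    f <- annotation$features
    f$feature_id[f$kind == "CDS" & f$start >= s & f$end <= e]
  })
  cand
}

#' Re-verify reported TIRs by direct comparison
#'
#' Self-audit: checks that each candidate's terminal `tir_len`-mers are
#' reverse complements within the stated mismatch count.
#'
#' @param seq the scanned sequence.
#' @param candidates output of [find_tir_segments()].
#' @return logical vector, one per candidate.
#' @export
verify_tir_candidates <- function(seq, candidates) {
  vapply(seq_len(nrow(candidates)), function(i) {
    s <- candidates$start[i]; e <- candidates$end[i]
    L <- candidates$tir_len[i]
    left <- substr(seq, s + 1L, s + L)
    right <- substr(seq, e - L + 1L, e)
    mm <- sum(strsplit(left, "")[[1]] !=
                strsplit(revcomp(right), "")[[1]])
    mm <= candidates$tir_mismatches[i]
  }, logical(1))
}
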