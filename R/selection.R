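# Pairwise dN/dS by Nei-Gojobori (1986) pathway counting with Jukes-Cantor
# correction, protein-guided codon alignment, the published filters
# (dN > 0, dS > 0, dS <= 2, dN/dS <= 10), and node-stratified aggregation.
#
# Site convention: each codon position contributes exactly one site, split
# into synonymous and nonsynonymous fractions over its non-stop single-
# nucleotide neighbors, so S_sites + N_sites = 3 per codon. A kappa-weighted
# site-counting variant (transition/transversion bias, in the spirit of
# Yang-Nielsen 2000) is available via `kappa`.

# ---- site and difference tables (built once, cached) -----------------------

ng86_env <- new.env(parent = emptyenv())

# synonymous/nonsynonymous site fractions for one sense codon.
# kappa weights transitions at each position (NG86 itself is kappa = 1).
ng86_sites_one <- function(codon, kappa = 1) {
  if (!codon %in% SENSE_CODONS) stop("not a sense codon: ", codon)
  aa <- GENETIC_CODE_VEC[[codon]]
  chars <- strsplit(codon, "")[[1]]
  s_total <- 0; n_total <- 0
  for (pos in 1:3) {
    s_w <- 0; tot_w <- 0; n_w <- 0
    for (nuc in setdiff(NUCS, chars[pos])) {
      mut <- chars; mut[pos] <- nuc
      mutc <- paste(mut, collapse = "")
      if (mutc %in% STOP_CODONS) next   # stop-leading changes excluded
      w <- if (is_transition(chars[pos], nuc)) kappa else 1
      tot_w <- tot_w + w
      if (GENETIC_CODE_VEC[[mutc]] == aa) s_w <- s_w + w else n_w <- n_w + w
    }
    if (tot_w > 0) {
      s_total <- s_total + s_w / tot_w
      n_total <- n_total + n_w / tot_w
    }
    # a position whose every change leads to a stop contributes no site
    if (tot_w == 0) {
      s_total <- s_total + 0
      n_total <- n_total + 1   # does not occur for sense codons (kept for safety)
    }
  }
  c(S_sites = s_total, N_sites = n_total)
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

#' NG86 synonymous/nonsynonymous site counts for a codon
#'
#' Over the single-nucleotide neighbors of each codon position, the fraction
#' of synonymous changes (changes to stop codons are excluded from the
#' denominator), so that `S_sites + N_sites = 3` for every sense codon.
#'
#' @param codon a sense codon (one of the 61).
#' @param kappa transition/transversion rate weight applied to site
#'   counting; `1` gives classic NG86, `> 1` gives a YN00-style variant.
#' @return named numeric vector `c(S_sites, N_sites)`.
#' @export
#' @examples
#' ng86_sites("TTT")
ng86_sites <- function(codon, kappa = 1) {
  ng86_sites_one(toupper(codon), kappa = kappa)
}

# average S/N difference counts over all shortest stop-free mutational
# pathways between two sense codons, pathways equally weighted.
ng86_diffs_one <- function(a, b) {
  if (a == b) return(c(S_diffs = 0, N_diffs = 0))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  perms <- all_permutations(pos)
  s_sum <- 0; n_sum <- 0; n_ok <- 0L
  for (p in seq_len(nrow(perms))) {
    cur <- ca
    s <- 0; n <- 0; ok <- TRUE
    for (j in perms[p, ]) {
      nxt <- cur; nxt[j] <- cb[j]
      codon_next <- paste(nxt, collapse = "")
      if (codon_next %in% STOP_CODONS) { ok <- FALSE; break }
      if (GENETIC_CODE_VEC[[paste(cur, collapse = "")]] ==
          GENETIC_CODE_VEC[[codon_next]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { s_sum <- s_sum + s; n_sum <- n_sum + n; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) {
    # no stop-free path (does not arise between sense codons at <=3 steps,
    # kept as a guard): fall back to counting over all paths
    return(ng86_diffs_all_paths(ca, cb, perms))
  }
  c(S_diffs = s_sum / n_ok, N_diffs = n_sum / n_ok)
}

ng86_diffs_all_paths <- function(ca, cb, perms) {
  s_sum <- 0; n_sum <- 0
  for (p in seq_len(nrow(perms))) {
    cur <- ca; s <- 0; n <- 0
    for (j in perms[p, ]) {
      nxt <- cur; nxt[j] <- cb[j]
      a0 <- GENETIC_CODE_VEC[[paste(cur, collapse = "")]]
      a1 <- GENETIC_CODE_VEC[[paste(nxt, collapse = "")]]
      if (identical(a0, a1)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    s_sum <- s_sum + s; n_sum <- n_sum + n
  }
  c(S_diffs = s_sum / nrow(perms), N_diffs = n_sum / nrow(perms))
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- all_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' NG86 synonymous/nonsynonymous difference counts between two codons
#'
#' Averages the synonymous and nonsynonymous step counts over all shortest
#' mutational pathways between the codons; pathways passing through a stop
#' codon are excluded and the remainder re-weighted equally.
#'
#' @param codon_a,codon_b sense codons.
#' @return named numeric vector `c(S_diffs, N_diffs)`.
#' @export
#' @examples
#' ng86_diffs("TTT", "TTC")
ng86_diffs <- function(codon_a, codon_b) {
  ng86_diffs_one(toupper(codon_a), toupper(codon_b))
}

# cached lookup tables over the 61 sense codons
ng86_tables <- function(kappa = 1) {
  key <- paste0("k", format(kappa, digits = 10))
  if (!is.null(ng86_env[[key]])) return(ng86_env[[key]])
  sites <- t(vapply(SENSE_CODONS, ng86_sites_one, numeric(2), kappa = kappa))
  n <- length(SENSE_CODONS)
  sd_mat <- matrix(0, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  nd_mat <- sd_mat
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- ng86_diffs_one(SENSE_CODONS[i], SENSE_CODONS[j])
        sd_mat[i, j] <- sd_mat[j, i] <- d[["S_diffs"]]
        nd_mat[i, j] <- nd_mat[j, i] <- d[["N_diffs"]]
      }
    }
  }
  tabs <- list(sites = sites, s_diffs = sd_mat, n_diffs = nd_mat)
  ng86_env[[key]] <- tabs
  tabs
}

# ---- protein-guided codon alignment ----------------------------------------

#' Align two coding sequences codon-wise via their proteins
#'
#' Globally aligns the translated proteins (BLOSUM62, gap open 11 / extend
#' 1), drops gapped columns, and re-attaches the codons per aligned residue,
#' yielding the gap-free codon columns the dN/dS estimator consumes.
#'
#' @param nt_a,nt_b in-frame coding sequences (length a multiple of 3, no
#'   internal stop; a terminal stop codon is dropped).
#' @return a `codon_pair_alignment`: list with `codons_a`, `codons_b`
#'   (equal-length codon vectors), `n_codons`, `gene_a`, `gene_b`.
#' @param gene_a,gene_b optional sequence identifiers carried through.
#' @export
codon_align_via_protein <- function(nt_a, nt_b, gene_a = "a", gene_b = "b") {
  for (s in c(nt_a, nt_b)) {
    if (nchar(s) %% 3L != 0L) stop("coding sequence length not a multiple of 3")
  }
  ca <- drop_terminal_stop(split_codons(nt_a))
  cb <- drop_terminal_stop(split_codons(nt_b))
  pa <- paste(GENETIC_CODE_VEC[ca], collapse = "")
  pb <- paste(GENETIC_CODE_VEC[cb], collapse = "")
  if (grepl("\\*", pa) || grepl("\\*", pb)) stop("internal stop codon")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  qb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(qa != "-"); ib <- cumsum(qb != "-")
  keep <- qa != "-" & qb != "-"
  structure(list(
    codons_a = ca[ia[keep]], codons_b = cb[ib[keep]],
    n_codons = sum(keep), gene_a = gene_a, gene_b = gene_b
  ), class = "codon_pair_alignment")
}

drop_terminal_stop <- function(codons) {
  if (length(codons) > 0L && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  codons
}

# ---- pairwise dN/dS ---------------------------------------------------------

#' Pairwise dN/dS for a codon alignment (NG86 + Jukes-Cantor)
#'
#' Site counts are averaged over the two sequences; proportions are
#' corrected with Jukes-Cantor, `d = -(3/4) log(1 - 4p/3)`. The estimate
#' passes the downstream filters iff `dN > 0`, `dS > 0`, `dS <= 2` and
#' `dN/dS <= 10`; a proportion `p >= 3/4` leaves the distance undefined and
#' fails the filters.
#'
#' @param aln a `codon_pair_alignment` (or a list with `codons_a`,
#'   `codons_b`).
#' @param min_codons minimum aligned codons required.
#' @param kappa site-counting transition weight (1 = classic NG86).
#' @return one-row tibble: `gene_a`, `gene_b`, `n_codons`, `S_sites`,
#'   `N_sites`, `S_diffs`, `N_diffs`, `dS`, `dN`, `omega`, `passed_filters`.
#' @export
dnds_pair <- function(aln, min_codons = 30L, kappa = 1) {
  ca <- aln$codons_a; cb <- aln$codons_b
  stopifnot(length(ca) == length(cb))
  keep <- ca %in% SENSE_CODONS & cb %in% SENSE_CODONS
  ca <- ca[keep]; cb <- cb[keep]
  n <- length(ca)
  if (n < min_codons) {
    stop("alignment has ", n, " codons; at least ", min_codons, " required")
  }
  tabs <- ng86_tables(kappa)
  s_sites <- (sum(tabs$sites[ca, "S_sites"]) + sum(tabs$sites[cb, "S_sites"])) / 2
  n_sites <- (sum(tabs$sites[ca, "N_sites"]) + sum(tabs$sites[cb, "N_sites"])) / 2
  idx <- cbind(match(ca, SENSE_CODONS), match(cb, SENSE_CODONS))
  s_diffs <- sum(tabs$s_diffs[idx])
  n_diffs <- sum(tabs$n_diffs[idx])
  ps <- s_diffs / s_sites
  pn <- n_diffs / n_sites
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ds <- jc(ps); dn <- jc(pn)
  omega <- if (!is.na(ds) && !is.na(dn) && ds > 0) dn / ds else NA_real_
  passed <- !is.na(dn) && !is.na(ds) && dn > 0 && ds > 0 && ds <= 2 &&
    !is.na(omega) && omega <= 10
  tibble::tibble(
    gene_a = aln$gene_a %||% "a", gene_b = aln$gene_b %||% "b",
    n_codons = n, S_sites = s_sites, N_sites = n_sites,
    S_diffs = s_diffs, N_diffs = n_diffs,
    dS = ds, dN = dn, omega = omega, passed_filters = passed
  )
}

#' Node-stratified summary of dN/dS estimates
#'
#' Joins per-pair estimates to their creation/acquisition node and
#' summarizes the filter-passing pairs per node: the microevolution figure
#' of selection strength against gene age. Nodes without passing pairs are
#' omitted.
#'
#' @param estimates tibble from [dnds_pair()] rows with a `node` column
#'   (internal node label), or without one if `assignments` is supplied.
#' @param assignments optional tibble `gene_a`, `node` mapping pairs to
#'   nodes (joined on `gene_a`).
#' @return tibble `node`, `mean_omega`, `sd_omega`, `n`, of class
#'   `node_omega_summary`.
#' @export
aggregate_by_node <- function(estimates, assignments = NULL) {
  est <- tibble::as_tibble(estimates)
  if (!is.null(assignments)) {
    est <- dplyr::left_join(est, dplyr::select(tibble::as_tibble(assignments),
                                               "gene_a", "node"),
                            by = "gene_a")
  }
  if (!"node" %in% names(est)) stop("estimates need a `node` column")
  out <- est |>
    dplyr::filter(.data$passed_filters, !is.na(.data$node)) |>
    dplyr::group_by(node = as.character(.data$node)) |>
    dplyr::summarise(mean_omega = mean(.data$omega),
                     sd_omega = sd(.data$omega),
                     n = dplyr::n(), .groups = "drop")
  class(out) <- c("node_omega_summary", class(out))
  out
}
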