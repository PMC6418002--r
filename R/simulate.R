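# Forward simulation of genome evolution along a labeled tree: GC-rich
# coding regions, lower-GC intergenic DNA, de novo gene birth from
# intergenic protogenes on specified branches, gene death with the dead
# copy left drifting as non-coding sequence, and transcript-coverage
# simulation around the expression-validation threshold. Every run returns
# ground truth for the downstream estimators.

#' Simulation parameters
#'
#' Defaults target the compositions observed in pandoravirus genomes:
#' coding G+C 64.4%, intergenic/protogene G+C 57.5%. Birth/death rates are
#' illustrative (the biology fixes no value); omega defaults encode
#' purifying selection on ancestral genes and weak purifying selection on
#' newborns.
#'
#' @param coding_gc G+C fraction of ancestral coding DNA.
#' @param intergenic_gc G+C fraction of intergenic DNA and protogenes.
#' @param omega_ancestral,omega_newborn dN/dS targets per gene class.
#' @param kappa transition/transversion rate ratio.
#' @param birth_rate expected de novo gene births per branch (Poisson).
#' @param death_rate per-gene probability of loss on a branch.
#' @param gene_length_meanlog,gene_length_sdlog log-normal parameters of
#'   newborn protein length (aa), truncated at `min_gene_aa`.
#' @param ancestral_length_meanlog,ancestral_length_sdlog log-normal
#'   parameters of ancestral protein length (aa).
#' @param min_gene_aa minimum protein length (aa).
#' @param indel_rate intergenic indel events per site per unit branch length.
#' @param n_ancestral_genes genes in the root genome.
#' @param intergenic_len mean intergenic segment length (nt).
#' @param n_ncrna ncRNA loci planted in the root genome.
#' @param ncrna_on_prob per-leaf probability that an ncRNA locus is
#'   transcriptionally on.
#' @param seed master seed; per-branch substreams are derived from it.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(coding_gc = 0.644, intergenic_gc = 0.575,
                       omega_ancestral = 0.2, omega_newborn = 0.6,
                       kappa = 2.0,
                       birth_rate = 1.0, death_rate = 0.05,
                       gene_length_meanlog = log(120),
                       gene_length_sdlog = 0.4,
                       ancestral_length_meanlog = log(330),
                       ancestral_length_sdlog = 0.5,
                       min_gene_aa = 30L,
                       indel_rate = 0.02,
                       n_ancestral_genes = 30L,
                       intergenic_len = 400L,
                       n_ncrna = 8L,
                       ncrna_on_prob = 0.5,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$coding_gc > 0, p$coding_gc < 1,
            p$intergenic_gc > 0, p$intergenic_gc < 1,
            p$birth_rate >= 0, p$death_rate >= 0, p$death_rate <= 1,
            p$omega_ancestral > 0, p$omega_newborn > 0, p$kappa > 0)
  structure(p, class = "sim_params")
}

# ---- codon model ------------------------------------------------------------

# Goldman-Yang-style symmetric rate matrix over the 61 sense codons:
# single-nucleotide changes only, x kappa for transitions, x omega for
# nonsynonymous changes, 0 to/from stop. Scaled so one unit of t is one
# expected nucleotide substitution per site (3 per codon) under the
# stationary (uniform) distribution.
codon_rate_matrix <- function(omega, kappa) {
  n <- length(SENSE_CODONS)
  Q <- matrix(0, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  chars <- strsplit(SENSE_CODONS, "")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(chars[[i]] != chars[[j]])
      if (length(diff) != 1L) next
      r <- if (is_transition(chars[[i]][diff], chars[[j]][diff])) kappa else 1
      if (GENETIC_CODE_VEC[[SENSE_CODONS[i]]] !=
          GENETIC_CODE_VEC[[SENSE_CODONS[j]]]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  Q * (3 / mean(-diag(Q)))
}

codon_model_env <- new.env(parent = emptyenv())

# eigen decomposition of the (symmetric) rate matrix, cached per model
codon_model_eigen <- function(omega, kappa) {
  key <- paste0("o", format(omega, digits = 12), "_k",
                format(kappa, digits = 12))
  if (is.null(codon_model_env[[key]])) {
    codon_model_env[[key]] <- eigen(codon_rate_matrix(omega, kappa),
                                    symmetric = TRUE)
  }
  codon_model_env[[key]]
}

codon_transition_probs <- function(omega, kappa, t) {
  e <- codon_model_eigen(omega, kappa)
  P <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(SENSE_CODONS, SENSE_CODONS)
  P
}

#' Evolve a codon sequence along one branch
#'
#' Continuous-time codon substitution (Goldman-Yang-style rates: transitions
#' weighted by `kappa`, nonsynonymous changes by `omega`, no paths to or
#' from stops), applied for a branch of length `t` expected substitutions
#' per nucleotide site. A terminal stop codon is carried through unchanged.
#'
#' @param seq in-frame coding sequence, stop-free except for an optional
#'   terminal stop.
#' @param t branch length (substitutions/site, >= 0).
#' @param omega dN/dS target.
#' @param kappa transition/transversion rate ratio.
#' @param seed integer seed (optional; uses the current RNG state if NULL).
#' @return evolved coding sequence, same length.
#' @export
evolve_codon_sequence <- function(seq, t, omega, kappa = 2.0, seed = NULL) {
  stopifnot(t >= 0)
  if (!is.null(seed)) set.seed(seed)
  codons <- split_codons(seq)
  term <- character(0)
  if (length(codons) > 0L && codons[length(codons)] %in% STOP_CODONS) {
    term <- codons[length(codons)]
    codons <- codons[-length(codons)]
  }
  if (any(!codons %in% SENSE_CODONS)) stop("internal stop or ambiguous codon")
  if (t == 0 || length(codons) == 0L) {
    return(paste(c(codons, term), collapse = ""))
  }
  P <- codon_transition_probs(omega, kappa, t)
  out <- codons
  for (cod in unique(codons)) {
    idx <- which(codons == cod)
    out[idx] <- sample(SENSE_CODONS, length(idx), replace = TRUE,
                       prob = P[cod, ])
  }
  paste(c(out, term), collapse = "")
}

# ---- protogene / coding sequence sampling ----------------------------------

# per-nucleotide GC probability such that codons drawn iid from the
# stop-free codon distribution realize the target GC in expectation
calibrate_gc <- function(target_gc, codons = SENSE_CODONS) {
  gc_count <- vapply(strsplit(codons, ""),
                     function(ch) sum(ch %in% c("G", "C")), numeric(1))
  expected_gc <- function(g) {
    p_nuc <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    w <- vapply(strsplit(codons, ""),
                function(ch) prod(p_nuc[ch]), numeric(1))
    sum(w * gc_count) / (3 * sum(w))
  }
  uniroot(function(g) expected_gc(g) - target_gc, c(0.02, 0.98))$root
}

sample_codons <- function(n, gc, codons = SENSE_CODONS) {
  g <- calibrate_gc(gc, codons)
  p_nuc <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  w <- vapply(strsplit(codons, ""), function(ch) prod(p_nuc[ch]), numeric(1))
  sample(codons, n, replace = TRUE, prob = w)
}

#' Sample a protogene: an intergenic-composition ORF
#'
#' Draws an open reading frame (ATG ... stop, no internal stop) whose codon
#' composition is calibrated to the intergenic G+C model rather than the
#' coding one -- the raw material for de novo gene birth.
#'
#' @param params a [sim_params()] object.
#' @param length_aa protein length in amino acids (>= 30), including the
#'   initiator methionine; the returned DNA has `3 * (length_aa + 1)` bases
#'   (terminal stop included).
#' @param seed integer seed (optional).
#' @return nucleotide sequence string.
#' @export
sample_protogene <- function(params, length_aa, seed = NULL) {
  stopifnot(length_aa >= 30L)
  if (!is.null(seed)) set.seed(seed)
  body <- sample_codons(length_aa - 1L, params$intergenic_gc)
  stop_codon <- sample(STOP_CODONS, 1L)
  paste(c("ATG", body, stop_codon), collapse = "")
}

# ancestral coding gene, coding-GC composition
sample_coding_gene <- function(params, length_aa) {
  body <- sample_codons(length_aa - 1L, params$coding_gc)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

# ---- intergenic evolution ---------------------------------------------------

# Jukes-Cantor substitution plus geometric-length indels (p = 0.5, max 10 nt)
evolve_noncoding <- function(seq, t, indel_rate, gc) {
  n <- nchar(seq)
  if (n == 0L || t == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  p_diff <- 0.75 * (1 - exp(-4 * t / 3))
  mut <- which(runif(n) < p_diff)
  if (length(mut) > 0L) {
    chars[mut] <- vapply(chars[mut],
                         function(b) sample(setdiff(NUCS, b), 1L), character(1))
  }
  n_events <- rpois(1, indel_rate * n * t)
  for (k in seq_len(n_events)) {
    len <- min(rgeom(1, 0.5) + 1L, 10L)
    pos <- sample.int(length(chars) + 1L, 1L)
    if (runif(1) < 0.5 && length(chars) > len) {   # deletion
      del <- pos:min(pos + len - 1L, length(chars))
      chars <- chars[-del]
    } else {                                       # insertion
      ins <- strsplit(random_dna(len, gc), "")[[1]]
      chars <- append(chars, ins, after = pos - 1L)
    }
  }
  paste(chars, collapse = "")
}

# ---- family simulation ------------------------------------------------------

#' Simulate a gene family history along a labeled tree
#'
#' The root genome alternates CDS and intergenic segments (plus planted
#' ncRNA loci). Down each branch, coding segments evolve under the codon
#' model at their class omega, non-coding segments drift under
#' Jukes-Cantor with indels, gene births insert protogene-derived CDS at
#' intergenic positions, and gene deaths demote the CDS to drifting
#' non-coding DNA -- so traces of dead and ancestral genes remain findable
#' by translated search. Per-branch RNG substreams are derived from the
#' master seed, so draws on one branch do not perturb the others.
#'
#' @param tree a `labeled_tree` (>= 2 leaves).
#' @param params a [sim_params()] object.
#' @return list with `annotations` (named list of [strain_annotation()] per
#'   leaf), `truth` (per-gene tibble: `gene_id`, `origin`, `birth_branch`,
#'   `death_branches`, `omega`, `length_aa`), `ncrna_truth` (tibble
#'   `ncrna_id`, `leaf`, `on`), and `presence` (gene x leaf logical matrix
#'   implied by the leaf annotations).
#' @export
simulate_family <- function(tree, params = sim_params()) {
  stopifnot(inherits(tree, "labeled_tree"), inherits(params, "sim_params"))
  phy <- tree$phylo
  if (length(phy$tip.label) < 2L) stop("tree needs at least 2 leaves")
  if (params$n_ancestral_genes + params$birth_rate == 0) {
    stop("parameters yield zero genes; increase n_ancestral_genes or birth_rate")
  }
  set.seed(derive_seed(params$seed, "root"))

  # root genome: intergenic / CDS alternation + ncRNA loci in intergenic gaps
  segments <- list()
  add_seg <- function(seg) segments[[length(segments) + 1L]] <<- seg
  rand_intergenic <- function() {
    random_dna(max(50L, rpois(1, params$intergenic_len)), params$intergenic_gc)
  }
  truth <- list()
  for (i in seq_len(params$n_ancestral_genes)) {
    add_seg(list(type = "intergenic", seq = rand_intergenic()))
    len <- max(params$min_gene_aa,
               round(rlnorm(1, params$ancestral_length_meanlog,
                            params$ancestral_length_sdlog)))
    gid <- sprintf("g%04d", i)
    add_seg(list(type = "cds", id = gid, strand = sample(c("+", "-"), 1L),
                 seq = sample_coding_gene(params, len),
                 omega = params$omega_ancestral))
    truth[[gid]] <- list(gene_id = gid, origin = "ancestral_core",
                         birth_branch = phy$node.label[1],
                         death_branches = character(0),
                         omega = params$omega_ancestral, length_aa = len)
  }
  for (j in seq_len(params$n_ncrna)) {
    add_seg(list(type = "intergenic", seq = rand_intergenic()))
    nlen <- max(200L, round(rlnorm(1, log(1000), 0.4)))
    add_seg(list(type = "ncrna", id = sprintf("nc%03d", j),
                 strand = sample(c("+", "-"), 1L),
                 seq = random_dna(nlen, params$intergenic_gc)))
  }
  add_seg(list(type = "intergenic", seq = rand_intergenic()))
  birth_counter <- new.env(parent = emptyenv())
  birth_counter$n <- 0L

  edges <- tree_edge_table(tree)
  root_label <- phy$node.label[1]
  annotations <- list()
  ncrna_truth <- list()

  descend <- function(node_label, segs) {
    kids <- edges[edges$parent == node_label, ]
    for (k in seq_len(nrow(kids))) {
      child <- kids$child[k]
      t <- kids$length[k]
      set.seed(derive_seed(params$seed, paste0("branch_", child)))
      csegs <- evolve_branch(segs, child, t, params, truth_env, birth_counter)
      if (kids$child_is_leaf[k]) {
        set.seed(derive_seed(params$seed, paste0("leaf_", child)))
        built <- assemble_leaf(child, csegs, params)
        annotations[[child]] <<- built$annotation
        ncrna_truth[[child]] <<- built$ncrna_states
      } else {
        descend(child, csegs)
      }
    }
  }
  truth_env <- new.env(parent = emptyenv())
  truth_env$truth <- truth
  descend(root_label, segments)

  truth_tbl <- dplyr::bind_rows(lapply(truth_env$truth, function(g) {
    tibble::tibble(gene_id = g$gene_id, origin = g$origin,
                   birth_branch = g$birth_branch,
                   death_branches = paste(g$death_branches, collapse = ","),
                   omega = g$omega, length_aa = g$length_aa)
  }))
  nc_tbl <- dplyr::bind_rows(lapply(names(ncrna_truth), function(leaf) {
    st <- ncrna_truth[[leaf]]
    tibble::tibble(ncrna_id = names(st), leaf = leaf, on = unname(st))
  }))
  presence <- presence_matrix_from_annotations(annotations, truth_tbl$gene_id)
  list(annotations = annotations, truth = truth_tbl,
       ncrna_truth = nc_tbl, presence = presence)
}

evolve_branch <- function(segs, child, t, params, truth_env, birth_counter) {
  out <- lapply(segs, function(seg) {
    switch(seg$type,
      cds = {
        seg$seq <- evolve_codon_sequence(seg$seq, t, seg$omega, params$kappa)
        seg
      },
      ncrna = {
        seg$seq <- evolve_noncoding(seg$seq, t, 0, params$intergenic_gc)
        seg
      },
      {
        seg$seq <- evolve_noncoding(seg$seq, t, params$indel_rate,
                                    params$intergenic_gc)
        seg
      })
  })
  # deaths: demote CDS to drifting non-coding DNA
  for (i in seq_along(out)) {
    if (out[[i]]$type == "cds" && runif(1) < params$death_rate) {
      g <- truth_env$truth[[out[[i]]$id]]
      g$death_branches <- c(g$death_branches, child)
      truth_env$truth[[out[[i]]$id]] <- g
      seqnc <- if (out[[i]]$strand == "+") out[[i]]$seq else revcomp(out[[i]]$seq)
      out[[i]] <- list(type = "intergenic", seq = seqnc)
    }
  }
  # births: protogene-derived CDS inserted at intergenic positions
  n_births <- rpois(1, params$birth_rate)
  for (b in seq_len(n_births)) {
    birth_counter$n <- birth_counter$n + 1L
    gid <- sprintf("n%04d", birth_counter$n)
    len <- max(params$min_gene_aa,
               round(rlnorm(1, params$gene_length_meanlog,
                            params$gene_length_sdlog)))
    gseq <- paste(c("ATG", sample_codons(len - 1L, params$intergenic_gc),
                    sample(STOP_CODONS, 1L)), collapse = "")
    newseg <- list(type = "cds", id = gid, strand = sample(c("+", "-"), 1L),
                   seq = gseq, omega = params$omega_newborn)
    ig <- which(vapply(out, function(s) s$type == "intergenic", logical(1)))
    pos <- sample(ig, 1L)
    cut <- sample.int(nchar(out[[pos]]$seq) + 1L, 1L) - 1L
    left <- list(type = "intergenic", seq = substr(out[[pos]]$seq, 1, cut))
    right <- list(type = "intergenic",
                  seq = substr(out[[pos]]$seq, cut + 1, nchar(out[[pos]]$seq)))
    out <- append(out[-pos], list(left, newseg, right), after = pos - 1L)
    truth_env$truth[[gid]] <- list(gene_id = gid, origin = "protogene_birth",
                                   birth_branch = child,
                                   death_branches = character(0),
                                   omega = params$omega_newborn,
                                   length_aa = len)
  }
  out
}

assemble_leaf <- function(leaf, segs, params) {
  pieces <- character(length(segs))
  feats <- list()
  ncrna_states <- logical(0)
  offset <- 0L
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    s <- switch(seg$type,
      cds = if (seg$strand == "+") seg$seq else revcomp(seg$seq),
      seg$seq)
    pieces[i] <- s
    len <- nchar(s)
    if (seg$type == "cds") {
      feats[[length(feats) + 1L]] <- tibble::tibble(
        feature_id = seg$id, kind = "CDS",
        start = offset, end = offset + len, strand = seg$strand)
    } else if (seg$type == "ncrna") {
      on <- runif(1) < params$ncrna_on_prob
      ncrna_states[seg$id] <- on
      if (on) {
        feats[[length(feats) + 1L]] <- tibble::tibble(
          feature_id = seg$id, kind = "ncRNA",
          start = offset, end = offset + len, strand = seg$strand)
      }
    }
    offset <- offset + len
  }
  ann <- strain_annotation(leaf, paste(pieces, collapse = ""),
                           dplyr::bind_rows(feats))
  list(annotation = ann, ncrna_states = ncrna_states)
}

# gene x leaf presence matrix read off the leaf annotations
presence_matrix_from_annotations <- function(annotations, gene_ids) {
  leaves <- names(annotations)
  m <- matrix(FALSE, length(gene_ids), length(leaves),
              dimnames = list(gene_ids, leaves))
  for (leaf in leaves) {
    f <- annotations[[leaf]]$features
    ids <- intersect(f$feature_id[f$kind == "CDS"], gene_ids)
    m[ids, leaf] <- TRUE
  }
  m
}

#' Presence matrix implied by a simulation truth table
#'
#' A gene is present in a leaf iff its birth branch is ancestral to (or is)
#' the leaf and no death occurred on the path from the birth branch to the
#' leaf.
#'
#' @param tree the `labeled_tree` used in the simulation.
#' @param truth the `truth` tibble from [simulate_family()].
#' @return logical matrix genes x leaves.
#' @export
truth_presence_matrix <- function(tree, truth) {
  leaves <- tree_leaves(tree)
  m <- matrix(FALSE, nrow(truth), length(leaves),
              dimnames = list(truth$gene_id, leaves))
  edges <- tree_edge_table(tree)
  parent_of <- setNames(edges$parent, edges$child)
  root <- setdiff(edges$parent, edges$child)[1]
  path_to_root <- function(x) {
    p <- character(0)
    while (x != root) { p <- c(p, x); x <- parent_of[[x]] }
    c(p, root)
  }
  for (i in seq_len(nrow(truth))) {
    birth <- truth$birth_branch[i]
    deaths <- strsplit(truth$death_branches[i], ",")[[1]]
    deaths <- deaths[nzchar(deaths)]
    for (leaf in leaves) {
      path <- path_to_root(leaf)
      if (!birth %in% path) next
      seg <- path[seq_len(match(birth, path))]   # birth branch .. leaf
      m[i, leaf] <- !any(deaths %in% seg)
    }
  }
  m
}

# ---- coverage simulation ----------------------------------------------------

#' Simulate per-feature median transcript coverage
#'
#' "On" features draw their median coverage from a high log-normal regime
#' (median around 300x, matching the order of magnitude of observed
#' transcript coverages), offset so every on-feature clears the
#' expression-validation threshold of 5; "off" features draw uniformly
#' below it.
#'
#' @param ann a [strain_annotation()] object.
#' @param on_fraction fraction of features transcriptionally on.
#' @param seed integer seed (optional).
#' @param meanlog,sdlog log-normal parameters of the on regime.
#' @return the annotation with `median_coverage` filled in, plus an `on`
#'   logical column in `$features`.
#' @export
simulate_coverage <- function(ann, on_fraction, seed = NULL,
                              meanlog = log(300), sdlog = 1) {
  stopifnot(on_fraction >= 0, on_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ann$features)
  on <- runif(n) < on_fraction
  cov <- ifelse(on, 5 + rlnorm(n, meanlog, sdlog), runif(n, 0, 4.9))
  ann$features$median_coverage <- cov
  ann$features$on <- on
  ann
}

#' Build a stranded per-base coverage track from annotated features
#'
#' Produces the abstract coverage input the ncRNA caller consumes: constant
#' depth over each feature interval on the feature's strand, zero
#' elsewhere. Intended for synthetic experiments where features carry an
#' `on` state and a `median_coverage`.
#'
#' @param ann a [strain_annotation()] whose features carry
#'   `median_coverage` (e.g. from [simulate_coverage()]).
#' @return tibble `pos` (0-based), `strand`, `depth` for nonzero positions.
#' @export
simulate_coverage_track <- function(ann) {
  f <- ann$features
  if ("on" %in% names(f)) f <- f[f$on, ]
  f <- f[!is.na(f$median_coverage) & f$median_coverage > 0, ]
  if (nrow(f) == 0L) {
    return(tibble::tibble(pos = integer(0), strand = character(0),
                          depth = numeric(0)))
  }
  purrr::pmap_dfr(list(f$start, f$end, f$strand, f$median_coverage),
                  function(s, e, st, d) {
                    tibble::tibble(pos = seq.int(s, e - 1L), strand = st,
                                   depth = d)
                  }) |>
    dplyr::group_by(.data$pos, .data$strand) |>
    dplyr::summarise(depth = sum(.data$depth), .groups = "drop")
}
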