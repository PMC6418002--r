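# Packaged synthetic recovery experiments: estimator calibration studies
# run at fixed, documented problem sizes. These define the study
# conditions under which the pipeline's claims are checked.

#' dN/dS recovery under a known selection regime
#'
#' Evolves a stop-free ancestral codon sequence for a branch of length
#' `2 * t_half` (ancestor to one descendant via the root, symmetrically),
#' aligns ancestor-free descendant pairs through their proteins and
#' re-estimates omega with the NG86 estimator.
#'
#' @param omega true dN/dS of the simulation.
#' @param n_codons sequence length in codons.
#' @param t_half branch length from the common ancestor to each
#'   descendant (substitutions/site).
#' @param n_reps replicates.
#' @param kappa transition/transversion ratio of the simulation.
#' @param seed master seed.
#' @return tibble with one row per replicate: `rep`, `omega_hat`, `dS`,
#'   `dN`, `passed_filters`.
#' @export
dnds_recovery_experiment <- function(omega, n_codons = 3000L, t_half = 0.15,
                                     n_reps = 20L, kappa = 1, seed = 1L) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    set.seed(derive_seed(seed, paste0("dnds_", omega, "_", r)))
    anc <- paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
    d1 <- evolve_codon_sequence(anc, t_half, omega, kappa)
    d2 <- evolve_codon_sequence(anc, t_half, omega, kappa)
    est <- dnds_pair(codon_align_via_protein(d1, d2))
    tibble::tibble(rep = r, omega_hat = est$omega, dS = est$dS, dN = est$dN,
                   passed_filters = est$passed_filters)
  })
}

#' Planted-trace creation-node recovery experiment
#'
#' Simulates genome families on a (scaled) labeled tree with de novo gene
#' births and deaths, then dates every newborn gene exactly as the
#' pipeline would: annotated homologs in strains still carrying the gene
#' plus translated non-coding trace searches in the others, MRCA
#' assignment on the tree. A gene born on a terminal branch is counted as
#' recovered when no evidence (hence no node) is assigned.
#'
#' @param tree a `labeled_tree`; branch lengths are multiplied by
#'   `tree_scale` to set the divergence regime.
#' @param n_reps number of simulated families.
#' @param seed master seed.
#' @param tree_scale branch-length multiplier (low-divergence default).
#' @param params_fn function(rep_seed) returning [sim_params()] for each
#'   replicate.
#' @param E_max trace-search E-value cutoff.
#' @return tibble with one row per assessable newborn gene: `rep`,
#'   `gene_id`, `true_node`, `assigned_node`, `correct`.
#' @export
trace_recovery_experiment <- function(tree = pandoravirus_tree(),
                                      n_reps = 20L, seed = 1L,
                                      tree_scale = 0.25,
                                      params_fn = NULL, E_max = 1e-3) {
  phy <- tree$phylo
  phy$edge.length <- phy$edge.length * tree_scale
  tr <- labeled_tree(phy)
  internal <- phy$node.label
  if (is.null(params_fn)) {
    params_fn <- function(s) {
      sim_params(seed = s, n_ancestral_genes = 6L, birth_rate = 0.5,
                 death_rate = 0.1, intergenic_len = 150L, n_ncrna = 2L)
    }
  }
  purrr::map_dfr(seq_len(n_reps), function(r) {
    sim <- simulate_family(tr, params_fn(derive_seed(seed, paste0("rep", r))))
    newborn <- sim$truth[sim$truth$origin == "protogene_birth", ]
    if (nrow(newborn) == 0L) return(NULL)
    idx_cache <- new.env(parent = emptyenv())
    index_of <- function(leaf) {
      if (is.null(idx_cache[[leaf]])) {
        idx_cache[[leaf]] <- subject_frame_index(sim$annotations[[leaf]])
      }
      idx_cache[[leaf]]
    }
    purrr::map_dfr(newborn$gene_id, function(g) {
      carriers <- colnames(sim$presence)[sim$presence[g, ]]
      if (length(carriers) == 0L) return(NULL)    # extinct: nothing to query
      focal <- sort(carriers)[1]
      prot <- annotation_proteins(sim$annotations[[focal]])
      query <- prot$protein[prot$gene_id == g]
      if (length(query) != 1L || nchar(query) < 20L) return(NULL)
      absent <- setdiff(tree_leaves(tr), carriers)
      traced <- absent[vapply(absent, function(leaf) {
        nrow(translated_noncoding_search(query, sim$annotations[[leaf]],
                                         E_max = E_max,
                                         index = index_of(leaf))) > 0L
      }, logical(1))]
      evidence <- union(setdiff(carriers, focal), traced)
      assigned <- assign_creation_node(tr, focal, evidence)$node
      truth_node <- newborn$birth_branch[newborn$gene_id == g]
      correct <- if (truth_node %in% internal) {
        identical(assigned, truth_node)
      } else {
        is.na(assigned)     # terminal-branch birth: truly strain-unique
      }
      tibble::tibble(rep = r, gene_id = g, true_node = truth_node,
                     assigned_node = assigned %||% NA_character_,
                     correct = correct)
    })
  })
}

#' Type-I error calibration of the composition chi-square
#'
#' Draws the reference residue pool once, then repeatedly samples a
#' "novel" set from the reference frequencies (the null) and records the
#' rejection rate at the nominal level.
#'
#' @param n_reps null replicates.
#' @param n_residues_a residues in each sampled novel set.
#' @param n_residues_b residues in the reference pool.
#' @param alpha nominal level.
#' @param seed master seed.
#' @return list `rejection_rate`, `p_values`.
#' @export
chi_square_null_calibration <- function(n_reps = 500L, n_residues_a = 3800L,
                                        n_residues_b = 100000L,
                                        alpha = 0.05, seed = 1L) {
  set.seed(derive_seed(seed, "chi2ref"))
  freqs <- c(8.6, 5, 4, 6, 1.5, 4, 6, 7, 2, 5, 9, 2, 2.2, 2.2, 5, 6.5,
             5.5, 1, 3, 6.5)
  freqs <- freqs / sum(freqs)
  ref <- paste(sample(AMINO_ACIDS, n_residues_b, replace = TRUE, prob = freqs),
               collapse = "")
  ref_freq <- residue_counts(ref)
  ref_freq <- ref_freq / sum(ref_freq)
  p <- vapply(seq_len(n_reps), function(r) {
    set.seed(derive_seed(seed, paste0("chi2_", r)))
    a <- paste(sample(AMINO_ACIDS, n_residues_a, replace = TRUE,
                      prob = ref_freq), collapse = "")
    composition_chi_square(a, ref)$p_value
  }, numeric(1))
  list(rejection_rate = mean(p < alpha), p_values = p)
}
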