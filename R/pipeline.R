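# End-to-end orchestration: the two-strain microevolution comparison
# (unique genes -> trace dating -> context -> signatures, mirroring the
# published unique-gene table) and the synthetic-mode pipeline run that
# writes every module's tables plus a summary JSON.

# coding nucleotide sequence of a CDS feature (coding sense)
feature_nt <- function(ann, feature_id) {
  f <- ann$features[ann$features$feature_id == feature_id, ]
  stopifnot(nrow(f) == 1L)
  nt <- substr(ann$sequence, f$start + 1L, f$end)
  if (f$strand == "-") nt <- revcomp(nt)
  nt
}

#' Compare a strain pair: unique genes, dating, contexts, signatures
#'
#' Identifies the protein-coding genes unique to each of two focal strains
#' (clusters with no member in the partner strain), dates each one by
#' combining annotated homologs in other strains with translated
#' non-coding trace searches, classifies the genomic context of the best
#' trace in the partner genome, and contrasts the compositional signatures
#' of the unique genes against the rest of the focal proteomes.
#'
#' @param ann_a,ann_b the two focal [strain_annotation()]s.
#' @param annotations named list of all strain annotations (must include
#'   the two focal strains; additional strains supply trace evidence).
#' @param tree `labeled_tree` containing every strain.
#' @param clusters optional precomputed [cluster_proteins()] result over
#'   all strains' proteins.
#' @param E_max trace-search E-value cutoff.
#' @param min_identity,min_coverage clustering thresholds.
#' @return list with `report` (one row per unique gene: `gene_id`,
#'   `strain`, `length_aa`, `most_ancestral_detection`, `homolog_context`,
#'   `median_coverage`), `unique_a`, `unique_b` (gene id vectors),
#'   `ortholog_pairs` (reciprocal-best pairs between the focal strains),
#'   `signatures` (tibble from [signature_report()]), and `clusters`.
#' @export
compare_strain_pair <- function(ann_a, ann_b, annotations, tree,
                                clusters = NULL, E_max = 1e-3,
                                min_identity = 0.30, min_coverage = 0.50) {
  sid_a <- ann_a$strain_id; sid_b <- ann_b$strain_id
  stopifnot(sid_a %in% names(annotations), sid_b %in% names(annotations),
            all(c(sid_a, sid_b) %in% tree_leaves(tree)))
  proteins <- dplyr::bind_rows(lapply(annotations, annotation_proteins))
  if (is.null(clusters)) {
    clusters <- cluster_proteins(proteins, min_identity, min_coverage)
  }
  mem <- clusters$members
  if (!all(c(sid_a, sid_b) %in% mem$strain)) {
    stop("focal strain missing from clustering: ",
         paste(setdiff(c(sid_a, sid_b), mem$strain), collapse = ", "))
  }
  strains_of <- split(mem$strain, mem$cluster)
  cluster_of <- setNames(mem$cluster, paste0(mem$strain, ":", mem$gene_id))

  unique_to <- function(sid, partner) {
    g <- mem[mem$strain == sid, ]
    keep <- vapply(g$cluster, function(cl) !partner %in% strains_of[[cl]],
                   logical(1))
    sort(g$gene_id[keep])
  }
  unique_a <- unique_to(sid_a, sid_b)
  unique_b <- unique_to(sid_b, sid_a)

  # six-frame indexes are built lazily once per subject strain
  index_cache <- new.env(parent = emptyenv())
  index_of <- function(sid) {
    if (is.null(index_cache[[sid]])) {
      index_cache[[sid]] <- subject_frame_index(annotations[[sid]])
    }
    index_cache[[sid]]
  }

  trace_one <- function(sid, partner_sid, gene_id) {
    ann <- annotations[[sid]]
    prot <- annotation_proteins(ann)
    query <- prot$protein[prot$gene_id == gene_id]
    cl <- cluster_of[[paste0(sid, ":", gene_id)]]
    homolog_strains <- setdiff(unique(strains_of[[cl]]), sid)
    others <- setdiff(names(annotations), sid)
    trace_strains <- character(0)
    partner_context <- "none"
    for (os in setdiff(others, homolog_strains)) {
      hits <- translated_noncoding_search(query, annotations[[os]],
                                          E_max = E_max,
                                          index = index_of(os))
      if (nrow(hits) > 0L) {
        trace_strains <- c(trace_strains, os)
        if (os == partner_sid) {
          partner_context <- classify_hit_context(hits[1, ], annotations[[os]])
        }
      }
    }
    evidence <- union(homolog_strains, trace_strains)
    asn <- assign_creation_node(tree, sid, evidence)
    f <- ann$features[ann$features$feature_id == gene_id, ]
    tibble::tibble(gene_id = gene_id, strain = sid,
                   length_aa = nchar(query),
                   most_ancestral_detection = asn$node,
                   homolog_context = if (partner_sid %in% homolog_strains)
                     "annotated_homolog" else partner_context,
                   median_coverage = f$median_coverage)
  }
  report <- dplyr::bind_rows(
    purrr::map_dfr(unique_a, function(g) trace_one(sid_a, sid_b, g)),
    purrr::map_dfr(unique_b, function(g) trace_one(sid_b, sid_a, g))
  )

  prot_a <- annotation_proteins(ann_a); prot_b <- annotation_proteins(ann_b)
  pairs <- reciprocal_best_pairs(prot_a, prot_b)

  novel_ids <- c(paste0(sid_a, ":", unique_a), paste0(sid_b, ":", unique_b))
  nt_of <- function(ann) {
    f <- ann$features[ann$features$kind == "CDS" & !ann$features$pseudogene, ]
    tibble::tibble(strain = ann$strain_id, gene_id = f$feature_id,
                   nt = vapply(f$feature_id, function(g) feature_nt(ann, g),
                               character(1)))
  }
  all_nt <- dplyr::bind_rows(nt_of(ann_a), nt_of(ann_b)) |>
    dplyr::mutate(key = paste0(.data$strain, ":", .data$gene_id))
  novel_nt <- all_nt[all_nt$key %in% novel_ids, ]
  backg_nt <- all_nt[!all_nt$key %in% novel_ids, ]
  signatures <- if (nrow(novel_nt) > 0L && nrow(backg_nt) > 0L) {
    signature_report(novel_nt, backg_nt)
  } else {
    tibble::tibble(metric = character(0), mean_novel = numeric(0),
                   mean_background = numeric(0), p_value = numeric(0))
  }
  list(report = report, unique_a = unique_a, unique_b = unique_b,
       ortholog_pairs = pairs, signatures = signatures, clusters = clusters)
}

#' Run the synthetic-mode analysis pipeline
#'
#' Simulates a genome family on the labeled tree, then runs every analysis
#' stage -- clustering and accumulation curves, the two-strain unique-gene
#' comparison, node-stratified dN/dS of focal ortholog pairs, coverage
#' validation, ncRNA calling/classification/matching, and structural
#' scans -- writing each stage's table as TSV plus a `summary.json` into
#' `out_dir`. Deterministic given the config and seed; every threshold in
#' effect and a hash of the config are recorded in the summary.
#'
#' @param config list (or path to a YAML file) with optional entries:
#'   `seed`, `out_dir`, `focal` (two leaf names), `sim` (overrides for
#'   [sim_params()]), `on_fraction`, `coverage_threshold`, `E_max`,
#'   `min_identity`, `min_coverage`.
#' @return the summary list, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tree <- if (!is.null(config$tree)) read_labeled_tree(config$tree)
          else pandoravirus_tree()
  focal <- config$focal %||% c("p_celtis", "p_quercus")
  on_fraction <- config$on_fraction %||% 0.9
  cov_thr <- config$coverage_threshold %||% 5
  E_max <- config$E_max %||% 1e-3
  min_id <- config$min_identity %||% 0.30
  min_cov <- config$min_coverage %||% 0.50

  simp <- do.call(sim_params, c(config$sim %||% list(),
                                list(seed = seed)))
  sim <- simulate_family(tree, simp)
  anns <- lapply(names(sim$annotations), function(leaf) {
    simulate_coverage(sim$annotations[[leaf]], on_fraction,
                      seed = derive_seed(seed, paste0("cov_", leaf)))
  })
  names(anns) <- names(sim$annotations)

  proteins <- dplyr::bind_rows(lapply(anns, annotation_proteins))
  clusters <- cluster_proteins(proteins, min_id, min_cov)
  curve <- accumulation_curves(clusters)
  readr::write_tsv(clusters$members, file.path(out_dir, "clusters.tsv"))
  readr::write_tsv(tibble::as_tibble(curve), file.path(out_dir, "accumulation.tsv"))

  cmp <- compare_strain_pair(anns[[focal[1]]], anns[[focal[2]]], anns, tree,
                             clusters = clusters, E_max = E_max)
  readr::write_tsv(cmp$report, file.path(out_dir, "unique_genes.tsv"))
  readr::write_tsv(cmp$signatures, file.path(out_dir, "signatures.tsv"))

  # node-stratified dN/dS over focal ortholog pairs (creation node = MRCA of
  # the strains carrying the cluster)
  ests <- list()
  mem <- clusters$members
  strains_of <- split(mem$strain, mem$cluster)
  shared <- mem |>
    dplyr::filter(.data$strain %in% focal) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::filter(dplyr::n_distinct(.data$strain) == 2L, dplyr::n() == 2L) |>
    dplyr::ungroup()
  for (cl in unique(shared$cluster)) {
    rows <- shared[shared$cluster == cl, ]
    ga <- rows$gene_id[rows$strain == focal[1]]
    gb <- rows$gene_id[rows$strain == focal[2]]
    nt_a <- feature_nt(anns[[focal[1]]], ga)
    nt_b <- feature_nt(anns[[focal[2]]], gb)
    aln <- try(codon_align_via_protein(nt_a, nt_b, ga, gb), silent = TRUE)
    if (inherits(aln, "try-error") || aln$n_codons < 30L) next
    est <- dnds_pair(aln)
    est$node <- mrca_label(tree, unique(strains_of[[cl]]))
    ests[[cl]] <- est
  }
  estimates <- dplyr::bind_rows(ests)
  node_summary <- if (nrow(estimates) > 0L) aggregate_by_node(estimates)
                  else tibble::tibble(node = character(0),
                                      mean_omega = numeric(0),
                                      sd_omega = numeric(0), n = integer(0))
  readr::write_tsv(estimates, file.path(out_dir, "dnds_pairs.tsv"))
  readr::write_tsv(tibble::as_tibble(node_summary),
                   file.path(out_dir, "dnds_by_node.tsv"))

  # expression validation + ncRNA calling on the two focal strains
  val <- validate_gene_expression(anns[[focal[1]]]$features, cov_thr)
  tracks <- lapply(focal, function(s) simulate_coverage_track(anns[[s]]))
  calls <- lapply(seq_along(focal), function(k) {
    classify_ncrna(call_ncrna_regions(tracks[[k]], anns[[focal[k]]],
                                      threshold = cov_thr), anns[[focal[k]]])
  })
  matched <- match_ncrna_across_strains(calls[[1]], calls[[2]],
                                        anns[[focal[1]]]$sequence,
                                        anns[[focal[2]]]$sequence)
  readr::write_tsv(dplyr::bind_rows(calls), file.path(out_dir, "ncrna_calls.tsv"))
  readr::write_tsv(matched$pairs, file.path(out_dir, "ncrna_pairs.tsv"))

  summary <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = seed,
    thresholds = list(coverage = cov_thr, E_max = E_max,
                      cluster_identity = min_id, cluster_coverage = min_cov,
                      on_fraction = on_fraction),
    n_strains = length(anns),
    n_clusters = nrow(clusters$presence),
    pan_increment = pan_increment(curve),
    n_unique_focal = length(cmp$unique_a) + length(cmp$unique_b),
    n_expression_kept = nrow(val$kept),
    n_expression_rejected = nrow(val$rejected),
    n_ncrna_calls = vapply(calls, nrow, integer(1)),
    n_ncrna_matched = nrow(matched$pairs),
    dnds_nodes = as.list(setNames(node_summary$mean_omega, node_summary$node))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
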