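# Genome, annotation, tree and table I/O plus translation and coordinate
# services. Internal convention: 0-based half-open intervals; GFF3 1-based
# inclusive coordinates are converted at the boundary only.

FEATURE_KINDS <- c("CDS", "ncRNA", "UTR5", "UTR3")

GFF3_TYPE_FOR_KIND <- c(
  CDS = "CDS", ncRNA = "ncRNA",
  UTR5 = "five_prime_UTR", UTR3 = "three_prime_UTR"
)
KIND_FOR_GFF3_TYPE <- setNames(names(GFF3_TYPE_FOR_KIND), GFF3_TYPE_FOR_KIND)

#' Construct a strain annotation object
#'
#' Bundles one genome sequence with its typed features. Features live in a
#' tibble with 0-based half-open `start`/`end` columns; this is the container
#' every other module consumes.
#'
#' @param strain_id strain identifier.
#' @param sequence genome sequence (single character string, uppercase
#'   A/C/G/T, ambiguity N allowed).
#' @param features tibble with columns `feature_id`, `kind` (one of CDS,
#'   ncRNA, UTR5, UTR3), `start`, `end` (0-based half-open), `strand`
#'   (`+`/`-`); optional `median_coverage` and `pseudogene` columns.
#' @param validate check invariants (intervals inside the genome, unique
#'   feature ids, CDS length divisible by 3).
#' @return an object of class `strain_annotation`.
#' @export
strain_annotation <- function(strain_id, sequence, features = NULL,
                              validate = TRUE) {
  if (is.null(features) || nrow(features) == 0L) {
    features <- tibble::tibble(
      feature_id = character(0), kind = character(0),
      start = integer(0), end = integer(0), strand = character(0),
      median_coverage = numeric(0), pseudogene = logical(0)
    )
  }
  features <- tibble::as_tibble(features)
  if (!"median_coverage" %in% names(features)) {
    features$median_coverage <- NA_real_
  }
  if (!"pseudogene" %in% names(features)) features$pseudogene <- FALSE
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  ann <- structure(
    list(strain_id = strain_id,
         sequence = toupper(sequence),
         features = features,
         length = nchar(sequence)),
    class = "strain_annotation"
  )
  if (validate) validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  f <- ann$features
  if (nrow(f) == 0L) return(invisible(ann))
  stopifnot(all(f$kind %in% FEATURE_KINDS), all(f$strand %in% c("+", "-")))
  if (anyDuplicated(f$feature_id)) {
    stop("duplicate feature ids: ",
         paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  }
  if (any(f$start >= f$end)) stop("feature with start >= end")
  if (any(f$start < 0L) || any(f$end > ann$length)) {
    stop("feature interval outside [0, genome length)")
  }
  bad <- f$kind == "CDS" & (f$end - f$start) %% 3L != 0L & !f$pseudogene
  if (any(bad)) {
    stop("CDS length not a multiple of 3 for: ",
         paste(f$feature_id[bad], collapse = ", "))
  }
  invisible(ann)
}

#' @export
print.strain_annotation <- function(x, ...) {
  cat("<strain_annotation> ", x$strain_id, ": ", format(x$length, big.mark = ","),
      " bp, ", nrow(x$features), " features (",
      sum(x$features$kind == "CDS"), " CDS, ",
      sum(x$features$kind == "ncRNA"), " ncRNA)\n", sep = "")
  invisible(x)
}

#' Read a strain genome and annotation from FASTA + GFF3
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention. A CDS with phase > 0 is trimmed at its
#' coding 5' end so the retained interval starts in frame. A CDS whose
#' length is not a multiple of 3 after phase adjustment is kept but flagged
#' as pseudogenized, with a warning.
#'
#' @param fasta_path FASTA file with exactly one sequence.
#' @param gff_path GFF3 file (`##gff-version 3` pragma expected).
#' @param strain_id optional override; defaults to the FASTA record name.
#' @return a [strain_annotation()] object.
#' @export
read_strain_annotation <- function(fasta_path, gff_path, strain_id = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L) stop("expected exactly one FASTA record, got ", length(dna))
  sid <- strain_id %||% sub("\\s.*$", "", names(dna)[1])
  seq <- as.character(dna[[1]])

  lines <- readLines(gff_path)
  if (!any(grepl("^##gff-version", lines))) {
    stop("GFF3 version pragma missing in ", gff_path)
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) {
    return(strain_annotation(sid, seq))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) stop("malformed GFF3 row (expected 9 columns)")
  m <- do.call(rbind, fields)
  keep <- m[, 3] %in% names(KIND_FOR_GFF3_TYPE)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(strain_annotation(sid, seq))

  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
  start0 <- start1 - 1L; end0 <- end1            # 0-based half-open
  strand <- m[, 7]
  phase <- suppressWarnings(as.integer(m[, 8]))
  phase[is.na(phase)] <- 0L
  kind <- unname(KIND_FOR_GFF3_TYPE[m[, 3]])
  ids <- stringr::str_match(m[, 9], "ID=([^;]+)")[, 2]
  ids[is.na(ids)] <- paste0(sid, "_feat_", which(is.na(ids)))
  cov <- suppressWarnings(
    as.numeric(stringr::str_match(m[, 9], "median_coverage=([^;]+)")[, 2]))

  # phase trimming: drop `phase` bases from the coding 5' end
  is_cds <- kind == "CDS"
  trim <- ifelse(is_cds, phase, 0L)
  start0 <- start0 + ifelse(strand == "+", trim, 0L)
  end0 <- end0 - ifelse(strand == "-", trim, 0L)

  pseudo <- is_cds & (end0 - start0) %% 3L != 0L
  if (any(pseudo)) {
    warning("CDS length not a multiple of 3 after phase adjustment; ",
            "flagged as pseudogenized: ", paste(ids[pseudo], collapse = ", "))
  }
  feats <- tibble::tibble(
    feature_id = ids, kind = kind, start = start0, end = end0,
    strand = strand, median_coverage = cov, pseudogene = pseudo
  )
  strain_annotation(sid, seq, feats)
}

#' Write a strain annotation to FASTA + GFF3
#'
#' Inverse of [read_strain_annotation()]: FASTA wrapped at 60 columns, GFF3
#' with the version pragma, 1-based inclusive coordinates, phase 0 (phase
#' trimming already applied internally), and `median_coverage` carried as an
#' attribute when present.
#'
#' @param ann a [strain_annotation()] object.
#' @param fasta_path,gff_path output paths.
#' @return `ann`, invisibly.
#' @export
write_strain_annotation <- function(ann, fasta_path, gff_path) {
  dna <- Biostrings::DNAStringSet(setNames(ann$sequence, ann$strain_id))
  Biostrings::writeXStringSet(dna, fasta_path, width = 60L)
  f <- ann$features
  con <- file(gff_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", ann$strain_id, ann$length), con)
  if (nrow(f) > 0L) {
    attrs <- paste0("ID=", f$feature_id)
    has_cov <- !is.na(f$median_coverage)
    attrs[has_cov] <- paste0(attrs[has_cov], ";median_coverage=",
                             f$median_coverage[has_cov])
    attrs[f$pseudogene] <- paste0(attrs[f$pseudogene], ";pseudo=true")
    rows <- sprintf("%s\tmicroevo\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                    ann$strain_id,
                    GFF3_TYPE_FOR_KIND[f$kind],
                    f$start + 1L, f$end,
                    f$strand,
                    ifelse(f$kind == "CDS", "0", "."),
                    attrs)
    writeLines(rows, con)
  }
  invisible(ann)
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames. Frame `-k`
#' is the forward translation of the reverse complement offset by `k - 1`
#' bases. Stops render as `*`, ambiguous codons as `X`.
#'
#' @param seq nucleotide sequence (length >= 3).
#' @return tibble with columns `frame` (+1, +2, +3, -1, -2, -3) and
#'   `peptide`.
#' @export
#' @examples
#' six_frame_translate("ATGAAA")
six_frame_translate <- function(seq) {
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  rc <- revcomp(seq)
  fwd <- vapply(1:3, function(k) translate_dna(substr(seq, k, nchar(seq))),
                character(1))
  rev <- vapply(1:3, function(k) translate_dna(substr(rc, k, nchar(rc))),
                character(1))
  tibble::tibble(frame = c(1L, 2L, 3L, -1L, -2L, -3L),
                 peptide = c(fwd, rev))
}

#' Non-coding intervals of a genome
#'
#' Strand-agnostic complement of the union of CDS intervals: the "non-coding
#' moiety" searched for traces of newborn genes. The returned intervals are
#' sorted, disjoint, and together with the CDS union tile `[0, length)`.
#'
#' @param ann a [strain_annotation()] object.
#' @return tibble with `start`, `end` columns (0-based half-open).
#' @export
noncoding_intervals <- function(ann) {
  cds <- ann$features[ann$features$kind == "CDS", ]
  merged <- merge_intervals(cds$start, cds$end)
  n <- nrow(merged)
  if (n == 0L) {
    return(tibble::tibble(start = 0L, end = as.integer(ann$length)))
  }
  starts <- c(0L, merged$end)
  ends <- c(merged$start, as.integer(ann$length))
  keep <- starts < ends
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Read the bundled table of strain-unique protein-coding genes
#'
#' Parses the machine-readable transcription of the published table of 30
#' protein-coding genes unique to p. celtis or p. quercus into one record
#' per gene. Strain is inferred from the id prefix (`pclt_` / `pqer_`),
#' the "most ancestral detection" column becomes an integer node label (NA
#' for no detected trace), and the homolog-context column is mapped onto a
#' closed vocabulary.
#'
#' @param tsv_path path to the TSV; defaults to the bundled fixture.
#' @param expect_rows expected record count (the published table has 30);
#'   set `NULL` to accept any size.
#' @return tibble with columns `gene_id`, `strain`, `length_aa`,
#'   `most_ancestral_detection`, `homolog_context`, `homolog_feature`,
#'   `predicted_dna_binding`, `median_coverage`.
#' @export
read_table1_fixture <- function(tsv_path = system.file(
                                  "extdata", "table1_unique_genes.tsv",
                                  package = "microevo"),
                                expect_rows = 30L) {
  raw <- readr::read_tsv(tsv_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!is.null(expect_rows) && nrow(raw) != expect_rows) {
    stop("fixture has ", nrow(raw), " rows, expected ", expect_rows)
  }
  ctx <- dplyr::case_when(
    raw$homolog_in_partner == "None" ~ "none",
    grepl("^[Ii]ntergenic", raw$homolog_in_partner) ~ "intergenic",
    grepl("^5'UTR", raw$homolog_in_partner) ~ "utr5",
    grepl("^3'UTR", raw$homolog_in_partner) ~ "utr3",
    grepl("^Anti 5'UTR", raw$homolog_in_partner) ~ "antisense_utr5",
    grepl("^Antisense", raw$homolog_in_partner) ~ "antisense_cds",
    grepl("^Alternative frame", raw$homolog_in_partner) ~ "alternative_frame",
    grepl("ncRNA", raw$homolog_in_partner) ~ "ncRNA",
    TRUE ~ NA_character_
  )
  if (anyNA(ctx)) {
    stop("unrecognized homolog context: ",
         paste(unique(raw$homolog_in_partner[is.na(ctx)]), collapse = "; "))
  }
  partner <- stringr::str_extract(raw$homolog_in_partner,
                                  "p(clt|qer)_(cds|ncRNA)_\\d+")
  out <- tibble::tibble(
    gene_id = raw$gene_id,
    strain = dplyr::if_else(startsWith(raw$gene_id, "pclt_"),
                            "p_celtis", "p_quercus"),
    length_aa = as.integer(raw$length_aa),
    most_ancestral_detection = suppressWarnings(as.integer(
      stringr::str_extract(raw$most_ancestral_detection, "\\d+"))),
    homolog_context = ctx,
    homolog_feature = partner,
    predicted_dna_binding = raw$predicted_dna_binding == "Yes",
    median_coverage = as.numeric(gsub(",", "", raw$median_coverage))
  )
  stopifnot(all(out$length_aa > 0L))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
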