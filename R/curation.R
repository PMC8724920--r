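# Curation of IEDB-style assay exports into per-allele 9-mer datasets.

#' Qualitative assay outcome levels, most positive first
#'
#' The ordering used to resolve duplicate (sequence, allele) epitope records:
#' tetramer staining defines the most stringent evidence of HLA restriction,
#' followed by graded functional positivity. `"none"` marks records without a
#' positive qualitative outcome (e.g. background decoys).
#'
#' @format Character vector of six outcome labels, strongest evidence first.
#' @export
OUTCOME_LEVELS <- c("tetramer", "positive-high", "positive-intermediate",
                    "positive", "positive-low", "none")

#' @rdname OUTCOME_LEVELS
#' @format NULL
#' @export
POSITIVE_LEVELS <- OUTCOME_LEVELS[1:5]

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_outcome <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ _]+", "-", x)
  x[x == "" | is.na(x)] <- "none"
  x
}

normalize_allele <- function(x) {
  x <- trimws(as.character(x))
  # unicode asterisk variants occur in some exports
  gsub("∗|✱", "*", x)
}

#' Test whether an allele name is a defined 4-digit HLA protein
#'
#' A "defined restriction" requires both the allele group and the specific
#' protein, e.g. `"HLA-A*02:01"`. Serotype-level names (`"HLA-A2"`) and class
#' II or empty names fail.
#'
#' @param x character vector of allele names.
#' @return logical vector.
#' @export
is_defined_allele <- function(x) {
  grepl("^HLA-[A-Z][A-Z0-9]*\\*[0-9]{2,3}:[0-9]{2,3}$", normalize_allele(x))
}

is_canonical_peptide <- function(x) {
  !is.na(x) & nzchar(x) & !grepl(sprintf("[^%s]", paste(AA_CANONICAL, collapse = "")), x)
}

#' Curation configuration
#'
#' Bundles the record-retention parameters applied when assembling the
#' positive ligand and epitope datasets.
#'
#' @param peptide_length retained peptide length (HLA class I canonical 9).
#' @param min_ligands_per_allele minimum unique ligands for an allele to be
#'   analyzed (default 100).
#' @param ligands_sampled_per_allele ligands drawn per retained allele
#'   (default 100).
#' @param min_assays_per_allele_epitope minimum retained epitope records for
#'   an allele to enter the epitope analysis (default 20).
#' @param epitopes_sampled_per_allele epitopes drawn per retained allele
#'   (default 50).
#' @param excluded_pubmed_ids PubMed IDs whose records are dropped wholesale
#'   (defaults exclude two studies of ligands eluted from transgenic rat
#'   cells).
#' @param rng_seed integer seed governing all per-allele sampling.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(peptide_length = 9L,
                            min_ligands_per_allele = 100L,
                            ligands_sampled_per_allele = 100L,
                            min_assays_per_allele_epitope = 20L,
                            epitopes_sampled_per_allele = 50L,
                            excluded_pubmed_ids = c("28188227", "29393594"),
                            rng_seed = 1L) {
  counts <- c(peptide_length, min_ligands_per_allele, ligands_sampled_per_allele,
              min_assays_per_allele_epitope, epitopes_sampled_per_allele)
  if (any(counts <= 0)) stop("all curation counts must be strictly positive")
  if (ligands_sampled_per_allele > min_ligands_per_allele)
    stop("ligands_sampled_per_allele must not exceed min_ligands_per_allele")
  structure(list(peptide_length = as.integer(peptide_length),
                 min_ligands_per_allele = as.integer(min_ligands_per_allele),
                 ligands_sampled_per_allele = as.integer(ligands_sampled_per_allele),
                 min_assays_per_allele_epitope = as.integer(min_assays_per_allele_epitope),
                 epitopes_sampled_per_allele = as.integer(epitopes_sampled_per_allele),
                 excluded_pubmed_ids = as.character(excluded_pubmed_ids),
                 rng_seed = as.integer(rng_seed)),
            class = "curation_config")
}

#' Column-mapping dialects for assay exports
#'
#' `iedb_dialect()` matches the two-row-header CSV produced by IEDB full
#' exports (group row + field row, flattened as `"Group - Field"`);
#' `plain_dialect()` matches a one-row header with the package's own column
#' names.
#'
#' @return A named list mapping the five required record fields to column
#'   names, plus `header_rows`.
#' @export
iedb_dialect <- function() {
  list(sequence = "Epitope - Description",
       allele = "MHC - Allele Name",
       outcome = "Assay - Qualitative Measure",
       source_protein_id = "Epitope - Parent Protein IRI",
       pubmed_id = "Reference - PMID",
       header_rows = 2L)
}

#' @rdname iedb_dialect
#' @export
plain_dialect <- function() {
  list(sequence = "sequence", allele = "allele", outcome = "outcome",
       source_protein_id = "source_protein_id", pubmed_id = "pubmed_id",
       header_rows = 1L)
}

#' Parse an assay export into peptide records
#'
#' Reads a CSV export of MHC ligand-elution or T-cell assays and returns one
#' record per row with the fields sequence, allele, role, outcome,
#' source_protein_id and pubmed_id. Rows without a parseable peptide sequence
#' (canonical amino-acid letters only) or without any allele name are dropped;
#' the number dropped is attached as attribute `n_dropped` and reported.
#'
#' @param path path to the CSV file.
#' @param role role assigned to every parsed record: `"ligand"` or
#'   `"epitope"`.
#' @param dialect column mapping, e.g. [iedb_dialect()] or [plain_dialect()].
#' @return data.frame of peptide records with attribute `n_dropped`.
#' @export
parse_assay_export <- function(path, role = c("ligand", "epitope"),
                               dialect = plain_dialect()) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("cannot read assay export: ", path)
  header_rows <- as.integer(dialect$header_rows %||% 1L)
  if (header_rows == 2L) {
    raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                           check.names = FALSE)
    if (nrow(raw) < 2L) stop("two-row-header export has fewer than 2 rows: ", path)
    nms <- trimws(paste(trimws(as.character(raw[1L, ])),
                        trimws(as.character(raw[2L, ])), sep = " - "))
    df <- raw[-(1:2), , drop = FALSE]
    names(df) <- nms
    rownames(df) <- NULL
  } else {
    df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  }
  required <- c("sequence", "allele", "outcome", "source_protein_id", "pubmed_id")
  for (field in required) {
    col <- dialect[[field]]
    if (is.null(col)) stop("dialect does not map required field: ", field)
    if (!col %in% names(df))
      stop("mapped column absent from export: '", col, "' (field ", field, ")")
  }
  rec <- data.frame(
    sequence = toupper(trimws(df[[dialect$sequence]])),
    allele = normalize_allele(df[[dialect$allele]]),
    role = role,
    outcome = normalize_outcome(df[[dialect$outcome]]),
    source_protein_id = trimws(df[[dialect$source_protein_id]]),
    pubmed_id = trimws(df[[dialect$pubmed_id]]),
    stringsAsFactors = FALSE
  )
  keep <- is_canonical_peptide(rec$sequence) & !is.na(rec$allele) & nzchar(rec$allele)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message("parse_assay_export: dropped ", n_dropped,
            " row(s) lacking a parseable sequence or allele")
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "n_dropped") <- n_dropped
  rec
}

#' Filter eluted-ligand records to the analyzable per-allele set
#'
#' Applies, in order: removal of excluded PubMed IDs; retention of peptides of
#' the configured length with a defined 4-digit HLA restriction; collapse to a
#' single instance per (sequence, allele) pair (first occurrence kept); and
#' removal of alleles carrying fewer than `cfg$min_ligands_per_allele` unique
#' ligands.
#'
#' @param records data.frame of peptide records with role `"ligand"`.
#' @param cfg a [curation_config()].
#' @return Filtered data.frame; attribute `funnel` records the count after
#'   each stage.
#' @export
filter_ligands <- function(records, cfg = curation_config()) {
  if (NROW(records) == 0L) {
    warning("filter_ligands: empty input")
    return(records[0L, , drop = FALSE])
  }
  stopifnot(all(records$role == "ligand"))
  funnel <- c(input = nrow(records))
  records <- records[!(records$pubmed_id %in% cfg$excluded_pubmed_ids), , drop = FALSE]
  funnel["after_pubmed_exclusion"] <- nrow(records)
  keep <- nchar(records$sequence) == cfg$peptide_length &
    is_defined_allele(records$allele)
  records <- records[keep, , drop = FALSE]
  records <- records[!duplicated(records[, c("sequence", "allele")]), , drop = FALSE]
  funnel["unique_kmers_defined_alleles"] <- nrow(records)
  n_per <- table(records$allele)
  keep_alleles <- names(n_per)[n_per >= cfg$min_ligands_per_allele]
  records <- records[records$allele %in% keep_alleles, , drop = FALSE]
  funnel["after_allele_minimum"] <- nrow(records)
  rownames(records) <- NULL
  attr(records, "funnel") <- funnel
  records
}

#' Draw a fixed-size random sample of peptides per allele
#'
#' Sampling is uniform without replacement from a single RNG stream seeded
#' once; alleles consume the stream in sorted order, so the selection does not
#' depend on input row order.
#'
#' @param table data.frame of peptide records with an `allele` column.
#' @param n peptides to draw per allele.
#' @param seed integer RNG seed.
#' @return data.frame with exactly `n` rows per allele.
#' @export
sample_per_allele <- function(table, n, seed) {
  stopifnot(NROW(table) > 0L, n > 0L)
  counts <- table(table$allele)
  short <- names(counts)[counts < n]
  if (length(short) > 0L)
    stop("allele(s) with fewer than ", n, " peptides: ",
         paste(short, collapse = ", "))
  ord <- order(table$allele, table$sequence)
  table <- table[ord, , drop = FALSE]
  set.seed(seed)
  picked <- unlist(lapply(sort(unique(table$allele)), function(a) {
    idx <- which(table$allele == a)
    sample(idx, n)
  }))
  out <- table[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter T-cell epitope records to the analyzable per-allele set
#'
#' Retains peptides of the configured length with a defined 4-digit HLA
#' restriction and a recognized positive outcome. Duplicate
#' (sequence, allele) pairs — including the same epitope found in several
#' source proteins — collapse to a single record keeping the most positive
#' outcome under the ordering in [OUTCOME_LEVELS] (first occurrence on ties).
#' Alleles with fewer than `cfg$min_assays_per_allele_epitope` retained
#' records are removed.
#'
#' @param records data.frame of peptide records with role `"epitope"`.
#' @param cfg a [curation_config()].
#' @return Filtered data.frame, one row per (sequence, allele).
#' @export
filter_epitopes <- function(records, cfg = curation_config()) {
  if (NROW(records) == 0L) {
    warning("filter_epitopes: empty input")
    return(records[0L, , drop = FALSE])
  }
  stopifnot(all(records$role == "epitope"))
  unknown <- setdiff(unique(records$outcome), POSITIVE_LEVELS)
  if (length(unknown) > 0L) {
    warning("filter_epitopes: rejecting records with unknown outcome label(s): ",
            paste(unknown, collapse = ", "))
    records <- records[records$outcome %in% POSITIVE_LEVELS, , drop = FALSE]
  }
  keep <- nchar(records$sequence) == cfg$peptide_length &
    is_defined_allele(records$allele)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) > 0L) {
    # stable sort by positivity rank; first row per (sequence, allele) wins
    pos_rank <- match(records$outcome, OUTCOME_LEVELS)
    ord <- order(pos_rank)        # stable: preserves input order within a rank
    records <- records[ord, , drop = FALSE]
    records <- records[!duplicated(records[, c("sequence", "allele")]), , drop = FALSE]
  }
  n_per <- table(records$allele)
  keep_alleles <- names(n_per)[n_per >= cfg$min_assays_per_allele_epitope]
  records <- records[records$allele %in% keep_alleles, , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Write curated peptide records to TSV
#'
#' @param records data.frame of peptide records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  cols <- intersect(c("sequence", "allele", "role", "outcome",
                      "source_protein_id", "pubmed_id"), names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
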