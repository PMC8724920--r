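# Decoy background peptides: k-mer windows over source proteins.

#' Background configuration
#'
#' @param k peptide length of the decoy windows (default 9).
#' @param n_background number of decoys to draw (default 10000; with 100
#'   positives per allele this gives the 1:100 design ratio for the ligand
#'   task and 1:200 for a 50-epitope task).
#' @param rng_seed integer seed for the decoy draw.
#' @return list of class `background_config`.
#' @export
background_config <- function(k = 9L, n_background = 10000L, rng_seed = 1L) {
  stopifnot(k > 0L, n_background > 0L)
  structure(list(k = as.integer(k), n_background = as.integer(n_background),
                 rng_seed = as.integer(rng_seed)),
            class = "background_config")
}

#' Extract all unique k-mer windows from protein sequences
#'
#' Slides a length-`k` window over every protein and returns the set of
#' distinct windows. Windows containing non-canonical residues (B, J, O, U,
#' X, Z or other symbols) are discarded; proteins shorter than `k` are
#' skipped with a warning.
#'
#' @param proteins a FASTA file path, a character vector of protein
#'   sequences, or a `Biostrings::AAStringSet`.
#' @param k window length.
#' @return character vector of unique k-mers.
#' @export
extract_kmers <- function(proteins, k = 9L) {
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins))
    proteins <- Biostrings::readAAStringSet(proteins)
  if (inherits(proteins, "AAStringSet")) proteins <- as.character(proteins)
  proteins <- toupper(proteins)
  short <- nchar(proteins) < k
  if (any(short))
    warning(sum(short), " protein(s) shorter than k = ", k, " skipped")
  proteins <- proteins[!short]
  if (length(proteins) == 0L) return(character(0))
  kmers <- unlist(lapply(proteins, function(p) {
    n <- nchar(p)
    substring(p, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  kmers <- unique(kmers)
  kmers[is_canonical_peptide(kmers)]
}

#' Sample the decoy background set
#'
#' Draws `cfg$n_background` peptides uniformly without replacement from the
#' k-mer pool after removing every sequence present in the positive datasets:
#' a peptide found in both pools is retained only as a positive.
#'
#' @param kmers character vector of candidate k-mers.
#' @param cfg a [background_config()].
#' @param exclude character vector of positive peptide sequences (union over
#'   all alleles).
#' @return data.frame of peptide records with role `"background"` and no
#'   allele assignment yet.
#' @export
sample_background <- function(kmers, cfg = background_config(),
                              exclude = character(0)) {
  eligible <- setdiff(unique(kmers), exclude)
  if (length(eligible) < cfg$n_background)
    stop("insufficient eligible k-mers: need ", cfg$n_background, ", have ",
         length(eligible), " (short by ", cfg$n_background - length(eligible), ")")
  eligible <- sort(eligible)    # selection independent of input order
  set.seed(cfg$rng_seed)
  picked <- sample(eligible, cfg$n_background)
  data.frame(sequence = picked, allele = NA_character_, role = "background",
             outcome = "none", source_protein_id = "", pubmed_id = "",
             stringsAsFactors = FALSE)
}

#' Assign the shared background set to every analyzed allele
#'
#' Forms the cross-product: each decoy peptide paired with each allele, so
#' every allele is tested against an identical negative set.
#'
#' @param background data.frame of background peptide records.
#' @param alleles character vector of allele names.
#' @return data.frame with `nrow(background) * length(alleles)` rows.
#' @export
assign_to_alleles <- function(background, alleles) {
  if (NROW(background) == 0L) stop("background is empty")
  if (length(alleles) == 0L) stop("allele list is empty")
  alleles <- as.character(alleles)
  out <- background[rep(seq_len(nrow(background)), times = length(alleles)), ,
                    drop = FALSE]
  out$allele <- rep(alleles, each = nrow(background))
  rownames(out) <- NULL
  out
}
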