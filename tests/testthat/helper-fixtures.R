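# Shared fixture builders. Everything is generated in code at test time.

make_records <- function(sequence, allele, role = "ligand",
                         outcome = if (role == "ligand") "positive" else "positive",
                         source_protein_id = "", pubmed_id = "") {
  data.frame(sequence = sequence, allele = allele, role = role,
             outcome = outcome, source_protein_id = source_protein_id,
             pubmed_id = pubmed_id, stringsAsFactors = FALSE)
}

# n distinct uppercase 9-mers, deterministic given the current RNG state
rand_9mers <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- unique(replicate(ceiling(n * 1.3) + 5,
                          paste(sample(aa, 9, TRUE), collapse = "")))
  while (length(out) < n)
    out <- unique(c(out, paste(sample(aa, 9, TRUE), collapse = "")))
  out[seq_len(n)]
}

# minimal scored data.frame in the artifact schema
make_scored <- function(allele, el_rank, role = "ligand",
                        ic50_nm = el_rank * 100 + 1, ba_rank = el_rank,
                        sequence = NULL) {
  n <- max(length(allele), length(el_rank))
  if (is.null(sequence)) sequence <- rand_9mers(n)
  data.frame(sequence = sequence, allele = allele, ic50_nm = ic50_nm,
             ba_rank = ba_rank, el_score = 1 - el_rank / 100,
             el_rank = el_rank, role = role, stringsAsFactors = FALSE)
}

small_curation_cfg <- function(...) {
  curation_config(min_ligands_per_allele = 10L,
                  ligands_sampled_per_allele = 5L,
                  min_assays_per_allele_epitope = 3L,
                  epitopes_sampled_per_allele = 2L, ...)
}

write_plain_export <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
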