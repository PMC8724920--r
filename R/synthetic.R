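# Synthetic scored datasets with allele-heterogeneous structure.
#
# The generator models prediction scores, not binding chemistry. Its contract
# (checked by tests): background EL ranks uniform on (0,100] per allele;
# ligand EL ranks concentrated near 0 with an allele-specific spread; epitope
# EL ranks stochastically inflated relative to ligands; IC50 positively
# associated with EL rank within every allele; binder fraction of the
# background at 500 nM recovering the allele's repertoire_breadth.

#' Synthetic dataset configuration
#'
#' Defaults mirror the study design the package analyzes: 100 eluted ligands
#' and 50 T-cell epitopes per allele against a shared background of 10,000
#' decoys (1:100 and 1:200 positive:negative ratios).
#'
#' @param n_alleles number of simulated HLA alleles.
#' @param n_ligands_per_allele positives for the ligand task (default 100).
#' @param n_epitopes_per_allele positives for the epitope task (default 50).
#' @param n_background shared decoy count (default 10000).
#' @param rng_seed integer seed; (config, seed) fully determine the dataset.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_alleles = 10L, n_ligands_per_allele = 100L,
                             n_epitopes_per_allele = 50L,
                             n_background = 10000L, rng_seed = 1L) {
  stopifnot(n_alleles >= 1L, n_ligands_per_allele > 0L,
            n_epitopes_per_allele > 0L, n_background > 0L)
  structure(list(n_alleles = as.integer(n_alleles),
                 n_ligands_per_allele = as.integer(n_ligands_per_allele),
                 n_epitopes_per_allele = as.integer(n_epitopes_per_allele),
                 n_background = as.integer(n_background),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

synthetic_allele_names <- function(n) {
  gene <- c("A", "B", "C")[(seq_len(n) - 1L) %% 3L + 1L]
  group <- (seq_len(n) - 1L) %/% 3L + 1L
  sprintf("HLA-%s*%02d:01", gene, group)
}

#' Per-allele generating profiles
#'
#' Builds one [SyntheticProfile][make_profiles] per allele. Repertoire
#' breadths are log-spaced across `breadth_range` (guaranteeing at least an
#' order of magnitude of spread whenever the range does, emulating the
#' observed allele-to-allele variability in repertoire size), and ligand
#' rank scales are log-spaced across `rank_scale_range` with a seeded random
#' pairing to breadths, so repertoire breadth and ligand spread are not
#' artificially collinear.
#'
#' @param cfg a [synthetic_config()].
#' @param breadth_range range of the background binder fraction at 500 nM.
#' @param rank_scale_range range of the ligand EL-rank median (the
#'   allele-specific spread of ligand scores).
#' @param epitope_inflation multiplicative widening of the epitope score law
#'   relative to ligands (>= 1; default 3, making ligand-derived thresholds
#'   under-capture epitopes as observed for real data).
#' @param rank_sdlog log-scale SD of the heavy-tailed ligand rank law.
#' @param ic50_spread log-scale spread of background IC50.
#' @return data.frame, one row per allele, with columns `allele`,
#'   `repertoire_breadth`, `ligand_rank_scale`, `epitope_inflation`,
#'   `rank_sdlog`, `ic50_location`, `ic50_spread`.
#' @export
make_profiles <- function(cfg = synthetic_config(),
                          breadth_range = c(0.002, 0.1),
                          rank_scale_range = c(0.01, 0.5),
                          epitope_inflation = 3,
                          rank_sdlog = 1.5,
                          ic50_spread = 2) {
  stopifnot(inherits(cfg, "synthetic_config"), epitope_inflation >= 1,
            all(breadth_range > 0), all(breadth_range < 1))
  n <- cfg$n_alleles
  logseq <- function(r, n) {
    if (n == 1L) exp(mean(log(r)))
    else exp(seq(log(r[1L]), log(r[2L]), length.out = n))
  }
  breadth <- logseq(breadth_range, n)
  scale <- logseq(rank_scale_range, n)
  set.seed(cfg$rng_seed)
  scale <- scale[sample.int(n)]   # decouple breadth and ligand spread
  data.frame(
    allele = synthetic_allele_names(n),
    repertoire_breadth = breadth,
    ligand_rank_scale = scale,
    epitope_inflation = epitope_inflation,
    rank_sdlog = rank_sdlog,
    ic50_location = log(500) - ic50_spread * stats::qnorm(breadth),
    ic50_spread = ic50_spread,
    stringsAsFactors = FALSE
  )
}

# distinct random 9-mers over the canonical alphabet
random_peptides <- function(n, k = 9L) {
  if (n > 0.01 * 20^k)
    stop("requested ", n, " distinct ", k, "-mers; sequence space too small")
  out <- character(0)
  while (length(out) < n) {
    rows <- ceiling((n - length(out)) * 1.05) + 1L
    m <- matrix(sample(AA_CANONICAL, rows * k, replace = TRUE), ncol = k)
    out <- unique(c(out, apply(m, 1L, paste, collapse = "")))
  }
  out[seq_len(n)]
}

# draw from scale * exp(rank_sdlog * Z), resampling into (0, 100]
rtrunc_rank <- function(n, scale, sdlog) {
  x <- scale * exp(sdlog * stats::rnorm(n))
  while (any(bad <- x > 100 | x <= 0))
    x[bad] <- scale * exp(sdlog * stats::rnorm(sum(bad)))
  x
}

clamp01 <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

# IC50 from a latent percentile via the allele's log-normal background law
ic50_from_latent <- function(u, location, spread) {
  exp(location + spread * stats::qnorm(clamp01(u)))
}

score_rows <- function(sequence, allele, role, outcome, el_rank, latent,
                       profile) {
  data.frame(sequence = sequence, allele = allele,
             ic50_nm = ic50_from_latent(latent, profile$ic50_location,
                                        profile$ic50_spread),
             ba_rank = 100 * clamp01(latent),
             el_score = 1 - el_rank / 100,
             el_rank = el_rank,
             role = role, outcome = outcome,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic scored dataset
#'
#' Produces the three scored tables the pipeline consumes: per-allele eluted
#' ligands, per-allele T-cell epitopes, and one shared background peptide
#' list scored against every allele. Ligand EL ranks follow a heavy-tailed
#' log-normal law with allele-specific median; epitopes draw from the same
#' law widened by `epitope_inflation`; background EL ranks are uniform on
#' (0, 100]. Background IC50 is a monotone map of the EL-rank percentile
#' calibrated so that the fraction at or below 500 nM equals the allele's
#' `repertoire_breadth`; positive IC50 derives from a noise-mixed percentile,
#' so binding-affinity scores separate positives less cleanly than EL ranks.
#'
#' @param profiles a profile table from [make_profiles()].
#' @param cfg the [synthetic_config()] used to build `profiles`.
#' @return list of class `synthetic_dataset` with data.frames `ligands`,
#'   `epitopes`, `background`, plus `profiles` and `config`.
#' @export
generate_dataset <- function(profiles, cfg = synthetic_config()) {
  stopifnot(nrow(profiles) == cfg$n_alleles)
  set.seed(cfg$rng_seed + 1L)
  n_pos <- cfg$n_alleles * (cfg$n_ligands_per_allele +
                              cfg$n_epitopes_per_allele)
  seqs <- random_peptides(n_pos + cfg$n_background)
  bg_seqs <- seqs[seq_len(cfg$n_background)]
  pos_seqs <- seqs[-seq_len(cfg$n_background)]

  lig <- vector("list", cfg$n_alleles)
  epi <- vector("list", cfg$n_alleles)
  bg <- vector("list", cfg$n_alleles)
  offset <- 0L
  mix <- 0.7   # weight of the true percentile in the positives' IC50 latent
  for (i in order(profiles$allele)) {
    p <- profiles[i, ]
    sl <- pos_seqs[offset + seq_len(cfg$n_ligands_per_allele)]
    offset <- offset + cfg$n_ligands_per_allele
    se <- pos_seqs[offset + seq_len(cfg$n_epitopes_per_allele)]
    offset <- offset + cfg$n_epitopes_per_allele

    r_lig <- rtrunc_rank(cfg$n_ligands_per_allele, p$ligand_rank_scale,
                         p$rank_sdlog)
    r_epi <- rtrunc_rank(cfg$n_epitopes_per_allele,
                         p$epitope_inflation * p$ligand_rank_scale,
                         p$rank_sdlog)
    v_lig <- mix * r_lig / 100 +
      (1 - mix) * stats::runif(cfg$n_ligands_per_allele)
    v_epi <- mix * r_epi / 100 +
      (1 - mix) * stats::runif(cfg$n_epitopes_per_allele)
    u_bg <- 1 - stats::runif(cfg$n_background)   # uniform on (0, 1]

    lig[[i]] <- score_rows(sl, p$allele, "ligand", "positive",
                           r_lig, v_lig, p)
    epi[[i]] <- score_rows(se, p$allele, "epitope",
                           sample(POSITIVE_LEVELS,
                                  cfg$n_epitopes_per_allele, replace = TRUE),
                           r_epi, v_epi, p)
    bg[[i]] <- score_rows(bg_seqs, p$allele, "background", "none",
                          100 * u_bg, u_bg, p)
  }
  structure(list(ligands = do.call(rbind, lig),
                 epitopes = do.call(rbind, epi),
                 background = do.call(rbind, bg),
                 profiles = profiles, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic scored dataset:",
      x$config$n_alleles, "alleles;",
      nrow(x$ligands), "ligand,", nrow(x$epitopes), "epitope,",
      nrow(x$background), "background rows\n")
  invisible(x)
}

#' Write a synthetic dataset as a self-describing fixture directory
#'
#' Emits `ligands.tsv`, `epitopes.tsv`, `background.tsv` (artifact-tsv
#' schema), `profiles.tsv`, and `config.json` carrying the generating
#' configuration and seed, so the identical dataset can be regenerated or
#' re-read from disk.
#'
#' @param datasets a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(datasets, dir) {
  stopifnot(inherits(datasets, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("ligands", "epitopes", "background"))
    write_score_table(datasets[[nm]], file.path(dir, paste0(nm, ".tsv")))
  utils::write.table(datasets$profiles, file.path(dir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(datasets$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `ligands`, `epitopes`, `background` data.frames,
#'   `profiles` and `config`.
#' @export
read_fixture <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(synthetic_config, cfg)
  out <- list(
    ligands = read_score_table(file.path(dir, "ligands.tsv")),
    epitopes = read_score_table(file.path(dir, "epitopes.tsv")),
    background = read_score_table(file.path(dir, "background.tsv")),
    profiles = utils::read.delim(file.path(dir, "profiles.tsv"),
                                 stringsAsFactors = FALSE),
    config = cfg
  )
  out
}
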