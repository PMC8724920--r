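# Prediction-score tables: four outputs per peptide-allele pair.
#
# Orientation convention used throughout the package: ic50 (nM), ba_rank and
# el_rank are lower-is-better; el_score is higher-is-better. Percentile ranks
# are carried on the 0-100 scale (a rank of 0.17 means the top 0.17% of a
# random-peptide reference). Only lower-is-better metrics may be thresholded.

SCORE_METRICS <- c(ic50 = "ic50_nm", el_rank = "el_rank", ba_rank = "ba_rank")

#' Resolve a score metric name to its table column
#'
#' Valid thresholding metrics are `"ic50"`, `"el_rank"` and `"ba_rank"`, all
#' with lower-is-positive orientation. The eluted-ligand likelihood score
#' (`el_score`, higher-is-better) is carried in score tables but is not a
#' thresholding metric.
#'
#' @param metric metric name.
#' @return the corresponding column name in scored tables.
#' @export
score_column <- function(metric) {
  metric <- match.arg(metric, names(SCORE_METRICS))
  SCORE_METRICS[[metric]]
}

score_range_ok <- function(df) {
  ok <- rep(TRUE, nrow(df))
  if ("ic50_nm" %in% names(df)) ok <- ok & !is.na(df$ic50_nm) & df$ic50_nm > 0
  if ("ba_rank" %in% names(df))
    ok <- ok & !is.na(df$ba_rank) & df$ba_rank >= 0 & df$ba_rank <= 100
  if ("el_rank" %in% names(df))
    ok <- ok & !is.na(df$el_rank) & df$el_rank >= 0 & df$el_rank <= 100
  if ("el_score" %in% names(df))
    ok <- ok & !is.na(df$el_score) & df$el_score >= 0 & df$el_score <= 1
  ok
}

SCORE_COLS <- c("sequence", "allele", "ic50_nm", "ba_rank", "el_score",
                "el_rank", "role")

#' Read a prediction-score table
#'
#' Two dialects are supported. `"artifact-tsv"` is the package's own schema:
#' a tab-separated file with columns `sequence`, `allele`, `ic50_nm`,
#' `ba_rank`, `el_score`, `el_rank`, `role`. `"netmhcpan-xls"` reads a
#' NetMHCpan-4.0-style tab-delimited export with a two-line header: line one
#' carries each allele name above the first column of its block, line two the
#' per-block column names. Three leading columns (`Pos`, `Peptide`, `ID`) are
#' followed, per allele, by a block `nM`, `BA_Rank`, `Score`, `EL_Rank`
#' holding the combined binding-affinity and eluted-ligand outputs.
#'
#' Rows violating the range invariants (ic50 <= 0, ranks outside 0-100,
#' el_score outside 0-1) are rejected; the count is reported and attached as
#' attribute `n_rejected`.
#'
#' @param path file path.
#' @param format `"artifact-tsv"` or `"netmhcpan-xls"`.
#' @param role role assigned to rows lacking a role column.
#' @return data.frame of scored peptides.
#' @export
read_score_table <- function(path, format = c("artifact-tsv", "netmhcpan-xls"),
                             role = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read score table: ", path)
  if (format == "artifact-tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    missing <- setdiff(setdiff(SCORE_COLS, "role"), names(df))
    if (length(missing) > 0L)
      stop("artifact-tsv is missing column(s): ", paste(missing, collapse = ", "))
    if (!"role" %in% names(df)) df$role <- role %||% NA_character_
  } else {
    lines <- readLines(path)
    if (length(lines) < 3L) stop("netmhcpan-xls file has no data rows: ", path)
    head1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
    head2 <- strsplit(lines[2L], "\t", fixed = TRUE)[[1]]
    body <- utils::read.delim(text = lines[-(1:2)], header = FALSE,
                              stringsAsFactors = FALSE)
    names(body) <- make.unique(head2[seq_len(ncol(body))])
    block_starts <- which(nzchar(head1))
    block_starts <- block_starts[block_starts > 3L]
    if (length(block_starts) == 0L)
      stop("netmhcpan-xls header line 1 names no alleles")
    alleles <- head1[block_starts]
    pieces <- lapply(seq_along(block_starts), function(i) {
      j <- block_starts[i]
      data.frame(sequence = toupper(trimws(body[[2L]])),
                 allele = normalize_allele(alleles[i]),
                 ic50_nm = as.numeric(body[[j]]),
                 ba_rank = as.numeric(body[[j + 1L]]),
                 el_score = as.numeric(body[[j + 2L]]),
                 el_rank = as.numeric(body[[j + 3L]]),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, pieces)
    df$role <- role %||% NA_character_
  }
  ok <- score_range_ok(df)
  n_rejected <- sum(!ok)
  if (n_rejected > 0L)
    message("read_score_table: rejected ", n_rejected,
            " row(s) violating score range invariants")
  df <- df[ok, SCORE_COLS, drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_rejected") <- n_rejected
  df
}

#' Write a score table in the artifact-tsv schema
#'
#' @param scores data.frame of scored peptides.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  missing <- setdiff(setdiff(SCORE_COLS, "role"), names(scores))
  if (length(missing) > 0L)
    stop("score table is missing column(s): ", paste(missing, collapse = ", "))
  if (!"role" %in% names(scores)) scores$role <- NA_character_
  utils::write.table(scores[, SCORE_COLS, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join curated peptides with their prediction scores
#'
#' Exact join on (sequence, allele). Every curated pair must be scored;
#' duplicated score rows with identical values are collapsed silently, while
#' conflicting duplicates raise an error (they signal an upstream prediction
#' mismatch).
#'
#' @param peptides data.frame of curated peptide records.
#' @param scores data.frame of scored peptides.
#' @return data.frame: the peptides annotated with `ic50_nm`, `ba_rank`,
#'   `el_score`, `el_rank`.
#' @export
join_scores <- function(peptides, scores) {
  key <- function(d) paste(d$sequence, d$allele, sep = "\r")
  scores <- scores[!duplicated(scores[, c("sequence", "allele", "ic50_nm",
                                          "ba_rank", "el_score", "el_rank")]), ,
                   drop = FALSE]
  dup <- duplicated(scores[, c("sequence", "allele")])
  if (any(dup)) {
    bad <- unique(paste(scores$sequence[dup], scores$allele[dup]))
    stop("conflicting score rows for pair(s): ",
         paste(utils::head(bad, 10L), collapse = "; "))
  }
  idx <- match(key(peptides), key(scores))
  if (anyNA(idx)) {
    miss <- unique(paste(peptides$sequence[is.na(idx)],
                         peptides$allele[is.na(idx)]))
    stop("missing scores for ", length(miss), " pair(s), e.g.: ",
         paste(utils::head(miss, 10L), collapse = "; "))
  }
  out <- peptides
  for (col in c("ic50_nm", "ba_rank", "el_score", "el_rank"))
    out[[col]] <- scores[[col]][idx]
  out
}
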