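#' Promoter region records
#'
#' Builds a validated table of promoter regions: 13-nt windows centred on
#' the expected -35 or -10 element, wide enough to absorb uncertainty in the
#' exact element position.
#'
#' @param sequence Character vector of DNA sequences.
#' @param role `"minus35"` or `"minus10"` (recycled).
#' @param source_id Identifiers (default `region_1`, `region_2`, ...).
#' @param width Required width; default 13. Set `relaxed = TRUE` to accept
#'   any width >= 6.
#' @param relaxed Allow widths other than 13 (still >= 6).
#' @return A data.frame of class `promoter_regions` with columns
#'   `source_id`, `sequence`, `role`.
#' @export
promoter_regions <- function(sequence, role = "minus35",
                             source_id = paste0("region_", seq_along(sequence)),
                             width = 13L, relaxed = FALSE) {
  role <- rep_len(match.arg(role, c("minus35", "minus10"), several.ok = TRUE),
                  length(sequence))
  sequence <- toupper(as.character(sequence))
  bad <- which(grepl("[^ACGT]", sequence))
  if (length(bad))
    stop(sprintf("region '%s' contains characters outside A/C/G/T",
                 source_id[bad[1]]))
  if (relaxed) {
    short <- which(nchar(sequence) < 6)
    if (length(short))
      stop(sprintf("region '%s' is shorter than 6 nt", source_id[short[1]]))
  } else {
    off <- which(nchar(sequence) != width)
    if (length(off))
      stop(sprintf("region '%s' has length %d, expected %d",
                   source_id[off[1]], nchar(sequence[off[1]]), width))
  }
  structure(
    data.frame(source_id = as.character(source_id), sequence = sequence,
               role = role, stringsAsFactors = FALSE),
    class = c("promoter_regions", "data.frame"))
}

#' Read promoter regions from FASTA or TSV
#'
#' FASTA: one region per record, the record name becomes `source_id` and
#' `role` is taken from the `role` argument. TSV: columns
#' `source_id`, `sequence`, `role` (header optional, detected).
#'
#' @param path File path.
#' @param role Role for FASTA input (minus35 or minus10).
#' @param relaxed Passed to [promoter_regions()].
#' @return A `promoter_regions` data.frame.
#' @export
read_regions <- function(path, role = "minus35", relaxed = FALSE) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    return(promoter_regions(as.character(seqs), role = role,
                            source_id = names(seqs), relaxed = relaxed))
  }
  header <- grepl("source_id", first, fixed = TRUE)
  tab <- utils::read.table(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!header) names(tab) <- c("source_id", "sequence", "role")[seq_along(tab)]
  if (is.null(tab$role)) tab$role <- role
  promoter_regions(tab$sequence, role = tab$role,
                   source_id = tab$source_id, relaxed = relaxed)
}

#' Best-scoring hexamer window within a region
#'
#' Slides a 6-nt window across the region, scores every window against the
#' PWM, and returns the maximum; ties go to the smallest (leftmost) offset.
#' The match carries the exact background p-value of its score.
#'
#' @param pwm A `pwm`.
#' @param region A single region sequence (character) of length >= 6.
#' @param dist Optional precomputed [score_distribution()] for the p-value.
#' @return A one-row data.frame: `hexamer`, `offset` (0-based), `score`,
#'   `p_value`.
#' @examples
#' p <- build_pwm(c("TTGACA", "TTGACG", "TTTACA"))
#' best_match_in_region(p, "CGCTTGACAGGCT")
#' @export
best_match_in_region <- function(pwm, region, dist = NULL) {
  stopifnot(inherits(pwm, "pwm"), length(region) == 1)
  region <- toupper(as.character(region))
  if (nchar(region) < 6)
    stop("region shorter than 6 nt cannot contain a hexamer")
  starts <- seq_len(nchar(region) - 5L)
  windows <- substring(region, starts, starts + 5L)
  scores <- score_hexamer(pwm, windows)
  best <- which.max(scores)  # first maximum: leftmost tie-break
  data.frame(hexamer = windows[best], offset = best - 1L,
             score = scores[best],
             p_value = exact_score_pvalue(pwm, scores[best], dist = dist),
             stringsAsFactors = FALSE)
}

#' Extract significant best-match hexamers from promoter regions
#'
#' For every region, finds the best-matching hexamer window and keeps it iff
#' its exact score p-value is below `alpha` — the dataset-construction step
#' that turns raw 13-nt promoter windows into a curated hexamer set. Input
#' order is preserved.
#'
#' @param regions A `promoter_regions` data.frame (or character vector of
#'   sequences).
#' @param pwm A `pwm` (or a consensus matcher; see [match_consensus()] for
#'   the PWM-free first pass).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return A data.frame with one row per region: `source_id`, `hexamer`,
#'   `offset`, `score`, `p_value`, `kept`; attribute `summary` records
#'   counts in/out, and `hexamers(x)` / `x$hexamer[x$kept]` give the
#'   retained set.
#' @export
extract_significant_hexamers <- function(regions, pwm, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  if (is.character(regions))
    regions <- promoter_regions(regions, relaxed = TRUE)
  dist <- score_distribution(pwm)
  rows <- lapply(seq_len(nrow(regions)), function(i)
    best_match_in_region(pwm, regions$sequence[i], dist = dist))
  out <- do.call(rbind, rows)
  out <- cbind(source_id = regions$source_id, out)
  out$kept <- out$p_value < alpha
  attr(out, "summary") <- c(n_in = nrow(out), n_kept = sum(out$kept))
  out
}

#' Retained hexamers of an extraction result
#' @param extraction Result of [extract_significant_hexamers()].
#' @return Character vector of hexamers that passed the filter.
#' @export
hexamers <- function(extraction) {
  extraction$hexamer[extraction$kept]
}

#' Match a region against a consensus hexamer by mismatch count
#'
#' Bootstrap matcher for the very first pass, before any PWM exists: each
#' window is scored as minus its Hamming distance to the consensus
#' (0 for an exact match, -1 per mismatching position); the best window
#' wins, leftmost on ties.
#'
#' @param region A single DNA sequence of length >= 6.
#' @param consensus A 6-nt consensus, e.g. `"TTGACA"` (-35) or `"TATAAT"`
#'   (-10).
#' @return A one-row data.frame: `hexamer`, `offset`, `score` (0 to -6).
#' @export
match_consensus <- function(region, consensus = "TTGACA") {
  region <- toupper(as.character(region))
  consensus <- check_hexamers(consensus, what = "consensus")
  if (nchar(region) < 6) stop("region shorter than 6 nt")
  cons <- strsplit(consensus, "")[[1]]
  starts <- seq_len(nchar(region) - 5L)
  windows <- substring(region, starts, starts + 5L)
  scores <- vapply(windows, function(w)
    -sum(strsplit(w, "")[[1]] != cons), numeric(1), USE.NAMES = FALSE)
  best <- which.max(scores)
  data.frame(hexamer = windows[best], offset = best - 1L, score = scores[best],
             stringsAsFactors = FALSE)
}

#' Write extraction results as TSV
#'
#' @param extraction Result of [extract_significant_hexamers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extraction <- function(extraction, path) {
  utils::write.table(extraction, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
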