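BASES <- c("A", "C", "G", "T")

#' Nucleotide background model
#'
#' A background distribution over A/C/G/T used for pseudocounts, log-odds
#' weights and score p-values. The default derives from the E. coli genomic
#' GC content of 50.8%: G and C each get gc/2, A and T each get (1 - gc)/2.
#'
#' @param gc GC content in (0, 1). Ignored when `freqs` is supplied.
#' @param freqs Optional named numeric vector of the four base frequencies
#'   (names A, C, G, T); must be positive and sum to 1.
#' @return A named numeric vector of class `nucleotide_background` with
#'   elements A, C, G, T.
#' @examples
#' nucleotide_background()          # GC = 0.508 default
#' nucleotide_background(gc = 0.5)  # uniform
#' @export
nucleotide_background <- function(gc = 0.508, freqs = NULL) {
  if (is.null(freqs)) {
    stopifnot(is.numeric(gc), length(gc) == 1, gc > 0, gc < 1)
    freqs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  } else {
    if (is.null(names(freqs)) || !setequal(names(freqs), BASES))
      stop("background frequencies must be named A, C, G, T")
    freqs <- freqs[BASES]
  }
  if (any(freqs <= 0))
    stop("all background frequencies must be > 0")
  if (abs(sum(freqs) - 1) > 1e-12)
    stop("background frequencies must sum to 1 (tolerance 1e-12)")
  structure(freqs, class = "nucleotide_background")
}

# Validate and uppercase a character vector of hexamers. U and IUPAC
# ambiguity codes are rejected: the model is defined over resolved DNA.
check_hexamers <- function(hexamers, width = 6L, what = "sequence") {
  if (length(hexamers) == 0)
    stop("no sequences")
  hexamers <- toupper(as.character(hexamers))
  bad_len <- which(nchar(hexamers) != width)
  if (length(bad_len))
    stop(sprintf("%s %d ('%s') has length %d, expected %d",
                 what, bad_len[1], hexamers[bad_len[1]],
                 nchar(hexamers[bad_len[1]]), width))
  bad_chr <- which(grepl(sprintf("[^%s]", paste(BASES, collapse = "")), hexamers))
  if (length(bad_chr))
    stop(sprintf("%s %d ('%s') contains characters outside A/C/G/T",
                 what, bad_chr[1], hexamers[bad_chr[1]]))
  hexamers
}

#' Per-position base counts of a hexamer set
#'
#' Tallies, for each of the 6 motif positions, how many input hexamers carry
#' each base there. This count matrix is the raw material for both the
#' log-odds weights ([to_log_odds()]) and the information-content profile
#' ([information_content()]).
#'
#' @param hexamers Character vector of 6-nt sequences over A/C/G/T
#'   (case-insensitive).
#' @return A `count_matrix`: a 6 x 4 matrix (rows = positions, columns =
#'   A, C, G, T) with attribute `n_sequences`.
#' @examples
#' build_count_matrix(c("TTGACA", "TTGACG", "TTTACA"))
#' @export
build_count_matrix <- function(hexamers) {
  hexamers <- check_hexamers(hexamers)
  n <- length(hexamers)
  chars <- matrix(unlist(strsplit(hexamers, "", fixed = TRUE)),
                  nrow = n, byrow = TRUE)
  counts <- vapply(seq_len(6), function(i) {
    tab <- table(factor(chars[, i], levels = BASES))
    as.numeric(tab)
  }, numeric(4))
  counts <- t(counts)
  dimnames(counts) <- list(position = 1:6, base = BASES)
  structure(counts, n_sequences = n, class = c("count_matrix", "matrix", "array"))
}

#' Convert base counts to a log-odds position weight matrix
#'
#' Counts at each position are augmented by a pseudocount apportioned
#' according to the background (so GC-rich backgrounds donate more mass to
#' G/C), normalized to frequencies, and divided by the background before
#' taking logs:
#' \deqn{w_{ib} = \log_{base} \frac{(c_{ib} + s\,q_b)/(n + s)}{q_b}}
#' where \eqn{c_{ib}} is the count of base b at position i, n the number of
#' sequences, s the total pseudocount mass and \eqn{q_b} the background
#' frequency. A base observed exactly at its background rate gets weight 0.
#'
#' @param counts A `count_matrix` from [build_count_matrix()].
#' @param background A [nucleotide_background()]; default GC = 0.508.
#' @param pseudocount_total Total pseudocount mass per position (> 0);
#'   default 1.
#' @param log_base Base of the logarithm; default 2. Recorded on the PWM.
#' @return A `pwm` object: list with `weights` (6 x 4 log-odds matrix),
#'   `background`, `pseudocount_total`, `log_base`, `n_sequences`.
#' @examples
#' cm <- build_count_matrix(c("TTGACA", "TTGACG", "TTTACA"))
#' to_log_odds(cm)
#' @export
to_log_odds <- function(counts, background = nucleotide_background(),
                        pseudocount_total = 1, log_base = 2) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.numeric(pseudocount_total) || pseudocount_total <= 0)
    stop("pseudocount_total must be > 0 (zero counts would give -Inf weights)")
  n <- attr(counts, "n_sequences")
  bg <- unclass(background)
  probs <- sweep(unclass(counts), 2, pseudocount_total * bg, `+`) /
    (n + pseudocount_total)
  weights <- log(sweep(probs, 2, bg, `/`)) / log(log_base)
  attributes(weights) <- list(dim = dim(counts), dimnames = dimnames(counts))
  structure(
    list(weights = weights, background = background,
         pseudocount_total = pseudocount_total, log_base = log_base,
         n_sequences = n),
    class = "pwm")
}

#' Build a PWM from hexamers in one step
#'
#' Convenience wrapper: [build_count_matrix()] then [to_log_odds()].
#'
#' @inheritParams build_count_matrix
#' @inheritParams to_log_odds
#' @return A `pwm` object.
#' @export
build_pwm <- function(hexamers, background = nucleotide_background(),
                      pseudocount_total = 1, log_base = 2) {
  to_log_odds(build_count_matrix(hexamers), background,
              pseudocount_total, log_base)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("Position weight matrix (6 x 4), log base %g, pseudocount %g, n = %d\n",
              x$log_base, x$pseudocount_total, x$n_sequences))
  print(round(x$weights, 4))
  cat(sprintf("Consensus: %s\n", pwm_consensus(x)))
  invisible(x)
}

#' Consensus hexamer of a PWM
#'
#' The highest-weight base at each position.
#'
#' @param pwm A `pwm`.
#' @return A 6-character string.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$weights, 1, which.max)], collapse = "")
}

#' Score a hexamer against a PWM
#'
#' The additive log-odds score: the sum over the six positions of the weight
#' of the observed base.
#'
#' @param pwm A `pwm`.
#' @param hexamer A 6-nt string (or vector of them) over A/C/G/T.
#' @return Numeric score(s), in the PWM's log-odds units.
#' @examples
#' p <- build_pwm(c("TTGACA", "TTGACG", "TTTACA"))
#' score_hexamer(p, "TTGACA")
#' @export
score_hexamer <- function(pwm, hexamer) {
  stopifnot(inherits(pwm, "pwm"))
  hexamer <- check_hexamers(hexamer)
  vapply(hexamer, function(h) {
    idx <- match(strsplit(h, "", fixed = TRUE)[[1]], BASES)
    sum(pwm$weights[cbind(1:6, idx)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Exact null distribution of PWM scores
#'
#' Distribution of the score of a random hexamer whose bases are drawn
#' i.i.d. from the background, computed by position-wise convolution.
#' Support points closer than `bin_width` are merged; the default bin is
#' fine enough that the result coincides with exhaustive enumeration of all
#' 4^6 hexamers.
#'
#' @param pwm A `pwm`.
#' @param background Background to draw from; defaults to the PWM's own.
#' @param bin_width Score-axis merge width for the convolution grid.
#' @return A `score_distribution`: list with sorted `support` and matching
#'   `probabilities` (summing to 1).
#' @export
score_distribution <- function(pwm, background = pwm$background,
                               bin_width = 1e-9) {
  stopifnot(inherits(pwm, "pwm"), bin_width > 0)
  bg <- unclass(background)
  support <- 0
  probs <- 1
  for (i in 1:6) {
    s <- outer(support, pwm$weights[i, ], `+`)
    p <- outer(probs, bg, `*`)
    key <- round(s / bin_width)
    agg <- rowsum(as.vector(p), as.vector(key))
    support <- as.numeric(rownames(agg)) * bin_width
    probs <- agg[, 1]
  }
  ord <- order(support)
  structure(list(support = support[ord], probabilities = probs[ord]),
            class = "score_distribution")
}

#' Exact p-value of a PWM score threshold
#'
#' P(score(X) >= threshold) for a hexamer X drawn i.i.d. from the background
#' at each position — the probability that background sequence matches the
#' motif at least this well. Non-increasing in the threshold; 1 at or below
#' the minimum achievable score.
#'
#' @inheritParams score_distribution
#' @param threshold Finite score threshold (vectorized).
#' @param dist Optionally a precomputed [score_distribution()] (saves
#'   recomputation when scanning many regions against one PWM).
#' @return p-value(s) in (0, 1].
#' @examples
#' p <- build_pwm(c("TTGACA", "TTGACG", "TTTACA"))
#' exact_score_pvalue(p, score_hexamer(p, "TTGACA"))
#' @export
exact_score_pvalue <- function(pwm, threshold, background = pwm$background,
                               bin_width = 1e-9, dist = NULL) {
  stopifnot(all(is.finite(threshold)))
  if (is.null(dist))
    dist <- score_distribution(pwm, background, bin_width)
  # half-bin slack so a score equal to a (merged) support point counts as >=
  vapply(threshold, function(t)
    sum(dist$probabilities[dist$support >= t - bin_width / 2]),
    numeric(1))
}

#' Per-position information content in bits
#'
#' Relative entropy of the observed base frequencies against the background,
#' position by position — the data behind a sequence logo. For a uniform
#' background each value lies in [0, 2] bits; a perfectly conserved column
#' reaches 2 bits.
#'
#' @param counts A `count_matrix`.
#' @param background A [nucleotide_background()]; default GC = 0.508.
#' @param pseudocount_total Pseudocount mass added before computing
#'   frequencies; 0 (the default) uses raw frequencies, under the convention
#'   0 * log(0) = 0.
#' @return Numeric vector of 6 per-position values, in bits.
#' @export
information_content <- function(counts, background = nucleotide_background(),
                                pseudocount_total = 0) {
  stopifnot(inherits(counts, "count_matrix"))
  n <- attr(counts, "n_sequences")
  if (n <= 0) stop("count matrix has no sequences")
  bg <- unclass(background)
  probs <- sweep(unclass(counts), 2, pseudocount_total * bg, `+`) /
    (n + pseudocount_total)
  apply(probs, 1, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / bg[nz]))
  })
}

#' Read hexamers from FASTA or plain text
#'
#' Accepts a FASTA file (one record per hexamer) or a headerless single
#' column / first-column TSV of sequences.
#'
#' @param path File path.
#' @return Character vector of validated, uppercased hexamers.
#' @export
read_hexamers <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    seqs <- as.character(Biostrings::readDNAStringSet(path))
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    seqs <- as.character(tab[[1]])
  }
  check_hexamers(seqs)
}

#' Write / read a PWM as JSON
#'
#' The JSON records the weights (6 x 4, base order ACGT), background,
#' pseudocount and log base, so a persisted PWM scores identically when
#' reloaded.
#'
#' @param pwm A `pwm`.
#' @param path Output (or input) file path.
#' @return `write_pwm` returns `path` invisibly; `read_pwm` returns a `pwm`.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm"))
  obj <- list(
    base_order = paste(BASES, collapse = ""),
    background = as.list(unclass(pwm$background)),
    pseudocount_total = pwm$pseudocount_total,
    log_base = pwm$log_base,
    n_sequences = pwm$n_sequences,
    weights = lapply(1:6, function(i) unname(pwm$weights[i, ]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  if (!file.exists(path))
    stop(sprintf("PWM file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- obj$weights
  if (is.list(w)) w <- do.call(rbind, lapply(w, unlist))
  w <- matrix(as.numeric(w), nrow = 6)
  dimnames(w) <- list(position = 1:6, base = BASES)
  structure(
    list(weights = w,
         background = nucleotide_background(freqs = unlist(obj$background)),
         pseudocount_total = obj$pseudocount_total,
         log_base = obj$log_base,
         n_sequences = obj$n_sequences),
    class = "pwm")
}
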