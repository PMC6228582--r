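# The 18-promoter Anderson library training set: constitutive tet-promoter
# variants with strengths normalized to the strongest member, together with
# the PWM feature scores of their -35 and -10 hexamers under the original
# RegulonDB-derived matrices. Strengths span two orders of magnitude.
ANDERSON <- local({
  txt <- "
id	hex35	hex10	strength	s35	s10
BBa_J23100	TTGACG	TACAGT	1	6.5966	2.398
BBa_J23101	TTTACA	TATTAT	0.7	6.9195	8.089
BBa_J23102	TTGACA	TACTGT	0.86	9.1308	0.402
BBa_J23104	TTGACA	TATTGT	0.72	9.1308	5.025
BBa_J23105	TTTACG	TACTAT	0.24	4.3854	3.465
BBa_J23106	TTTACG	TATAGT	0.47	4.3854	7.022
BBa_J23107	TTTACG	TATTAT	0.36	4.3854	8.089
BBa_J23108	CTGACA	TATAAT	0.51	4.5119	10.086
BBa_J23109	TTTACA	GACTGT	0.04	6.9195	-4.474
BBa_J23110	TTTAGG	TACAAT	0.33	4.3854	5.462
BBa_J23111	TTGACG	TATAGT	0.58	6.5966	7.022
BBa_J23112	CTGATA	GATTAT	0.01	2.5179	3.213
BBa_J23113	CTGATG	GATTAT	0.01	-0.0162	3.213
BBa_J23114	TTTATG	TACAAT	0.1	2.3914	5.462
BBa_J23115	TTTATA	TACAAT	0.15	4.9255	5.462
BBa_J23116	TTGACA	GACTAT	0.16	9.1308	-1.411
BBa_J23117	TTGACA	GATTGT	0.06	9.1308	0.15
BBa_J23118	TTGACG	TATTGT	0.56	6.5966	5.025"
  utils::read.table(text = txt, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
})

#' The Anderson-library training fixture
#'
#' The 18 characterized constitutive promoters used to train the strength
#' regression: each row carries the promoter id, its -35 and -10 hexamers,
#' its strength normalized to the strongest member (BBa_J23100 = 1), and
#' the published PWM feature scores `s35`/`s10` of its hexamers. With these
#' scores a [featurize()] call needs no PWMs, so the regression side of the
#' package is exactly reproducible.
#'
#' @return A `promoter_records` data.frame of 18 rows with extra columns
#'   `s35`, `s10`.
#' @examples
#' fit_ols(featurize(anderson_fixture()))
#' @export
anderson_fixture <- function() {
  rec <- promoter_records(ANDERSON$id, ANDERSON$hex35, ANDERSON$hex10,
                          ANDERSON$strength)
  rec$s35 <- ANDERSON$s35
  rec$s10 <- ANDERSON$s10
  rec
}

#' Per-position base-probability profile for a hexamer motif
#'
#' A 6 x 4 row-stochastic matrix describing how strongly each position of a
#' motif is conserved: the consensus base at position i gets probability
#' `conservation[i]` and the other three bases share the remainder equally.
#' The defaults for the canonical sigma70 elements mimic the conservation
#' gradient seen in curated E. coli promoter collections (ends of each
#' hexamer more conserved than the middle).
#'
#' @param consensus 6-nt consensus; `"TTGACA"` (-35) or `"TATAAT"` (-10)
#'   for the canonical elements.
#' @param conservation Probability of the consensus base at each position,
#'   length 6 (recycled from length 1); each in (0, 1].
#' @return A `motif_profile`: 6 x 4 matrix (columns A, C, G, T) with the
#'   consensus stored as an attribute.
#' @export
motif_profile <- function(consensus = "TTGACA",
                          conservation = c(0.70, 0.78, 0.60, 0.55, 0.52, 0.55)) {
  consensus <- check_hexamers(consensus, what = "consensus")
  conservation <- rep_len(conservation, 6)
  stopifnot(all(conservation > 0), all(conservation <= 1))
  cons <- match(strsplit(consensus, "")[[1]], BASES)
  prof <- matrix((1 - conservation) / 3, nrow = 6, ncol = 4)
  prof[cbind(1:6, cons)] <- conservation
  dimnames(prof) <- list(position = 1:6, base = BASES)
  structure(prof, consensus = consensus,
            class = c("motif_profile", "matrix", "array"))
}

#' Canonical sigma70 motif profiles
#'
#' Ready-made [motif_profile()]s for the -35 (TTGACA) and -10 (TATAAT)
#' elements, with per-position conservation patterned on the familiar
#' sigma70 logos: the TT / TA dinucleotides at the 5' ends and the final
#' -10 T strongly conserved, the middle positions degenerate.
#'
#' @param element `"minus35"` or `"minus10"`.
#' @return A `motif_profile`.
#' @export
sigma70_profile <- function(element = c("minus35", "minus10")) {
  element <- match.arg(element)
  if (element == "minus35")
    motif_profile("TTGACA", c(0.70, 0.78, 0.60, 0.55, 0.52, 0.55))
  else
    motif_profile("TATAAT", c(0.78, 0.76, 0.55, 0.55, 0.52, 0.82))
}

#' Sample hexamers from a motif profile
#'
#' Draws `n` hexamers with each position sampled independently from the
#' profile's base probabilities — a synthetic stand-in for a curated
#' promoter-element collection. Deterministic given the seed.
#'
#' @param profile A `motif_profile`.
#' @param n Number of hexamers.
#' @param seed Integer seed.
#' @return Character vector of `n` hexamers.
#' @examples
#' generate_hexamer_set(sigma70_profile("minus35"), 10, seed = 1)
#' @export
generate_hexamer_set <- function(profile, n, seed) {
  stopifnot(inherits(profile, "motif_profile"), n > 0)
  withr_seed(seed, function() {
    cols <- vapply(1:6, function(i)
      sample(BASES, n, replace = TRUE, prob = profile[i, ]), character(n))
    apply(matrix(cols, nrow = n), 1, paste, collapse = "")
  })
}

#' Embed hexamers in random 13-nt promoter regions
#'
#' Places each hexamer at a random offset inside a `width`-nt window whose
#' remaining bases are drawn from the background — synthetic regions of the
#' kind the extraction step scans.
#'
#' @param hexamers Character vector of hexamers.
#' @param width Region width; default 13.
#' @param background A [nucleotide_background()] for the flanks.
#' @param seed Integer seed.
#' @param role Region role label.
#' @return A `promoter_regions` data.frame; the true offsets are stored in
#'   attribute `true_offset`.
#' @export
generate_regions <- function(hexamers, width = 13L,
                             background = nucleotide_background(),
                             seed = 1, role = "minus35") {
  hexamers <- check_hexamers(hexamers)
  stopifnot(width >= 6)
  n <- length(hexamers)
  out <- withr_seed(seed, function() {
    offs <- sample.int(width - 5L, n, replace = TRUE) - 1L
    seqs <- vapply(seq_len(n), function(i) {
      flank <- sample(BASES, width - 6L, replace = TRUE,
                      prob = unclass(background))
      left <- offs[i]
      paste(c(flank[seq_len(left)], strsplit(hexamers[i], "")[[1]],
              flank[seq_len(width - 6L - left) + left]), collapse = "")
    }, character(1))
    list(seqs = seqs, offs = offs)
  })
  reg <- promoter_regions(out$seqs, role = role, width = width)
  attr(reg, "true_offset") <- out$offs
  reg
}
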