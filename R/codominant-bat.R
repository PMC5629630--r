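## Binomial analysis of three-point gametes (BAT) for codominant triples.
##
## Codominant genotypes expose parent of origin at every locus, so the 27
## three-locus genotypes collapse into 14 complementary zygote-pair classes
## whose expected frequencies are quadratic forms in the sister-pair gamete
## frequencies q1..q4.  Sums of the right classes are perfect squares
## (qi + qj)^2, which makes the inversion closed form.

#' Tally codominant zygote-pair class frequencies
#'
#' Each individual's ordered three-locus genotype over codes \{0,1,2\} is
#' assigned to exactly one of the 14 complementary classes (e.g. genotypes
#' 200 and 211 both count towards P12; 222 towards the uninformative triple
#' heterozygote).  Individuals with a missing call at any of the three
#' markers are dropped.
#'
#' @param x a codominant [genotype_matrix()].
#' @param triple character length 3, ordered marker names.
#' @return Object of class `codominant_class_freqs`: list with `P` (named
#'   relative frequencies over the 14 classes, summing to 1), `n_used`, and
#'   `loci`.
#' @export
tally_zygote_pairs <- function(x, triple) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (x$marker_type != "codominant")
    stop("marker_type must be 'codominant'; use tally_dominant_phenotypes() for dominant data")
  calls <- .triple_calls(x, triple)
  if (nrow(calls) == 0L)
    stop("no individuals with complete calls at triple ",
         paste(triple, collapse = "-"))
  lab <- .codom_class_of[apply(calls, 1L, paste, collapse = "")]
  counts <- table(factor(lab, levels = .codom_classes))
  structure(list(P = stats::setNames(as.numeric(counts) / nrow(calls),
                                     .codom_classes),
                 n_used = nrow(calls), loci = as.character(triple)),
            class = "codominant_class_freqs")
}

#' Closed-form BAT estimation of gamete frequencies from codominant classes
#'
#' Two independent estimates of each pairwise binomial quantity
#' Qij = (qi + qj)^2 are formed -- Q1ij = (Pi + Pij + Pj)/2 from the
#' one-heterozygote classes and Q2ij from the two-heterozygote classes
#' (e.g. Q2_12 = (P1 + P1234 - P34 + P2)/2) -- and combined with weights
#' a_ij = Q1ij/(Q1ij + Q2ij), b_ij = 1 - a_ij (or equal weights).  The four
#' gamete frequencies then follow from sqrt(Qij) = qi + qj and
#' sqrt(Pk/2) = qk.  Negative Q2ij (possible in small samples, since it
#' subtracts a class frequency) clamps to 0 before weighting; when both
#' estimates are 0 the weight is immaterial and set to 1/2; a negative
#' final estimate clamps to 0 and sets the `clamped` attribute.
#'
#' @param classes a [tally_zygote_pairs()] result, or a named numeric vector
#'   over the 14 class labels.
#' @param weight_mode `"proportional"` (the published combination) or
#'   `"equal"`.
#' @return A [gamete_freqs()] vector `q1..q4` with attributes `Qij` (the six
#'   combined binomial quantities) and `clamped`.
#' @export
bat_estimate <- function(classes, weight_mode = c("proportional", "equal")) {
  weight_mode <- match.arg(weight_mode)
  P <- if (inherits(classes, "codominant_class_freqs")) classes$P
       else classes[.codom_classes]
  if (anyNA(P)) stop("class frequency vector must cover all 14 classes")
  loci <- if (inherits(classes, "codominant_class_freqs")) classes$loci
          else c("a", "b", "c")
  P <- as.list(P)

  pair_names <- c("12", "13", "14", "23", "24", "34")
  Q1 <- c(P$P1 + P$P12 + P$P2, P$P1 + P$P13 + P$P3, P$P1 + P$P14 + P$P4,
          P$P2 + P$P23 + P$P3, P$P2 + P$P24 + P$P4, P$P3 + P$P34 + P$P4) / 2
  Q2 <- c(P$P1 + P$P1234 - P$P34 + P$P2, P$P1 + P$P1324 - P$P24 + P$P3,
          P$P1 + P$P1423 - P$P23 + P$P4, P$P2 + P$P1423 - P$P14 + P$P3,
          P$P2 + P$P1324 - P$P13 + P$P4, P$P3 + P$P1234 - P$P12 + P$P4) / 2
  Q2 <- pmax(Q2, 0)                     # (qi+qj)^2 is non-negative
  tot <- Q1 + Q2
  a <- ifelse(tot > 0, Q1 / tot, 0.5)
  if (weight_mode == "equal") a <- rep(0.5, 6L)
  Qij <- stats::setNames(a * Q1 + (1 - a) * Q2, pair_names)

  rP <- sqrt(pmax(c(P$P1, P$P2, P$P3, P$P4), 0) / 2)   # = qk for exact input
  rQ <- sqrt(Qij)                                      # = qi + qj
  q <- c(((rQ["12"] + rQ["13"] + rQ["14"] - (rP[2] + rP[3] + rP[4])) / 3 + rP[1]),
         ((rQ["12"] + rQ["23"] + rQ["24"] - (rP[1] + rP[3] + rP[4])) / 3 + rP[2]),
         ((rQ["13"] + rQ["23"] + rQ["34"] - (rP[1] + rP[2] + rP[4])) / 3 + rP[3]),
         ((rQ["14"] + rQ["24"] + rQ["34"] - (rP[1] + rP[2] + rP[3])) / 3 + rP[4])) / 2
  clamped <- q < 0
  if (any(clamped)) {
    warning("negative gamete-frequency estimate clamped to 0 for class ",
            paste(which(clamped), collapse = ", "))
    q[clamped] <- 0
  }
  out <- gamete_freqs(unname(q), loci)
  attr(out, "Qij") <- Qij
  attr(out, "clamped") <- any(clamped)
  out
}
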