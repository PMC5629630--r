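## Gamete-class conventions used throughout the package
##
## For an ordered locus triple the eight gamete haplotypes form four
## complementary sister pairs, indexed:
##   class 1: 000/111   class 2: 100/011   class 3: 110/001   class 4: 101/010
## (dominant-notation analogues abc/ABC, Abc/aBC, ABc/abC, AbC/aBc).
## Sister gametes are assumed equally frequent, so the four pair frequencies
## q1..q4 satisfy 2(q1+q2+q3+q4) = 1.

#' Gamete sister-pair frequencies for a locus triple
#'
#' @param q numeric length 4, frequencies of the four sister-gamete pairs
#'   (see class conventions in the package docs); each must be >= 0.
#' @param loci character length 3, the ordered marker names the classes
#'   refer to.
#' @return Object of class `gamete_freqs`: numeric vector `q1..q4` with a
#'   `loci` attribute.
#' @export
gamete_freqs <- function(q, loci = c("a", "b", "c")) {
  q <- as.numeric(q)
  stopifnot(length(q) == 4L, length(loci) == 3L)
  if (any(q < 0)) stop("gamete frequencies must be non-negative")
  structure(stats::setNames(q, paste0("q", 1:4)), loci = as.character(loci),
            class = "gamete_freqs")
}

#' Normalize gamete frequencies to sum exactly 0.5
#'
#' Separately estimated sister-pair frequencies need not satisfy the
#' constraint q1+q2+q3+q4 = 0.5; this rescales them so it holds exactly:
#' p_i = q_i / (2 * sum(q)).
#'
#' @param q a [gamete_freqs()] object (or numeric length 4).
#' @param loci ordered marker names; defaults to those carried by `q`.
#' @return Object of class `norm_gamete_freqs`, numeric `p1..p4` summing to
#'   0.5, with a `loci` attribute.
#' @export
normalize_gamete_freqs <- function(q, loci = NULL) {
  if (is.null(loci)) loci <- attr(q, "loci") %||% c("a", "b", "c")
  q <- as.numeric(q)
  stopifnot(length(q) == 4L)
  if (any(q < 0)) stop("gamete frequencies must be non-negative")
  s <- sum(q)
  if (s <= 0) stop("degenerate input: all gamete frequencies are zero")
  structure(stats::setNames(q / (2 * s), paste0("p", 1:4)),
            loci = as.character(loci), class = "norm_gamete_freqs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected dominant phenotype-class frequencies for given gamete frequencies
#'
#' Forward model for a dominant three-locus triple. The seven informative
#' phenotype classes (all-recessive; one dominant locus; two dominant loci)
#' have expectations Q1 = q1^2, Q2 = q3^2 + 2 q1 q3, Q3 = q4^2 + 2 q1 q4,
#' Q4 = q2^2 + 2 q1 q2, and Q5..Q7 = Q2..Q4 + Q with
#' Q = 2(q2 q3 + q2 q4 + q3 q4); Q8 (all three loci dominant) absorbs the
#' remainder.
#'
#' @param q numeric length 4 of sister-pair frequencies summing to 0.5.
#' @return Named numeric vector `Q1..Q8` summing to 1.
#' @export
expected_dominant_freqs <- function(q) {
  q <- as.numeric(q)
  stopifnot(length(q) == 4L)
  Qc <- 2 * (q[2] * q[3] + q[2] * q[4] + q[3] * q[4])
  Q <- numeric(8)
  Q[1] <- q[1]^2
  Q[2] <- q[3]^2 + 2 * q[1] * q[3]
  Q[3] <- q[4]^2 + 2 * q[1] * q[4]
  Q[4] <- q[2]^2 + 2 * q[1] * q[2]
  Q[5:7] <- Q[2:4] + Qc
  Q[8] <- 1 - sum(Q[1:7])
  stats::setNames(Q, paste0("Q", 1:8))
}

## the 14 codominant zygote-pair class labels, in canonical order
.codom_classes <- c("P1", "P2", "P3", "P4",
                    "P12", "P13", "P14", "P23", "P24", "P34",
                    "P1234", "P1324", "P1423", "P222")

## genotype string (digits 0/1/2 per locus) -> complementary class label
.codom_class_of <- c(
  "000" = "P1", "111" = "P1", "100" = "P2", "011" = "P2",
  "110" = "P3", "001" = "P3", "101" = "P4", "010" = "P4",
  "200" = "P12", "211" = "P12", "112" = "P13", "002" = "P13",
  "121" = "P14", "020" = "P14", "021" = "P23", "120" = "P23",
  "102" = "P24", "012" = "P24", "201" = "P34", "210" = "P34",
  "122" = "P1234", "022" = "P1234", "221" = "P1324", "220" = "P1324",
  "212" = "P1423", "202" = "P1423", "222" = "P222")

#' Expected codominant zygote-pair class frequencies
#'
#' Forward model for a codominant triple: the 27 three-locus genotypes
#' collapse into 14 complementary zygote-pair classes with expectations
#' P_i = 2 q_i^2, P_ij = 4 q_i q_j, P_1234 = 4(q1 q2 + q3 q4),
#' P_1324 = 4(q1 q3 + q2 q4), P_1423 = 4(q1 q4 + q2 q3) and
#' P_222 = 2 sum(q^2) for the uninformative triple heterozygote.
#'
#' @inheritParams expected_dominant_freqs
#' @return Named numeric vector over the 14 classes, summing to 1.
#' @export
expected_codominant_freqs <- function(q) {
  q <- as.numeric(q)
  stopifnot(length(q) == 4L)
  P <- c(2 * q^2,
         4 * q[1] * q[2], 4 * q[1] * q[3], 4 * q[1] * q[4],
         4 * q[2] * q[3], 4 * q[2] * q[4], 4 * q[3] * q[4],
         4 * (q[1] * q[2] + q[3] * q[4]),
         4 * (q[1] * q[3] + q[2] * q[4]),
         4 * (q[1] * q[4] + q[2] * q[3]),
         2 * sum(q^2))
  stats::setNames(P, .codom_classes)
}
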