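## From normalized gamete-class frequencies to order, phase, recombination
## fractions, and multi-locus maps.
##
## Geometry of the four sister-pair classes: pick the parental class (largest
## frequency).  Every other class then has exactly one member that differs
## from the parental gamete at exactly one locus, and each of the three loci
## is hit by exactly one class.  The class assigned to the middle locus is
## the double-crossover class (smallest frequency); gametes recombinant
## between loci x and y are precisely the classes assigned to x and to y, so
## r(x, y) = 2 (p_S(x) + p_S(y)).

## 0-side representative haplotypes of the four classes
.class_rep <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(1L, 0L, 1L))

## locus at which class `cl`'s nearest member differs from class `parental`'s
## representative (classes represented up to complementation)
.diff_locus <- function(cl, parental) {
  d <- xor(.class_rep[cl, ], .class_rep[parental, ])
  if (sum(d) == 1L) which(d) else which(!d)
}

## locus -> class map S(l) for a given parental class: S[l] is the class
## whose near member differs from the parental gamete at locus l only
.locus_class_map <- function(parental) {
  S <- integer(3)
  for (cl in setdiff(1:4, parental)) S[.diff_locus(cl, parental)] <- cl
  S
}

#' Infer within-triple locus order and linkage phase
#'
#' The parental class is the most frequent, the double-crossover class the
#' least frequent.  The middle locus is the one locus at which the
#' double-crossover gamete (the member of its sister pair sharing two
#' alleles with the parental gamete) differs from the parental gamete.
#' Phase is coupling when the parental class is class 1 (all recessive /
#' all dominant on one strand); otherwise one locus -- recorded in
#' `repulsion_locus` -- is in repulsion with the outer pair.  Ties in the
#' largest or smallest frequency (within 1e-9) set the `ambiguous` flag.
#'
#' @param p a [normalize_gamete_freqs()] vector (or numeric length 4).
#' @param loci ordered marker names; defaults to those carried by `p`.
#' @return Object of class `triple_result`: list with `loci`,
#'   `parental_class`, `double_co_class`, `middle`, `ordered_loci`, `phase`
#'   (`"coupling"`, `"repulsion"` or `"ambiguous"`), `repulsion_locus`,
#'   `ambiguous`, and `p`.
#' @export
infer_order_phase <- function(p, loci = NULL) {
  if (is.null(loci)) loci <- attr(p, "loci") %||% c("a", "b", "c")
  p <- as.numeric(p)
  stopifnot(length(p) == 4L)
  tol <- 1e-9
  parental <- which.max(p)
  dco <- which.min(p)
  parental_tie <- sum(p >= max(p) - tol) > 1L
  dco_tie <- sum(p <= min(p) + tol) > 1L
  ambiguous <- parental_tie || dco_tie          # order undetermined
  mid <- .diff_locus(dco, parental)
  outer <- setdiff(1:3, mid)
  phase <- if (parental_tie) "ambiguous"
           else if (parental == 1L) "coupling" else "repulsion"
  structure(list(loci = as.character(loci),
                 parental_class = parental,
                 double_co_class = dco,
                 middle = mid,
                 ordered_loci = as.character(loci[c(outer[1], mid, outer[2])]),
                 phase = phase,
                 repulsion_locus =
                   if (parental == 1L || parental_tie) NA_character_
                   else as.character(loci[.diff_locus(1L, parental)]),
                 ambiguous = ambiguous,
                 parental_tie = parental_tie,
                 dco_tie = dco_tie,
                 p = p),
            class = "triple_result")
}

#' @export
print.triple_result <- function(x, ...) {
  cat(sprintf("triple %s: order %s, phase %s (parental class %d, double-CO class %d)\n",
              paste(x$loci, collapse = "-"),
              paste(x$ordered_loci, collapse = "-"),
              x$phase, x$parental_class, x$double_co_class))
  if (!is.null(x$r))
    cat(sprintf("  r(%s,%s) = %.6f   r(%s,%s) = %.6f   r(%s,%s) = %.6f\n",
                x$ordered_loci[1], x$ordered_loci[2], x$r[1],
                x$ordered_loci[2], x$ordered_loci[3], x$r[2],
                x$ordered_loci[1], x$ordered_loci[3], x$r[3]))
  invisible(x)
}

#' Recombination fractions within a triple
#'
#' Fills the three recombination fractions of an inferred triple:
#' r(outer1, mid) = 2(p_S1 + p_D), r(mid, outer2) = 2(p_S2 + p_D), and
#' r(outer1, outer2) = 2(p_S1 + p_S2), where D is the double-crossover
#' class and S1/S2 are the single-crossover classes assigned to the two
#' outer loci.  The outer-pair fraction deliberately excludes the
#' double-crossover class.  The fractions depend only on the parental
#' class (recombinant classes between two loci are the classes assigned to
#' them), so a tied double-crossover class -- e.g. complete linkage, where
#' all three crossover classes are empty -- still yields fractions, with
#' only the within-triple order left undetermined; a tied parental class is
#' refused.
#'
#' @param result an [infer_order_phase()] result.
#' @param p the normalized frequencies the result was inferred from;
#'   defaults to those stored in `result`.
#' @return `result` with fields `r` (named by interval, in ordered-loci
#'   terms) and `pair_r` (data frame `x`, `y`, `r` over the three unordered
#'   locus pairs, in input-order names).
#' @export
triple_recomb_fractions <- function(result, p = NULL) {
  stopifnot(inherits(result, "triple_result"))
  if (result$parental_tie)
    stop("undetermined: tied parental class")
  if (is.null(p)) p <- result$p
  p <- as.numeric(p)
  S <- .locus_class_map(result$parental_class)
  mid <- result$middle
  outer <- setdiff(1:3, mid)
  r_pair <- function(x, y) 2 * (p[S[x]] + p[S[y]])
  result$r <- stats::setNames(
    c(r_pair(outer[1], mid), r_pair(mid, outer[2]), r_pair(outer[1], outer[2])),
    c("outer1_mid", "mid_outer2", "outer1_outer2"))
  pr <- t(utils::combn(3L, 2L))
  result$pair_r <- data.frame(
    x = result$loci[pr[, 1]], y = result$loci[pr[, 2]],
    r = apply(pr, 1L, function(ij) r_pair(ij[1], ij[2])),
    stringsAsFactors = FALSE)
  result
}

#' Chi-square screen of the 1:1:1:1 gamete-class ratio
#'
#' Unlinked triples segregate their four gamete classes equally.  Gamete
#' counts are reconstructed as round(2 * n_used * 2 * p_i) (each F2
#' individual carries two gametes) and tested against equal expectation
#' with 3 degrees of freedom.  A small p-value indicates linkage.
#'
#' @param p a [normalize_gamete_freqs()] vector (or numeric length 4).
#' @param n_used number of individuals the frequencies were tallied from.
#' @return List with `statistic`, `p_value`, and `counts`.
#' @export
linkage_chisq <- function(p, n_used) {
  p <- as.numeric(p)
  stopifnot(length(p) == 4L, n_used > 0)
  counts <- round(2 * n_used * 2 * p)
  expected <- 2 * n_used / 4
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 3, lower.tail = FALSE),
       counts = counts)
}

#' Per-triple gamete-frequency estimation over a genotype matrix
#'
#' Runs the full per-triple pipeline (tally, ELS or BAT estimation,
#' normalization, 1:1:1:1 screen, order/phase inference, recombination
#' fractions) for every requested marker triple.
#'
#' @param x a [genotype_matrix()]; dominant matrices use `method = "els"`,
#'   codominant `method = "bat"`.
#' @param method `"els"` or `"bat"`; defaults to the one matching
#'   `x$marker_type`.
#' @param triples a character matrix / data frame with 3 columns of marker
#'   names, one row per triple; default all combinations.
#' @param config an [els_config()] (ELS only).
#' @param weight_mode BAT combination weights (BAT only).
#' @return A data frame with one row per triple: loci `a`, `b`, `c`, raw
#'   estimates `q1..q4`, normalized `p1..p4`, `n_used`, `chisq`, `p_value`,
#'   `parental_class`, `double_co_class`, `order`, `phase`, `ambiguous`,
#'   and the three pairwise fractions `r_ab`, `r_ac`, `r_bc` (in input
#'   locus order; `NA` when the parental class is tied).  ELS adds `S2`,
#'   `iterations`, `converged`.
#' @export
estimate_triples <- function(x, method = NULL, triples = NULL,
                             config = els_config(),
                             weight_mode = c("proportional", "equal")) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(method))
    method <- if (x$marker_type == "dominant") "els" else "bat"
  method <- match.arg(method, c("els", "bat"))
  if (is.null(triples)) {
    if (length(x$markers) < 3L) stop("need at least 3 markers")
    triples <- t(utils::combn(x$markers, 3L))
  }
  triples <- as.matrix(triples)
  rows <- lapply(seq_len(nrow(triples)), function(i) {
    tri <- as.character(triples[i, ])
    if (method == "els") {
      tal <- tally_dominant_phenotypes(x, tri)
      q <- els_estimate(tal, config)
      extra <- data.frame(S2 = attr(q, "S2"),
                          iterations = attr(q, "iterations"),
                          converged = attr(q, "converged"))
    } else {
      tal <- tally_zygote_pairs(x, tri)
      q <- bat_estimate(tal, weight_mode = weight_mode)
      extra <- NULL
    }
    p <- normalize_gamete_freqs(q, loci = tri)
    chi <- linkage_chisq(p, tal$n_used)
    res <- infer_order_phase(p, loci = tri)
    if (res$parental_tie) {
      r <- rep(NA_real_, 3)
      ord <- NA_character_
    } else {
      res <- triple_recomb_fractions(res, p)
      r <- res$pair_r$r
      ord <- if (res$ambiguous) NA_character_
             else paste(res$ordered_loci, collapse = "-")
    }
    out <- data.frame(a = tri[1], b = tri[2], c = tri[3],
                      q1 = q[1], q2 = q[2], q3 = q[3], q4 = q[4],
                      p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4],
                      n_used = tal$n_used,
                      chisq = chi$statistic, p_value = chi$p_value,
                      parental_class = res$parental_class,
                      double_co_class = res$double_co_class,
                      order = ord, phase = res$phase,
                      ambiguous = res$ambiguous,
                      r_ab = r[1], r_ac = r[2], r_bc = r[3],
                      stringsAsFactors = FALSE)
    if (!is.null(extra)) out <- cbind(out, extra)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average triple-based recombination fractions into pairwise estimates
#'
#' For markers i and j, every other marker k yields one triple-based
#' estimate r_ijk of the recombination fraction between i and j; the
#' pairwise estimate theta_ij is their mean over the included reference
#' loci.  With `filter = "linked"` a reference k is included only when the
#' triple (i, j, k) rejects the 1:1:1:1 ratio at level `alpha`.  Triples
#' whose fractions are undefined (tied parental class, recorded as `NA`)
#' never contribute.  Pairs with no eligible reference are `NA`.
#'
#' @param triples a data frame from [estimate_triples()] (columns `a`, `b`,
#'   `c`, `r_ab`, `r_ac`, `r_bc`, `p_value`, `ambiguous`).
#' @param markers marker names defining the matrix; defaults to all markers
#'   appearing in `triples`.
#' @param filter `"all"` (every reference locus) or `"linked"`.
#' @param alpha screen level for `filter = "linked"`.
#' @param cap_half truncate fractions at 0.5 before averaging (off by
#'   default; estimates above 0.5 are reported as computed).
#' @return Object of class `theta_matrix`: list with symmetric matrices
#'   `theta` and `n_refs` and the `markers` vector.
#' @export
pairwise_theta <- function(triples, markers = NULL,
                           filter = c("all", "linked"), alpha = 0.05,
                           cap_half = FALSE) {
  filter <- match.arg(filter)
  if (is.null(markers))
    markers <- sort(unique(c(triples$a, triples$b, triples$c)))
  m <- length(markers)
  theta <- matrix(NA_real_, m, m, dimnames = list(markers, markers))
  n_refs <- matrix(0L, m, m, dimnames = list(markers, markers))
  acc <- matrix(0, m, m)
  pair_cols <- list(c("a", "b", "r_ab"), c("a", "c", "r_ac"), c("b", "c", "r_bc"))
  for (t_i in seq_len(nrow(triples))) {
    row <- triples[t_i, ]
    if (filter == "linked" && !(row$p_value < alpha)) next
    for (pc in pair_cols) {
      r <- row[[pc[3]]]
      if (is.na(r)) next
      if (cap_half) r <- min(r, 0.5)
      i <- match(row[[pc[1]]], markers); j <- match(row[[pc[2]]], markers)
      if (is.na(i) || is.na(j)) next
      acc[i, j] <- acc[i, j] + r
      n_refs[i, j] <- n_refs[i, j] + 1L
    }
  }
  acc <- acc + t(acc); n_refs <- n_refs + t(n_refs)
  theta[n_refs > 0L] <- acc[n_refs > 0L] / n_refs[n_refs > 0L]
  structure(list(theta = theta, n_refs = n_refs, markers = markers),
            class = "theta_matrix")
}

#' @export
print.theta_matrix <- function(x, digits = 6, ...) {
  cat("pairwise recombination fractions (averaged over reference loci)\n")
  print(round(x$theta, digits))
  invisible(x)
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.permutations(v[-i]), function(p) c(v[i], p)))
  out
}

#' Order loci by exhaustive minimum-SARF search
#'
#' Evaluates every permutation (up to reversal) of the loci and returns the
#' order minimizing the sum of adjacent recombination fractions (SARF).
#' Ties resolve to the lexicographically smallest order.  The returned
#' order is canonical: its first locus name sorts before its last.
#'
#' @param theta a [pairwise_theta()] result (or a symmetric numeric matrix
#'   with marker dimnames).
#' @param loci subset of loci to order; default all.
#' @return Character vector of locus names, with attribute `sarf`.
#' @export
order_map <- function(theta, loci = NULL) {
  tm <- if (inherits(theta, "theta_matrix")) theta$theta else as.matrix(theta)
  if (is.null(loci)) loci <- rownames(tm)
  m <- length(loci)
  if (m < 3L) stop("ordering needs at least 3 loci")
  if (m > 10L) stop("exhaustive search limited to 10 loci")
  sub <- tm[loci, loci, drop = FALSE]
  if (any(is.na(sub[upper.tri(sub)]))) {
    idx <- which(is.na(sub) & upper.tri(sub), arr.ind = TRUE)
    stop("theta undefined for pair(s): ",
         paste(paste(loci[idx[, 1]], loci[idx[, 2]], sep = "-"), collapse = ", "))
  }
  best <- NULL; best_sarf <- Inf; best_key <- NULL
  for (perm in .permutations(seq_len(m))) {
    ord <- loci[perm]
    if (ord[1] > ord[m]) next                       # canonical direction only
    sarf <- sum(sub[cbind(perm[-m], perm[-1])])
    key <- paste(ord, collapse = "\r")
    if (sarf < best_sarf - 1e-12 ||
        (abs(sarf - best_sarf) <= 1e-12 && key < best_key)) {
      best <- ord; best_sarf <- sarf; best_key <- key
    }
  }
  structure(best, sarf = best_sarf)
}
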