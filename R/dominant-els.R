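## Expectation-least-square (ELS) estimation of gamete frequencies from
## dominant three-locus phenotype classes.
##
## The dominant phenotype at a locus hides the heterozygote, so a triple of
## dominant markers shows only 8 phenotype classes.  Seven of them are
## informative; the all-dominant class dissects into every gamete pair and
## carries no information.  ELS inverts the forward model (see
## expected_dominant_freqs) by a one-dimensional +/-delta line search on q1,
## with q2..q4 restored in closed form from combined class frequencies at
## each step.
##
## The complement re-estimates Q#k = Qhat(k+3) - Q need the two-dominant
## excess Q = 2(q2q3 + q2q4 + q3q4).  During iteration Q is tied to the
## current estimates, i.e. the evaluation at a given q1 must satisfy the
## self-consistency Q = g(Q; q1) where g maps an excess value to the excess
## recomputed from the restored q2..q4.  g is non-increasing in Q, so the
## fixed point is found robustly by bisection on g(Q) - Q; S^2 is then a
## pure function of q1, shared by the line search and the grid oracle.

#' ELS tuning parameters
#'
#' @param delta step size of the q1 line search, on the gamete-frequency
#'   scale (default 1e-4; also the resolution of the final estimate).
#' @param tol stopping tolerance on the least-square criterion S^2, a sum
#'   of six squared frequency differences (default 1e-6).  When the input
#'   carries its sample size (a [tally_dominant_phenotypes()] result) the
#'   effective tolerance is raised to the criterion's expected sampling
#'   floor, sum of Qhat_i (1 - Qhat_i) / n over the six fitted classes:
#'   S^2 residuals below that floor are sampling noise, and chasing them
#'   distorts q1, whose direct information sits in Qhat_1 (see the methods
#'   vignette).  Exact inputs are unaffected.
#' @param max_iter iteration cap for the line search.
#' @param weight_mode how the directly observed class frequency and its
#'   complement-based re-estimate are combined: `"equal"` (equal weights;
#'   carries maximum information for F2 class frequencies) or
#'   `"proportional"` (weights proportional to the two estimates).
#' @return A list of class `els_config`.
#' @export
els_config <- function(delta = 1e-4, tol = 1e-6, max_iter = 10000L,
                       weight_mode = c("equal", "proportional")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(delta > 0, tol > 0, max_iter >= 1L)
  structure(list(delta = delta, tol = tol, max_iter = as.integer(max_iter),
                 weight_mode = weight_mode), class = "els_config")
}

## dominant phenotype-state triple (0 recessive / 1 dominant) -> class 1..8
## classes: 1 aabbcc, 2 aabbC_, 3 aaB_cc, 4 A_bbcc, 5 A_B_cc, 6 A_bbC_,
##          7 aaB_C_, 8 A_B_C_
.dom_class_index <- local({
  key <- c("000" = 1L, "001" = 2L, "010" = 3L, "100" = 4L,
           "110" = 5L, "101" = 6L, "011" = 7L, "111" = 8L)
  function(states) key[apply(states, 1L, paste, collapse = "")]
})

#' Tally dominant three-locus phenotype class frequencies
#'
#' Individuals with a missing call at any of the three markers are dropped
#' (per-triple complete-case tally).
#'
#' @param x a dominant [genotype_matrix()].
#' @param triple character length 3, ordered marker names.
#' @return Object of class `dominant_pheno_freqs`: list with `Qhat` (named
#'   relative frequencies `Q1..Q8` summing to 1), `n_used`, and `loci`.
#' @export
tally_dominant_phenotypes <- function(x, triple) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (x$marker_type != "dominant")
    stop("marker_type must be 'dominant'; use tally_zygote_pairs() for codominant data")
  calls <- .triple_calls(x, triple)
  if (nrow(calls) == 0L)
    stop("no individuals with complete calls at triple ",
         paste(triple, collapse = "-"))
  cls <- .dom_class_index(calls)
  counts <- tabulate(cls, nbins = 8L)
  structure(list(Qhat = stats::setNames(counts / nrow(calls), paste0("Q", 1:8)),
                 n_used = nrow(calls), loci = as.character(triple)),
            class = "dominant_pheno_freqs")
}

## weighted combination of Qhat_k and its complement estimate Qsharp_k
## (both vectorized), with the degenerate-sample rules:
##   Qsharp <= 0            -> use Qhat alone
##   Qsharp  > 0, Qhat == 0 -> use Qsharp alone
.combine_q <- function(Qhat_k, Qsharp, weight_mode) {
  n <- max(length(Qhat_k), length(Qsharp))
  Qhat_k <- rep_len(Qhat_k, n); Qsharp <- rep_len(Qsharp, n)
  a <- rep(1, n); b <- rep(1, n)
  if (weight_mode == "proportional") {
    tot <- Qhat_k + Qsharp
    ok <- tot > 0 & Qsharp > 0
    a[ok] <- Qhat_k[ok] / tot[ok]
    b[ok] <- 1 - a[ok]
  }
  neg <- Qsharp <= 0
  a[neg] <- 1; b[neg] <- 0
  alt <- !neg & Qhat_k == 0
  a[alt] <- 0; b[alt] <- 1
  (a * Qhat_k + b * Qsharp) / (a + b)
}

#' Combine observed and complement-derived class frequencies
#'
#' The two-dominant-locus classes re-estimate the one-dominant-locus
#' classes: Q#k = Qhat(k+3) - Q, where Q = 2(q2 q3 + q2 q4 + q3 q4) is
#' supplied either from a model expectation (`E`) or, by default, from the
#' observed-frequency identity Q = (Qhat1 + Qhat5 + Qhat6 + Qhat7 - 0.25)/2
#' (which follows from the forward model and the sum constraint on q).
#' Each Q#k is then averaged with the directly observed Qhat_k under the
#' configured weights, with the small-sample degenerate rules (a=1, b=0
#' when Q#k <= 0; a=0, b=1 when Q#k > 0 and Qhat_k = 0).
#'
#' @param pheno a [tally_dominant_phenotypes()] result, or a named numeric
#'   vector `Q1..Q7`(..`Q8`) of class frequencies.
#' @param config an [els_config()].
#' @param E optional scalar: the expected two-dominant-class excess
#'   2(q2q3+q2q4+q3q4) from a current iterate, replacing the observed
#'   identity.
#' @return List with `Qstar` (combined `Q2*..Q4*`), `Qsharp`, and `Q` (the
#'   excess actually used).
#' @export
complement_and_combine <- function(pheno, config = els_config(), E = NULL) {
  Qhat <- if (inherits(pheno, "dominant_pheno_freqs")) pheno$Qhat else pheno
  Q <- if (is.null(E)) (Qhat[1] + Qhat[5] + Qhat[6] + Qhat[7] - 0.25) / 2 else E
  Qsharp <- unname(Qhat[5:7]) - unname(Q)
  Qstar <- vapply(1:3, function(k)
    .combine_q(unname(Qhat[k + 1]), Qsharp[k], config$weight_mode), numeric(1))
  list(Qstar = stats::setNames(Qstar, c("Q2", "Q3", "Q4")),
       Qsharp = stats::setNames(Qsharp, c("Q2", "Q3", "Q4")),
       Q = unname(Q))
}

## restored q2..q4 at (q1, excess E), vectorized over q1/E of equal length:
## q3 from Q2*, q4 from Q3*, q2 from Q4*; negative radicands clamp to 0 and
## the estimates are confined to [0, 0.5]
.els_restore <- function(q1, Qhat, E, weight_mode) {
  Qs2 <- .combine_q(Qhat[2], Qhat[5] - E, weight_mode)
  Qs3 <- .combine_q(Qhat[3], Qhat[6] - E, weight_mode)
  Qs4 <- .combine_q(Qhat[4], Qhat[7] - E, weight_mode)
  clamp <- function(v) pmin(pmax(v, 0), 0.5)
  list(q2 = clamp(sqrt(pmax(Qs4 + q1^2, 0)) - q1),
       q3 = clamp(sqrt(pmax(Qs2 + q1^2, 0)) - q1),
       q4 = clamp(sqrt(pmax(Qs3 + q1^2, 0)) - q1))
}

## exact self-consistent excess at each q1 (vectorized): bisection on
## g(E) - E, g non-increasing in E, bracket [0, 1.5] (g <= 2*3*(1/2)^2)
.solve_excess <- function(q1, Qhat, weight_mode) {
  g <- function(E) {
    qs <- .els_restore(q1, Qhat, E, weight_mode)
    2 * (qs$q2 * qs$q3 + qs$q2 * qs$q4 + qs$q3 * qs$q4)
  }
  lo <- rep(0, length(q1)); hi <- rep(1.5, length(q1))
  for (i in 1:52) {
    mid <- (lo + hi) / 2
    up <- g(mid) > mid
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

## the ELS objective: S^2(q1) with the excess solved to self-consistency;
## vectorized over q1
.els_objective <- function(q1, Qhat, weight_mode) {
  E <- .solve_excess(q1, Qhat, weight_mode)
  qs <- .els_restore(q1, Qhat, E, weight_mode)
  E2 <- qs$q3^2 + 2 * q1 * qs$q3
  E3 <- qs$q4^2 + 2 * q1 * qs$q4
  E4 <- qs$q2^2 + 2 * q1 * qs$q2
  Qc <- 2 * (qs$q2 * qs$q3 + qs$q2 * qs$q4 + qs$q3 * qs$q4)
  S2 <- (Qhat[2] - E2)^2 + (Qhat[3] - E3)^2 + (Qhat[4] - E4)^2 +
    (Qhat[5] - E2 - Qc)^2 + (Qhat[6] - E3 - Qc)^2 + (Qhat[7] - E4 - Qc)^2
  list(q2 = qs$q2, q3 = qs$q3, q4 = qs$q4, S2 = unname(S2), E = E)
}

.as_Qhat <- function(pheno) {
  Qhat <- if (inherits(pheno, "dominant_pheno_freqs")) unname(pheno$Qhat)
          else unname(as.numeric(pheno))
  if (length(Qhat) == 7L) Qhat <- c(Qhat, 1 - sum(Qhat))
  stopifnot(length(Qhat) == 8L, Qhat[1] >= 0)
  Qhat
}

#' ELS estimation of gamete frequencies from dominant phenotype classes
#'
#' Initializes q1 at sqrt(Q1hat) and walks it in steps of `delta`, keeping
#' the direction while the least-square criterion S^2 falls and reversing
#' when it rises; q2..q4 are restored in closed form at every step from the
#' combined class frequencies (see [complement_and_combine()]), with the
#' complement excess Q = 2(q2q3 + q2q4 + q3q4) solved to self-consistency
#' at each evaluation, so the walk and [els_grid_oracle()] share one
#' well-defined objective.  Stops when S^2 <= `tol`, when neither direction
#' improves S^2 (a local minimum at resolution `delta`), or at `max_iter`.
#'
#' @inheritParams complement_and_combine
#' @return A [gamete_freqs()] vector with attributes `S2` (final criterion,
#'   equal to S^2 recomputed from the returned estimates), `iterations`,
#'   `converged` (FALSE only when `max_iter` was exhausted), `status`
#'   (`"tol"`, `"stalled"` or `"max_iter"`), and `trace` (per-iteration
#'   incumbent and candidate criteria and the acceptance flag).
#' @export
els_estimate <- function(pheno, config = els_config()) {
  Qhat <- .as_Qhat(pheno)
  loci <- if (inherits(pheno, "dominant_pheno_freqs")) pheno$loci
          else c("a", "b", "c")
  delta <- config$delta
  tol <- config$tol
  ## tallied input: raise the tolerance to the expected sampling floor of
  ## S^2 -- residuals below sum Var(Qhat_i) over the fitted classes are
  ## noise, and minimizing into them trades q1 (anchored by Qhat_1 through
  ## the initialization) for spurious fit in classes 2..7
  if (inherits(pheno, "dominant_pheno_freqs") && is.finite(pheno$n_used) &&
      pheno$n_used > 0)
    tol <- max(tol, sum(Qhat[2:7] * (1 - Qhat[2:7])) / pheno$n_used)
  wm <- config$weight_mode
  S2_of <- function(q1) .els_objective(q1, Qhat, wm)$S2

  q1 <- min(max(sqrt(Qhat[1]), 0), 0.5)
  f <- S2_of(q1)
  iter <- 0L
  status <- NA_character_
  path_q <- q1; path_S2 <- f
  if (f <= tol) status <- "tol"

  ## direction choice: the first move tries +delta; a rejected move flips
  ## the direction, and a second rejection from the same point is a local
  ## minimum of S^2 at resolution delta ("stalled")
  dir <- 0L
  if (is.na(status)) {
    up_q <- min(q1 + delta, 0.5)
    if (up_q > q1) {
      iter <- iter + 1L
      if (S2_of(up_q) < f) dir <- 1L
    }
    if (dir == 0L) {
      dn_q <- max(q1 - delta, 0)
      if (dn_q < q1) {
        iter <- iter + 1L
        if (S2_of(dn_q) < f) dir <- -1L
      }
      if (dir == 0L) status <- "stalled"
    }
  }

  ## monotone descent in the chosen direction; the walk can never cross back
  ## past the start (the step behind the incumbent is always uphill), so the
  ## remaining path is a straight ray, evaluated in vectorized chunks with
  ## decisions identical to the one-step-at-a-time search
  chunk <- 256L
  while (is.na(status)) {
    if (iter >= config$max_iter) { status <- "max_iter"; break }
    k <- seq_len(min(chunk, config$max_iter - iter))
    qs <- q1 + dir * delta * k
    qs <- qs[qs > 0 - 1e-15 & qs < 0.5 + 1e-15]
    qs <- unique(pmin(pmax(qs, 0), 0.5))
    qs <- qs[qs != q1]
    if (!length(qs)) { status <- "stalled"; break }      # pinned at boundary
    fs <- S2_of(qs)
    prevf <- c(f, fs[-length(fs)])
    stop_i <- which(fs >= prevf)[1]                      # first rejected step
    take <- if (is.na(stop_i)) seq_along(qs) else seq_len(stop_i - 1L)
    hit <- which(fs[take] <= tol)[1]                     # early exit at tol
    if (!is.na(hit)) take <- take[seq_len(hit)]
    if (length(take)) {
      q1 <- qs[take[length(take)]]
      f <- fs[take[length(take)]]
      path_q <- c(path_q, qs[take]); path_S2 <- c(path_S2, fs[take])
    }
    iter <- iter + if (is.na(stop_i)) length(qs) else stop_i
    if (!is.na(hit) && f <= tol) status <- "tol"
    else if (!is.na(stop_i)) status <- "stalled"         # local minimum
    ## else: chunk exhausted while still descending; continue the ray
  }
  if (status == "max_iter" && f <= tol) status <- "tol"

  fin <- .els_objective(q1, Qhat, wm)
  out <- gamete_freqs(c(q1, fin$q2, fin$q3, fin$q4), loci)
  attr(out, "S2") <- fin$S2
  attr(out, "tol_used") <- tol
  attr(out, "iterations") <- iter
  attr(out, "converged") <- status != "max_iter"
  attr(out, "status") <- status
  attr(out, "trace") <- data.frame(q1 = path_q, S2 = path_S2)
  out
}

#' Exhaustive grid minimizer of the ELS criterion (test oracle)
#'
#' Evaluates the same self-consistent objective S^2(q1) as [els_estimate()]
#' on the grid 0, step, ..., 0.5 and returns the argmin (ties resolve to
#' the smallest q1).  Being an exhaustive scan, it is immune to any defect
#' in the line search and serves as its independent check.
#'
#' @inheritParams complement_and_combine
#' @param step grid spacing (> 0).
#' @return The grid value of q1 minimizing S^2, with attributes `S2` and
#'   `curve` (the full grid of criterion values).
#' @export
els_grid_oracle <- function(pheno, step = 1e-3, config = els_config()) {
  stopifnot(step > 0)
  Qhat <- .as_Qhat(pheno)
  grid <- seq(0, 0.5, by = step)
  obj <- .els_objective(grid, Qhat, config$weight_mode)
  i <- which.min(obj$S2)               # which.min takes the first (smallest q1)
  structure(grid[i], S2 = obj$S2[i],
            curve = data.frame(q1 = grid, S2 = obj$S2))
}
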