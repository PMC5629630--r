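## Textbook two-point EM estimation of the recombination fraction for an F2
## pair of markers, used as the comparison baseline for the three-point
## estimators.
##
## The latent variable is the pair of gametes forming each individual; a
## gamete is parental with probability (1-r)/2 per type and recombinant with
## probability r/2.  The E-step distributes each observed genotype/phenotype
## class over its compatible gamete pairs and accumulates expected
## recombinant-gamete counts; the M-step sets r to expected recombinants
## over 2N.  Codominant pairs have one ambiguous class (the double
## heterozygote); dominant pairs are ambiguous in all but the fully
## recessive class, and in repulsion phase carry very little information --
## the failure mode the three-point estimators exist to fix.

## model structure for one marker pair: the 16 ordered gamete pairs with
## their observable class index and total recombinant-gamete count
.em_structure <- function(marker_type, phase) {
  gam <- expand.grid(sa = 0:1, sb = 0:1)      # parent-of-origin per locus
  rec <- as.integer(gam$sa != gam$sb)
  pr <- expand.grid(g = 1:4, h = 1:4)
  u <- gam[pr$g, ]; v <- gam[pr$h, ]
  if (marker_type == "codominant") {
    ## observed parent labels; repulsion = flipped labelling at the second locus
    flip <- if (phase == "repulsion") c(0L, 1L) else c(0L, 0L)
    digit <- function(a, b) ifelse(a == b, a, 2L)
    ga <- digit(xor(u$sa, flip[1]), xor(v$sa, flip[1]))
    gb <- digit(xor(u$sb, flip[2]), xor(v$sb, flip[2]))
    class_idx <- 3L * ga + gb + 1L              # 9 classes
    n_class <- 9L
  } else {
    ## dominant allele sits on strand d_l; repulsion puts it on opposite
    ## strands at the two loci
    d <- if (phase == "repulsion") c(1L, 0L) else c(1L, 1L)
    pa <- as.integer(u$sa == d[1] | v$sa == d[1])
    pb <- as.integer(u$sb == d[2] | v$sb == d[2])
    class_idx <- 2L * pa + pb + 1L              # 4 phenotype classes
    n_class <- 4L
  }
  list(class_idx = class_idx, rec_tot = rec[pr$g] + rec[pr$h],
       n_rec_gam = rec[pr$g] + rec[pr$h],      # recombinant gametes per pair
       gam_rec = rec, pair = pr, n_class = n_class)
}

.em_fit <- function(counts, struct, r0 = 0.25, tol = 1e-8, max_iter = 1000L) {
  N <- sum(counts)
  r <- r0
  loglik <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    gam <- expand.grid(sa = 0:1, sb = 0:1)
    f <- ifelse(gam$sa == gam$sb, (1 - r) / 2, r / 2)
    w <- f[struct$pair$g] * f[struct$pair$h]
    class_prob <- vapply(seq_len(struct$n_class), function(k)
      sum(w[struct$class_idx == k]), numeric(1))
    exp_rec_class <- vapply(seq_len(struct$n_class), function(k) {
      sel <- struct$class_idx == k
      if (class_prob[k] <= 0) 0 else
        sum(w[sel] * struct$n_rec_gam[sel]) / class_prob[k]
    }, numeric(1))
    ll <- sum(counts[class_prob > 0] * log(class_prob[class_prob > 0]))
    trace <- c(trace, ll)
    ## r is confined to [0, 0.5]: beyond one half the phase models mirror
    ## each other (a parent-label flip maps repulsion at 1-r onto coupling
    ## at r), so phase + r <= 0.5 parametrizes the family uniquely
    r_new <- sum(counts * exp_rec_class) / (2 * N)
    r_new <- min(max(r_new, 1e-9), 0.5)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  list(r = r, loglik = trace[length(trace)], loglik_trace = trace,
       iterations = length(trace), converged = it < max_iter)
}

#' Two-point EM estimation of the recombination fraction
#'
#' @param x a [genotype_matrix()] (dominant or codominant).
#' @param pair character length 2, the marker names.
#' @param phase_mode `"unknown"` (fit both phase models, keep the higher
#'   log-likelihood), `"coupling"`, or `"repulsion"`.
#' @param r0 starting value.
#' @param tol convergence tolerance on |change in r|.
#' @param max_iter EM iteration cap.
#' @return Object of class `em_result`: list with `r_hat` (truncated at
#'   0.5; the untruncated fit is in `r_raw`), `phase`, `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, and `n_used`.
#' @export
em_two_point <- function(x, pair,
                         phase_mode = c("unknown", "coupling", "repulsion"),
                         r0 = 0.25, tol = 1e-8, max_iter = 1000L) {
  phase_mode <- match.arg(phase_mode)
  stopifnot(inherits(x, "genotype_matrix"), length(pair) == 2L)
  calls <- .triple_calls(x, pair)
  if (nrow(calls) == 0L) stop("no individuals with complete calls at pair")
  for (j in 1:2)
    if (length(unique(calls[, j])) < 2L)
      stop("marker '", pair[j], "' is monomorphic in the complete cases")
  if (x$marker_type == "codominant") {
    counts <- tabulate(3L * calls[, 1] + calls[, 2] + 1L, nbins = 9L)
  } else {
    counts <- tabulate(2L * calls[, 1] + calls[, 2] + 1L, nbins = 4L)
  }
  phases <- if (phase_mode == "unknown") c("coupling", "repulsion") else phase_mode
  fits <- lapply(phases, function(ph)
    .em_fit(counts, .em_structure(x$marker_type, ph), r0, tol, max_iter))
  best <- which.max(vapply(fits, `[[`, numeric(1), "loglik"))
  fit <- fits[[best]]
  structure(list(r_hat = min(fit$r, 0.5), r_raw = fit$r,
                 phase = phases[best], loglik = fit$loglik,
                 loglik_trace = fit$loglik_trace,
                 iterations = fit$iterations, converged = fit$converged,
                 n_used = nrow(calls)),
            class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("two-point EM: r_hat = %.4f (%s phase, loglik %.3f, %d iterations%s)\n",
              x$r_hat, x$phase, x$loglik, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
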