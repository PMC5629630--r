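## F2 meiosis simulator under independent crossovers.
##
## Each F2 individual is the union of two independent F1 gametes.  A gamete
## is generated by walking the loci left to right on the parental strand
## pair, switching strand between adjacent loci with the recombination
## probability implied by the interval's map distance (Haldane by default:
## no crossover interference).

#' Haldane map function
#'
#' Converts a map distance in centiMorgans to a recombination probability
#' under independent crossovers: r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM distance in cM.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Specify a linkage map for simulation
#'
#' Adjacent map distances are drawn i.i.d. uniformly from
#' `distance_choices`.  `phase_mode` fixes how parental origin relates to
#' the observable codes at each locus: `"coupling"` puts every marker in the
#' same orientation (for dominant markers, all dominant alleles on the same
#' parental strand); `"unknown"` randomizes the orientation independently
#' per locus, the realistic situation for dominant markers.
#'
#' @param n_loci number of loci (>= 3).
#' @param distance_choices candidate interval distances in cM.
#' @param marker_type `"dominant"` or `"codominant"`.
#' @param phase_mode `"coupling"` or `"unknown"`.
#' @param map_function `"haldane"` (default) or `"morgan"` (identity,
#'   r = d/100; for sensitivity checks only).
#' @param seed optional integer seed.
#' @return Object of class `linkage_map`: list with `loci`, `distances`
#'   (cM), `r` (per-interval recombination fractions), `marker_type`,
#'   `phase` (per-locus orientation bits), `phase_mode`.
#' @export
make_map <- function(n_loci, distance_choices = c(10, 15, 20, 25, 30),
                     marker_type = c("dominant", "codominant"),
                     phase_mode = c("coupling", "unknown"),
                     map_function = c("haldane", "morgan"), seed = NULL) {
  marker_type <- match.arg(marker_type)
  phase_mode <- match.arg(phase_mode)
  map_function <- match.arg(map_function)
  if (n_loci < 3L) stop("a linkage map needs at least 3 loci")
  if (!length(distance_choices)) stop("empty distance choice set")
  if (any(distance_choices <= 0)) stop("map distances must be positive")
  if (!is.null(seed)) set.seed(seed)
  choices <- as.numeric(distance_choices)
  d <- choices[sample.int(length(choices), n_loci - 1L, replace = TRUE)]
  phase <- if (phase_mode == "coupling") rep(0L, n_loci)
           else stats::rbinom(n_loci, 1L, 0.5)
  r <- if (map_function == "haldane") haldane_r(d) else d / 100
  structure(list(loci = paste0("M", seq_len(n_loci)),
                 distances = d, r = r, marker_type = marker_type,
                 phase = phase, phase_mode = phase_mode,
                 map_function = map_function),
            class = "linkage_map")
}

## one batch of N gametes over the map's loci: matrix of parent-of-origin
## bits, strand switching between adjacent loci with probability r
.sim_gametes <- function(n, r_intervals) {
  L <- length(r_intervals) + 1L
  s <- matrix(0L, n, L)
  s[, 1] <- stats::rbinom(n, 1L, 0.5)
  for (l in seq_along(r_intervals))
    s[, l + 1L] <- xor(s[, l], stats::rbinom(n, 1L, r_intervals[l]))
  s
}

#' Simulate an F2 genotype matrix
#'
#' Draws two independent gametes per individual by the strand-walk model
#' and codes the observable genotype per the map's marker type and
#' per-locus orientation.  Codominant loci segregate 1:2:1, dominant loci
#' 3:1.  The hidden truth (the two parent-of-origin strand matrices) is
#' kept in the `"gametes"` attribute for validation.
#'
#' @param map a [make_map()] specification.
#' @param n number of F2 individuals.
#' @param seed optional integer seed.
#' @return A [genotype_matrix()] with attributes `map` and `gametes`.
#' @export
sim_f2 <- function(map, n, seed = NULL) {
  stopifnot(inherits(map, "linkage_map"))
  if (n < 1L) stop("need at least one individual")
  if (!is.null(seed)) set.seed(seed)
  u <- .sim_gametes(n, map$r)
  v <- .sim_gametes(n, map$r)
  out <- .code_strands(u, v, map)
  attr(out, "map") <- map
  attr(out, "gametes") <- list(u, v)
  out
}

## observable codes from the two strand matrices under a map's orientation
.code_strands <- function(u, v, map) {
  L <- length(map$loci)
  ph <- matrix(map$phase, nrow(u), L, byrow = TRUE)
  if (map$marker_type == "codominant") {
    a <- xor(u, ph) + 0L; b <- xor(v, ph) + 0L
    calls <- ifelse(a == b, a, 2L)
  } else {
    ## dominant allele carried by strand (1 - phase bit)
    d <- 1L - ph
    calls <- ((u == d) | (v == d)) + 0L
  }
  genotype_matrix(calls, map$loci, map$marker_type)
}

#' Benchmark three-point and EM estimators on simulated F2 populations
#'
#' For each replicate a fresh map is drawn (random interval distances,
#' fresh per-locus orientations under `phase_mode`), one set of meioses is
#' simulated, and every requested estimator is run on data derived from
#' those same meioses: `"els"` and `"em"` on the dominant coding, `"bat"`
#' on the codominant coding.  Three-point estimators produce the pairwise
#' recombination-fraction matrix by averaging over all reference loci; EM
#' estimates each pair directly (phase resolved by likelihood).  The map is
#' then ordered by [order_map()] and scored against the truth (up to
#' reversal), and the squared error of each adjacent-interval estimate
#' against the replicate's true recombination fraction is recorded.  A
#' replicate on which an estimator fails counts as non-recovery.
#'
#' @param estimators subset of `"els"`, `"bat"`, `"em"`.
#' @param phase_mode `"coupling"` or `"unknown"`.
#' @param em_phase phase model for the EM baseline: `"coupling"` (default)
#'   runs EM blind to phase, the variant whose repulsion-phase failure on
#'   dominant markers motivates three-point analysis; `"unknown"` lets EM
#'   pick the phase per pair by likelihood, a stronger baseline.
#' @param n sample size (F2 individuals per replicate).
#' @param replicates number of replicates.
#' @param n_loci,distance_choices map specification per replicate.
#' @param config an [els_config()] for the ELS runs.
#' @param seed optional integer seed for the whole run.
#' @return List with `summary` (one row per estimator: recovery percentage
#'   and per-interval MSE columns `mse1`..) and `raw` (per replicate and
#'   estimator: recovery flag and squared errors).
#' @export
run_benchmark <- function(estimators = c("els", "em", "bat"),
                          phase_mode = c("coupling", "unknown"),
                          n = 200, replicates = 100, n_loci = 6,
                          distance_choices = c(10, 15, 20, 25, 30),
                          config = els_config(), em_phase = "coupling",
                          seed = NULL) {
  phase_mode <- match.arg(phase_mode)
  estimators <- match.arg(estimators, c("els", "em", "bat"),
                          several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n_int <- n_loci - 1L
  raw <- list()
  for (rep_i in seq_len(replicates)) {
    map <- make_map(n_loci, distance_choices, "dominant", phase_mode)
    u <- .sim_gametes(n, map$r)
    v <- .sim_gametes(n, map$r)
    dom <- .code_strands(u, v, map)
    map_co <- map; map_co$marker_type <- "codominant"
    codom <- if ("bat" %in% estimators) .code_strands(u, v, map_co) else NULL
    truth <- map$loci
    for (est in estimators) {
      rec <- list(replicate = rep_i, estimator = est, recovered = FALSE,
                  sqerr = rep(NA_real_, n_int))
      res <- try({
        theta <- switch(est,
          els = pairwise_theta(estimate_triples(dom, "els", config = config),
                               markers = map$loci),
          bat = pairwise_theta(estimate_triples(codom, "bat"),
                               markers = map$loci),
          em = {
            m <- length(map$loci)
            th <- matrix(NA_real_, m, m,
                         dimnames = list(map$loci, map$loci))
            for (i in 1:(m - 1)) for (j in (i + 1):m) {
              fit <- em_two_point(dom, c(map$loci[i], map$loci[j]), em_phase)
              th[i, j] <- th[j, i] <- fit$r_hat
            }
            structure(list(theta = th,
                           n_refs = matrix(1L, m, m),
                           markers = map$loci), class = "theta_matrix")
          })
        ord <- order_map(theta)
        rec$recovered <- identical(as.character(ord), truth) ||
          identical(rev(as.character(ord)), truth)
        adj <- cbind(map$loci[-n_loci], map$loci[-1])
        rec$sqerr <- (theta$theta[adj] - map$r)^2
        TRUE
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        message("replicate ", rep_i, " (", est, ") failed: ",
                attr(res, "condition")$message)
      raw[[length(raw) + 1L]] <- rec
    }
  }
  raw_df <- do.call(rbind, lapply(raw, function(r)
    data.frame(replicate = r$replicate, estimator = r$estimator,
               recovered = r$recovered,
               t(stats::setNames(r$sqerr, paste0("sqerr", seq_len(n_int)))))))
  summ <- do.call(rbind, lapply(unique(raw_df$estimator), function(est) {
    sub <- raw_df[raw_df$estimator == est, ]
    mse <- colMeans(sub[, paste0("sqerr", seq_len(n_int)), drop = FALSE],
                    na.rm = TRUE)
    cbind(data.frame(estimator = est, phase_mode = phase_mode, n = n,
                     replicates = replicates,
                     recovery_rate = 100 * mean(sub$recovered)),
          t(stats::setNames(mse, paste0("mse", seq_len(n_int)))))
  }))
  rownames(summ) <- NULL
  list(summary = summ, raw = raw_df)
}
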