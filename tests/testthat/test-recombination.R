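test_that("normalization rescales to an exact half", {
  expect_equal(as.numeric(normalize_gamete_freqs(c(0.2, 0.1, 0.1, 0.1))),
               c(0.2, 0.1, 0.1, 0.1))
  expect_equal(as.numeric(normalize_gamete_freqs(c(0.4, 0.2, 0.2, 0.2))),
               c(0.2, 0.1, 0.1, 0.1))
  expect_equal(as.numeric(normalize_gamete_freqs(c(0.3, 0.05, 0.1, 0.05))),
               c(0.3, 0.05, 0.1, 0.05))
  expect_equal(sum(normalize_gamete_freqs(runif(4))), 0.5)
  expect_error(normalize_gamete_freqs(c(0, 0, 0, 0)), "degenerate")
})

test_that("order and phase follow the parental and double-crossover classes", {
  # mouse triple 1-2-3: parental class 1 (abc), double-CO class 2 (Abc),
  # so locus 1 is in the middle: order 2-1-3, coupling
  p <- normalize_gamete_freqs(c(0.208668, 0.086162, 0.094698, 0.110472),
                              loci = c("1", "2", "3"))
  res <- infer_order_phase(p)
  expect_equal(res$parental_class, 1L)
  expect_equal(res$double_co_class, 2L)
  expect_equal(res$ordered_loci, c("2", "1", "3"))
  expect_identical(res$phase, "coupling")
  expect_false(res$ambiguous)

  # parental class 2 (Abc/aBC): locus a carries the repulsion-phase allele;
  # double-CO class 1 differs from Abc at locus a, so a is the middle
  res <- infer_order_phase(c(0.05, 0.2, 0.125, 0.124), c("a", "b", "c"))
  expect_equal(res$parental_class, 2L)
  expect_equal(res$double_co_class, 1L)
  expect_equal(res$ordered_loci, c("b", "a", "c"))
  expect_identical(res$phase, "repulsion")
  expect_identical(res$repulsion_locus, "a")

  # exact ties are flagged, and fraction computation refuses them
  res <- infer_order_phase(rep(0.125, 4), c("a", "b", "c"))
  expect_true(res$ambiguous)
  expect_true(res$parental_tie)
  expect_identical(res$phase, "ambiguous")
  expect_error(triple_recomb_fractions(res), "undetermined")
})

test_that("triple fractions recover the true two-interval model exactly", {
  # under independent crossovers with parental haplotype h and middle locus m,
  # class frequencies are products of interval recombination indicators; the
  # role rule must return the interval fractions exactly, for every phase
  set.seed(121)
  ords <- rbind(c(1, 2, 3), c(2, 1, 3), c(1, 3, 2))
  for (i in 1:25) {
    r1 <- runif(1, 0.02, 0.45); r2 <- runif(1, 0.02, 0.45)
    h <- sample(0:1, 3, replace = TRUE)          # parental haplotype
    ord <- ords[sample(3, 1), ]                  # ord[2] is the middle locus
    pr <- c(1 - r1, r1)                          # switch between ord1, ord2
    ps <- c(1 - r2, r2)                          # switch between ord2, ord3
    p <- numeric(4)
    for (s1 in 0:1) for (s2 in 0:1) {
      g <- h
      if (s1 == 1) g[ord[2]] <- 1 - g[ord[2]]    # recombinant in interval 1
      if (s2 == 1) g[ord[3]] <- 1 - g[ord[3]]
      if (s1 == 1) g[ord[3]] <- 1 - g[ord[3]]    # switch persists downstream
      p[hap_class(g)] <- pr[s1 + 1] * ps[s2 + 1] / 2
    }
    res <- infer_order_phase(p, c("a", "b", "c"))
    expect_equal(res$middle, ord[2])
    expect_equal(res$parental_class, hap_class(h))
    res <- triple_recomb_fractions(res, p)
    r_named <- res$pair_r
    key <- function(x, y) which((r_named$x == x & r_named$y == y) |
                                (r_named$x == y & r_named$y == x))
    l <- c("a", "b", "c")
    expect_equal(r_named$r[key(l[ord[1]], l[ord[2]])], r1, tolerance = 1e-12)
    expect_equal(r_named$r[key(l[ord[2]], l[ord[3]])], r2, tolerance = 1e-12)
    expect_equal(r_named$r[key(l[ord[1]], l[ord[3]])],
                 r1 * (1 - r2) + (1 - r1) * r2, tolerance = 1e-12)
    # complete linkage degenerates to zero everywhere
  }
  res <- triple_recomb_fractions(infer_order_phase(c(0.5, 0, 0, 0)))
  expect_equal(unname(res$r), c(0, 0, 0))
})

test_that("mouse triples reproduce the published fractions and averages", {
  fx <- mouse_dominant_triples()
  r_tab <- lapply(seq_len(nrow(fx)), function(i) {
    p <- normalize_gamete_freqs(as.numeric(fx[i, paste0("p", 1:4)]),
                                loci = c(fx$a[i], fx$b[i], fx$c[i]))
    triple_recomb_fractions(infer_order_phase(p))
  })
  # row sums of the fixture are pre-normalized to 0.5 within a thousandth
  expect_true(all(abs(rowSums(fx[, paste0("p", 1:4)]) - 0.5) < 1e-3))
  get_r <- function(k, x, y) {
    pr <- r_tab[[k]]$pair_r
    pr$r[(pr$x == x & pr$y == y) | (pr$x == y & pr$y == x)]
  }
  # triple-wise fractions, to the published five decimal places (the
  # published table truncates, so compare absolutely at 1e-5)
  checks <- list(
    list(1, "2", "1", 0.39326), list(1, "1", "3", 0.36172),
    list(1, "2", "3", 0.41034), list(2, "2", "1", 0.38106),
    list(2, "1", "5", 0.37834), list(2, "2", "5", 0.43669),
    list(3, "3", "1", 0.33707), list(3, "1", "5", 0.37631),
    list(3, "3", "5", 0.45024), list(4, "3", "2", 0.37067),
    list(4, "2", "5", 0.39575), list(4, "3", "5", 0.42332))
  for (ck in checks)
    expect_lt(abs(get_r(ck[[1]], ck[[2]], ck[[3]]) - ck[[4]]), 1e-5)
})

test_that("chi-square screen matches direct arithmetic", {
  chi <- linkage_chisq(rep(0.125, 4), 200)
  expect_equal(chi$statistic, 0)
  expect_equal(chi$p_value, 1)

  chi <- linkage_chisq(c(0.25, 0.25, 0, 0), 100)
  expect_equal(chi$statistic, 200)        # counts (100,100,0,0) against 50
  expect_lt(chi$p_value, 1e-3)

  p <- c(0.15, 0.10, 0.125, 0.125); n <- 200
  counts <- round(2 * n * 2 * p)
  expect_equal(linkage_chisq(p, n)$statistic, sum((counts - 100)^2 / 100))
})

test_that("reference-locus averaging and filters behave as specified", {
  tri <- data.frame(a = c("1", "1"), b = c("2", "2"), c = c("3", "5"),
                    r_ab = c(0.393268, 0.38106), r_ac = c(0.3, 0.31),
                    r_bc = c(0.41, 0.42), p_value = c(0.001, 0.001),
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  th <- pairwise_theta(tri)
  expect_equal(th$theta["1", "2"], 0.387164)
  expect_equal(th$n_refs["1", "2"], 2L)
  expect_true(isSymmetric(th$theta))
  # identical estimates average to themselves
  tri2 <- tri; tri2$r_ab <- 0.25
  expect_equal(pairwise_theta(tri2)$theta["1", "2"], 0.25)
  # linked-only screening drops unlinked reference triples
  tri3 <- tri; tri3$p_value[2] <- 0.5
  th3 <- pairwise_theta(tri3, filter = "linked", alpha = 0.05)
  expect_equal(th3$theta["1", "2"], 0.393268)
  expect_equal(th3$n_refs["1", "2"], 1L)
  # no eligible reference: undefined, not 0.5
  tri4 <- tri; tri4$p_value <- 0.5
  expect_true(all(is.na(pairwise_theta(tri4, filter = "linked")$theta)))
  # triples with a tied parental class (all fractions NA) never contribute
  tri5 <- tri
  tri5$ambiguous[2] <- TRUE
  tri5[2, c("r_ab", "r_ac", "r_bc")] <- NA
  expect_equal(pairwise_theta(tri5)$n_refs["1", "2"], 1L)
})

test_that("exhaustive SARF ordering finds the true line", {
  th <- matrix(NA, 3, 3, dimnames = list(c("1", "2", "3"), c("1", "2", "3")))
  th["1", "2"] <- th["2", "1"] <- 0.387
  th["1", "3"] <- th["3", "1"] <- 0.349
  th["2", "3"] <- th["3", "2"] <- 0.391
  ord <- order_map(th)
  expect_equal(as.character(ord), c("2", "1", "3"))
  expect_equal(attr(ord, "sarf"), 0.387 + 0.349)

  # four equidistant loci on a line with Haldane-consistent pairwise theta
  loci <- paste0("L", 1:4)
  pos <- c(0, 20, 40, 60)
  th4 <- outer(pos, pos, function(a, b) haldane_r(abs(a - b)))
  dimnames(th4) <- list(loci, loci); diag(th4) <- NA
  expect_equal(as.character(order_map(th4)), loci)
  # reversal invariance: permuting to the reversed truth gives the same output
  rev_idx <- 4:1
  th4r <- th4[rev_idx, rev_idx]
  expect_equal(as.character(order_map(th4r)), loci)

  expect_error(order_map(th4[1:2, 1:2]), "at least 3")
  th_na <- th4; th_na["L1", "L3"] <- th_na["L3", "L1"] <- NA
  expect_error(order_map(th_na), "L1-L3")
})

test_that("the per-triple driver ties the pipeline together", {
  set.seed(131)
  map <- make_map(4, c(15, 25), "dominant", "coupling")
  gm <- sim_f2(map, 400)
  tri <- estimate_triples(gm, "els")
  expect_equal(nrow(tri), choose(4, 3))
  expect_true(all(abs(rowSums(tri[, paste0("p", 1:4)]) - 0.5) < 1e-9))
  expect_true(all(tri$chisq >= 0))
  th <- pairwise_theta(tri, markers = map$loci)
  expect_true(all(th$n_refs[upper.tri(th$n_refs)] <= 2L))
})
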