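# Independent brute-force oracles: enumerate the 8 gamete haplotypes and all
# 64 ordered gamete pairs, classify each zygote directly, and accumulate
# probabilities.  Deliberately shares no code with the package's closed-form
# forward models or estimators.

# the 8 haplotypes as rows (0 = recessive/first-parent allele)
hap_table <- as.matrix(expand.grid(l1 = 0:1, l2 = 0:1, l3 = 0:1))

# sister-pair class of a haplotype: {000,111}=1 {100,011}=2 {110,001}=3 {101,010}=4
hap_class <- function(h) {
  key <- paste(h, collapse = "")
  unname(c("000" = 1, "111" = 1, "100" = 2, "011" = 2,
           "110" = 3, "001" = 3, "101" = 4, "010" = 4)[key])
}

# probability of each haplotype given sister-pair frequencies q1..q4
hap_probs <- function(q) apply(hap_table, 1, function(h) q[hap_class(h)])

# brute-force dominant phenotype class frequencies Q1..Q8
bf_dominant_freqs <- function(q) {
  pr <- hap_probs(q)
  cls_name <- c("000" = 1, "001" = 2, "010" = 3, "100" = 4,
                "110" = 5, "101" = 6, "011" = 7, "111" = 8)
  Q <- numeric(8)
  for (i in 1:8) for (j in 1:8) {
    state <- pmax(hap_table[i, ], hap_table[j, ])   # dominant allele shows
    k <- cls_name[paste(state, collapse = "")]
    Q[k] <- Q[k] + pr[i] * pr[j]
  }
  stats::setNames(Q, paste0("Q", 1:8))
}

# brute-force codominant zygote-pair class frequencies over the 14 classes
bf_codominant_freqs <- function(q) {
  pr <- hap_probs(q)
  canonical <- function(digits) {
    s <- paste(digits, collapse = "")
    comp <- paste(ifelse(digits == 2, 2, 1 - digits), collapse = "")
    min(s, comp)
  }
  acc <- list()
  for (i in 1:8) for (j in 1:8) {
    g <- ifelse(hap_table[i, ] == hap_table[j, ], hap_table[i, ], 2)
    key <- canonical(g)
    acc[[key]] <- (acc[[key]] %||% 0) + pr[i] * pr[j]
  }
  # canonical genotype string -> package class label
  lab <- c("000" = "P1", "011" = "P2", "001" = "P3", "010" = "P4",
           "200" = "P12", "002" = "P13", "020" = "P14", "021" = "P23",
           "012" = "P24", "201" = "P34", "022" = "P1234", "220" = "P1324",
           "202" = "P1423", "222" = "P222")
  out <- stats::setNames(numeric(length(lab)), unname(lab))
  for (key in names(acc)) out[lab[key]] <- acc[[key]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a random sister-pair frequency vector, components in [lo, hi], sum 0.5
random_q <- function(lo = 0, hi = 0.5) {
  repeat {
    q <- runif(4, lo, hi)
    q <- 0.5 * q / sum(q)
    if (all(q >= lo & q <= hi)) return(q)
  }
}

# dominant genotype matrix with individuals drawn from exact class
# probabilities (counts supplied per phenotype class 1..8)
dominant_matrix_from_counts <- function(counts) {
  states <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
                  c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  calls <- states[rep(1:8, counts), , drop = FALSE]
  genotype_matrix(calls, c("a", "b", "c"), "dominant")
}
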