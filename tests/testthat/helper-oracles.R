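# Independent oracles used to pin expected values. Each is deliberately
# coded along a different route than the package implementation.

# Centered-simplex projection: place the centered log2 profile on three
# unit axes 120 degrees apart (G1 30, S 150, G2M 270 degrees, clockwise
# from up) and sum the vectors. Works from the raw triple, not from
# fold changes.
oracle_project <- function(e1, e2, e3) {
  l <- log2(c(e1, e2, e3))
  cen <- l - mean(l)
  ax <- c(30, 150, 270) * pi / 180
  c(p = sum(cen * sin(ax)), q = sum(cen * cos(ax)))
}

# Angle of a plane vector, clockwise from up, via explicit quadrant
# reasoning on acos (no atan2).
oracle_angle <- function(p, q) {
  r <- sqrt(p^2 + q^2)
  if (r == 0) return(NA_real_)
  base <- acos(q / r) * 180 / pi        # in [0, 180]
  if (p >= 0) base else 360 - base
}

# Brute-force exact multinomial p: enumerate every ordered assignment of
# n draws to 6 bins, score each by the multinomial probability of its
# composition, and sum the sequence probabilities of outcomes no more
# likely than the observed composition. Only feasible for small n.
oracle_multinomial_p <- function(observed, probs, tol = 1e-12) {
  n <- sum(observed)
  comp_prob <- function(x) {
    if (any(x > 0 & probs == 0)) return(0)
    exp(lgamma(n + 1) - sum(lgamma(x + 1)) +
          sum(x[probs > 0] * log(probs[probs > 0])))
  }
  p_obs <- comp_prob(observed)
  if (p_obs == 0) return(0)
  seqs <- as.matrix(expand.grid(rep(list(1:6), n)))
  total <- 0
  for (i in seq_len(nrow(seqs))) {
    x <- tabulate(seqs[i, ], nbins = 6)
    if (comp_prob(x) <= p_obs + tol)
      total <- total + prod(probs[seqs[i, ]])
  }
  total
}

# Same brute-force enumeration, aggregated: enumerate all 6^n ordered
# outcomes once, sum sequence probabilities by composition, and return
# one row per composition with its multinomial probability. p for an
# observed composition is then the total probability of compositions no
# more likely than it.
oracle_multinomial_table <- function(n, probs) {
  seqs <- as.matrix(expand.grid(rep(list(1:6), n)))
  seqp <- apply(seqs, 1, function(s) prod(probs[s]))
  key <- apply(seqs, 1, function(s)
    paste(tabulate(s, nbins = 6), collapse = ","))
  tapply(seqp, key, sum)
}

oracle_multinomial_p_fast <- function(observed, table, tol = 1e-12) {
  p_obs <- unname(table[paste(observed, collapse = ",")])
  if (is.na(p_obs)) return(0)
  sum(table[table <= p_obs + tol])
}

# Brute-force BH step-up: q_i = min_{j: p_j >= p_i} min(1, m p_(j) / j),
# computed from the definition by explicit looping.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * p[o[j]] / j), numeric(1))
    q_sorted[i] <- min(vals)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Small deterministic DE table used by filter tests: one row failing
# each criterion, three passing everything.
fixture_de_table <- function() {
  S4Vectors::DataFrame(
    gene_id = paste0("g", 1:6),
    fdr = c(0.0005, 0.01, 0.0005, 0.0005, 0.0002, 0.0009),
    ave_logCPM = c(2.0, 3.0, 0.5, 2.5, 4.0, 1.0),
    max_fc = c(1.6, 2.0, 2.0, 1.2, 3.0, 1.5))
}

# Random positive triples used by the symmetry suites.
random_triples <- function(n, seed) {
  set.seed(seed)
  matrix(2^stats::runif(3 * n, -5, 5), ncol = 3)
}
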