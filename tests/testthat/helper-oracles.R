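# Independent oracles used by the estimator and chaining tests. These
# deliberately re-derive every probability by explicit enumeration of
# parental chromosomes and gametes, sharing no code with the package.

# gamete probabilities of one heterozygous parent: chromosomes are
# (0,0)/(1,1) in coupling, (0,1)/(1,0) in repulsion; the gamete picks a
# chromosome per locus, switching with probability r
oracle_gametes <- function(r, phase) {
  chroms <- if (phase == 0) list(c(0, 0), c(1, 1)) else list(c(0, 1), c(1, 0))
  out <- matrix(0, 2, 2) # [allele1+1, allele2+1]
  for (c1 in 1:2) for (c2 in 1:2) {
    p <- 0.5 * (if (c1 == c2) 1 - r else r)
    a1 <- chroms[[c1]][1]; a2 <- chroms[[c2]][2]
    out[a1 + 1, a2 + 1] <- out[a1 + 1, a2 + 1] + p
  }
  out
}

# 3x3 genotype-class probabilities for an hkxhk pair
oracle_ic_cellprobs <- function(r, phase_f, phase_m) {
  gf <- oracle_gametes(r, phase_f)
  gm <- oracle_gametes(r, phase_m)
  cells <- matrix(0, 3, 3)
  for (f1 in 0:1) for (f2 in 0:1) for (m1 in 0:1) for (m2 in 0:1) {
    p <- gf[f1 + 1, f2 + 1] * gm[m1 + 1, m2 + 1]
    cells[f1 + m1 + 1, f2 + m2 + 1] <- cells[f1 + m1 + 1, f2 + m2 + 1] + p
  }
  cells
}

# grid maximization of the intercross likelihood over r and phases
oracle_ic_grid <- function(cells9, step = 1e-4) {
  rg <- seq(0, 0.5, by = step)
  best <- c(r = NA, ll = -Inf)
  for (ph in list(c(0, 0), c(0, 1), c(1, 1))) {
    ll <- vapply(rg, function(r) {
      p <- pmax(as.vector(oracle_ic_cellprobs(r, ph[1], ph[2])), 1e-300)
      sum(cells9 * log(p))
    }, 0)
    w <- which.max(ll)
    if (ll[w] > best["ll"]) best <- c(r = rg[w], ll = ll[w])
  }
  best
}

# vectorised variant (the inner vapply above is too slow for many cases)
oracle_ic_grid_fast <- function(cells9, step = 1e-4) {
  rg <- seq(0, 0.5, by = step)
  best_r <- NA_real_; best_ll <- -Inf
  for (ph in list(c(0, 0), c(0, 1), c(1, 1))) {
    # build 9 x G prob matrix by enumeration at each grid point (vectorised
    # over the grid via the algebra of oracle_gametes)
    P <- matrix(0, 9, length(rg))
    for (f1 in 0:1) for (f2 in 0:1) for (m1 in 0:1) for (m2 in 0:1) {
      pf <- oracle_gamete_prob_vec(rg, ph[1], f1, f2)
      pm <- oracle_gamete_prob_vec(rg, ph[2], m1, m2)
      cell <- 3 * (f1 + m1) + (f2 + m2) + 1
      P[cell, ] <- P[cell, ] + pf * pm
    }
    ll <- as.vector(cells9 %*% log(pmax(P, 1e-300)))
    w <- which.max(ll)
    if (ll[w] > best_ll) { best_ll <- ll[w]; best_r <- rg[w] }
  }
  c(r = best_r, ll = best_ll)
}

oracle_gamete_prob_vec <- function(r, phase, a1, a2) {
  chroms <- if (phase == 0) list(c(0, 0), c(1, 1)) else list(c(0, 1), c(1, 0))
  out <- 0
  for (c1 in 1:2) for (c2 in 1:2) {
    if (chroms[[c1]][1] == a1 && chroms[[c2]][2] == a2) {
      out <- out + 0.5 * (if (c1 == c2) 1 - r else r)
    }
  }
  out
}

# testcross pair: counts (same, different); grid max over r and phase
oracle_tt_grid <- function(n_same, n_diff, step = 1e-4) {
  rg <- seq(0, 0.5, by = step)
  ll_c <- n_diff * log(pmax(rg, 1e-300)) + n_same * log(pmax(1 - rg, 1e-300))
  ll_r <- n_same * log(pmax(rg, 1e-300)) + n_diff * log(pmax(1 - rg, 1e-300))
  if (max(ll_c) >= max(ll_r)) rg[which.max(ll_c)] else rg[which.max(ll_r)]
}

# mixed pair: 2x3 table n[a+1, g+1] (a father allele at the testcross
# locus, g genotype at the hkxhk locus); likelihood by enumeration:
# father gamete (a, f2), mother contributes m2 ~ Bernoulli(1/2)
oracle_mixed_grid <- function(n23, step = 1e-4) {
  rg <- seq(0, 0.5, by = step)
  best_r <- NA_real_; best_ll <- -Inf
  for (phase in 0:1) {
    P <- matrix(0, length(rg), 6) # columns a*3 + g + 1
    for (a in 0:1) for (f2 in 0:1) for (m2 in 0:1) {
      p <- oracle_gamete_prob_vec(rg, phase, a, f2) * 0.5
      col <- a * 3 + (f2 + m2) + 1
      P[, col] <- P[, col] + p
    }
    ll <- as.vector(log(pmax(P, 1e-300)) %*% as.vector(t(n23)))
    w <- which.max(ll)
    if (ll[w] > best_ll) { best_ll <- ll[w]; best_r <- rg[w] }
  }
  best_r
}

# exhaustive longest monotone subsequence by subset enumeration
popcount_cache <- new.env()
oracle_longest_monotone <- function(y) {
  n <- length(y)
  S <- 0:(2^n - 1)
  key <- as.character(n)
  if (is.null(popcount_cache[[key]])) {
    pc <- integer(2^n)
    for (b in 0:(n - 1)) pc <- pc + as.integer(bitwAnd(S, 2^b) > 0)
    popcount_cache[[key]] <- pc
  }
  pc <- popcount_cache[[key]]
  best <- 0L
  for (decreasing in c(FALSE, TRUE)) {
    valid <- rep(TRUE, 2^n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      bad <- if (decreasing) y[j] >= y[i] else y[j] <= y[i]
      if (bad) {
        m <- bitwOr(2^(i - 1), 2^(j - 1))
        valid[bitwAnd(S, m) == m] <- FALSE
      }
    }
    best <- max(best, max(pc[valid]))
  }
  best
}

# simulate progeny call vectors for one testcross pair at recombination r
sim_tt_pair <- function(n, r) {
  a1 <- sample(0:1, n, replace = TRUE)
  flip <- runif(n) < r
  a2 <- ifelse(flip, 1 - a1, a1)
  list(calls_i = c("AA", "AB")[a1 + 1], calls_j = c("AA", "AB")[a2 + 1])
}

# simulate one hkxhk pair (coupling/coupling) at recombination r
sim_ic_pair <- function(n, r) {
  g <- function() {
    h1 <- sample(0:1, n, replace = TRUE)
    h2 <- ifelse(runif(n) < r, 1 - h1, h1)
    cbind(h1, h2)
  }
  f <- g(); m <- g()
  list(calls_i = c("AA", "AB", "BB")[f[, 1] + m[, 1] + 1],
       calls_j = c("AA", "AB", "BB")[f[, 2] + m[, 2] + 1])
}

# simulate a mixed pair: marker 1 lmxll (father informative), marker 2 hkxhk
sim_mixed_pair <- function(n, r) {
  f1 <- sample(0:1, n, replace = TRUE)
  f2 <- ifelse(runif(n) < r, 1 - f1, f1)
  m2 <- sample(0:1, n, replace = TRUE)
  list(tc_calls = c("AA", "AB")[f1 + 1],
       hk_calls = c("AA", "AB", "BB")[f2 + m2 + 1])
}

# a truth-perfect genetic_map object (map stage bypassed), used where a
# test targets homoeology/synteny logic rather than map construction
truth_map <- function(truth) {
  mk <- truth$markers[order(truth$markers$chromosome, truth$markers$true_cm), ]
  tab <- data.frame(lg = mk$chromosome, locus_index = ave(mk$true_cm, mk$chromosome,
                                                          FUN = seq_along),
                    marker_id = mk$id, position_cm = mk$true_cm,
                    pattern = mk$pattern)
  structure(list(table = tab, lg = list(), summary = data.frame(),
                 origin = "truth"), class = "genetic_map")
}
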