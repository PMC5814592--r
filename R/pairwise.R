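# Two-point recombination-fraction and LOD engine for CP populations.
#
# Pair types:
#   * testcross x testcross, same parent (lmxll-lmxll, nnxnp-nnxnp):
#     the informative parent's transmitted allele is observed directly,
#     so r-hat is the phase-corrected recombinant fraction min(R, N-R)/N.
#   * intercross x intercross (hkxhk-hkxhk): joint multinomial likelihood
#     of the 3x3 genotype table, maximised numerically over r for each
#     parental phase combination (cc/cr/rr; cr and rc are
#     indistinguishable from genotypes).
#   * mixed (testcross x hkxhk): only the informative parent's meiosis
#     carries linkage; heterozygous calls at the hkxhk marker are
#     ambiguous for parental origin and contribute a constant 1/4 to the
#     likelihood, so the MLE is the testcross estimator restricted to
#     progeny with a homozygous call at the hkxhk marker.
#   * lmxll x nnxnp: different meioses, no two-point information.

# LOD of a phase-corrected testcross estimate (Rm recombinants of N)
lod_testcross <- function(Rm, N) {
  t1 <- ifelse(Rm > 0, Rm * log10(2 * Rm / N), 0)
  t2 <- ifelse(N - Rm > 0, (N - Rm) * log10(2 * (N - Rm) / N), 0)
  out <- t1 + t2
  out[N == 0] <- NA_real_
  out
}

# gamete (haplotype) probabilities of one heterozygous parent;
# columns: transmitted alleles (0,0), (0,1), (1,0), (1,1)
gamete_probs <- function(r, phase) {
  if (phase == 0) cbind((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  else cbind(r / 2, (1 - r) / 2, (1 - r) / 2, r / 2)
}

GAMETES <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))

# 9 genotype-class probabilities of a double-heterozygote (hkxhk) pair;
# cell index = 3*g1 + g2 + 1. Vectorised over r.
ic_cell_probs <- function(r, phase_f, phase_m) {
  Pf <- gamete_probs(r, phase_f)
  Pm <- gamete_probs(r, phase_m)
  out <- matrix(0, length(r), 9)
  for (fi in 1:4) {
    for (mi in 1:4) {
      g1 <- GAMETES[fi, 1] + GAMETES[mi, 1]
      g2 <- GAMETES[fi, 2] + GAMETES[mi, 2]
      idx <- 3L * g1 + g2 + 1L
      out[, idx] <- out[, idx] + Pf[, fi] * Pm[, mi]
    }
  }
  out
}

# row-wise log-likelihood: N9 is (pairs x 9), r a vector per row
ic_loglik_rows <- function(N9, r, phase_f, phase_m) {
  P <- ic_cell_probs(r, phase_f, phase_m)
  rowSums(N9 * log(pmax(P, 1e-300)))
}

# vectorised golden-section maximisation per row within [lo, hi]
ic_golden <- function(N9, lo, hi, phase_f, phase_m, iters = 45L) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- ic_loglik_rows(N9, x1, phase_f, phase_m)
  f2 <- ic_loglik_rows(N9, x2, phase_f, phase_m)
  for (it in seq_len(iters)) {
    left <- f1 >= f2
    if (any(left)) {
      hi[left] <- x2[left]; x2[left] <- x1[left]; f2[left] <- f1[left]
      x1[left] <- hi[left] - gr * (hi[left] - lo[left])
      f1[left] <- ic_loglik_rows(N9[left, , drop = FALSE], x1[left],
                                 phase_f, phase_m)
    }
    rgt <- !left
    if (any(rgt)) {
      lo[rgt] <- x1[rgt]; x1[rgt] <- x2[rgt]; f1[rgt] <- f2[rgt]
      x2[rgt] <- lo[rgt] + gr * (hi[rgt] - lo[rgt])
      f2[rgt] <- ic_loglik_rows(N9[rgt, , drop = FALSE], x2[rgt],
                                phase_f, phase_m)
    }
  }
  (lo + hi) / 2
}

IC_PHASES <- list(cc = c(0L, 0L), cr = c(0L, 1L), rr = c(1L, 1L))

# maximum-likelihood estimation for rows of 9-cell intercross tables;
# returns data.frame(r, lod, phase)
ic_estimate <- function(N9, grid_step = 0.001, chunk = 8192L) {
  npair <- nrow(N9)
  rg <- seq(0, 0.5, by = grid_step)
  LP <- lapply(IC_PHASES, function(ph)
    t(log(pmax(ic_cell_probs(rg, ph[1], ph[2]), 1e-300))))  # 9 x G
  ll_half <- as.vector(N9 %*% log(pmax(ic_cell_probs(0.5, 0L, 0L), 1e-300))[1, ])

  best_ll <- rep(-Inf, npair)
  best_r0 <- numeric(npair)
  best_ph <- integer(npair)
  for (start in seq(1L, npair, by = chunk)) {
    rows <- start:min(start + chunk - 1L, npair)
    Nc <- N9[rows, , drop = FALSE]
    for (p in seq_along(IC_PHASES)) {
      LL <- Nc %*% LP[[p]]
      w <- max.col(LL, ties.method = "first")
      v <- LL[cbind(seq_along(rows), w)]
      better <- v > best_ll[rows]
      idx <- rows[better]
      best_ll[idx] <- v[better]
      best_r0[idx] <- rg[w[better]]
      best_ph[idx] <- p
    }
  }

  r_hat <- numeric(npair)
  for (p in seq_along(IC_PHASES)) {
    sel <- which(best_ph == p)
    if (!length(sel)) next
    ph <- IC_PHASES[[p]]
    lo <- pmax(best_r0[sel] - grid_step, 0)
    hi <- pmin(best_r0[sel] + grid_step, 0.5)
    r_hat[sel] <- ic_golden(N9[sel, , drop = FALSE], lo, hi, ph[1], ph[2])
    best_ll[sel] <- ic_loglik_rows(N9[sel, , drop = FALSE], r_hat[sel],
                                   ph[1], ph[2])
  }
  data.frame(r = pmin(r_hat, 0.5), lod = pmax((best_ll - ll_half) / log(10), 0),
             phase = names(IC_PHASES)[best_ph])
}

# --- call-coding helpers -------------------------------------------------

# transmitted-allele matrix for testcross markers: rows of gm$geno for the
# given markers, translated so that 0/1 is the informative parent's allele
# and pattern-impossible calls are NA. hom_geno: genotype (0 or 2) of the
# homozygous parent per marker.
testcross_alleles <- function(geno_rows, hom_geno) {
  a <- sweep(geno_rows, 1L, ifelse(hom_geno == 2L, 1L, 0L), "-")
  a[!(a %in% c(0L, 1L))] <- NA_integer_
  a
}

indicator <- function(m, value) {
  out <- (m == value)
  out[is.na(out)] <- FALSE
  storage.mode(out) <- "double"
  out
}

# --- single-pair interfaces ---------------------------------------------

#' Two-point estimate for a same-parent testcross marker pair
#'
#' Both markers must be informative in the same parent (both `lmxll` or
#' both `nnxnp`). Each progeny with both calls present is classified as
#' recombinant or not; the reported estimate is taken under the better of
#' the two parental phases, `rhat = min(R, N - R) / N`.
#'
#' @param calls_i,calls_j progeny call vectors (`"AA"`/`"AB"`/`"BB"`/`"NC"`).
#' @param hom_parent_call_i,hom_parent_call_j genotype of the
#'   uninformative (homozygous) parent at each marker (default `"AA"`).
#' @return list with `r`, `lod`, `phase` (`coupling`/`repulsion`),
#'   `n_informative`.
#' @examples
#' rf_testcross_pair(rep(c("AA", "AB"), 10), rep(c("AA", "AB"), 10))
#' @export
rf_testcross_pair <- function(calls_i, calls_j,
                              hom_parent_call_i = "AA",
                              hom_parent_call_j = "AA") {
  ai <- testcross_alleles(matrix(code_call(calls_i), 1), code_call(hom_parent_call_i))
  aj <- testcross_alleles(matrix(code_call(calls_j), 1), code_call(hom_parent_call_j))
  ok <- !is.na(ai) & !is.na(aj)
  N <- sum(ok)
  if (N == 0) return(list(r = NA_real_, lod = NA_real_, phase = "none",
                          n_informative = 0L))
  R <- sum(ai[ok] != aj[ok])
  Rm <- min(R, N - R)
  list(r = Rm / N, lod = lod_testcross(Rm, N),
       phase = if (R <= N - R) "coupling" else "repulsion",
       n_informative = as.integer(N))
}

#' Two-point estimate for an intercross (hkxhk) marker pair
#'
#' Maximises the joint multinomial likelihood of the 3x3 genotype table
#' over the recombination fraction for each parental phase combination
#' (both meioses informative; the same r is assumed for both parents) and
#' reports the best phase, its MLE and the LOD against r = 0.5.
#'
#' @param calls_i,calls_j progeny call vectors for the two markers.
#' @param grid_step grid resolution of the global search stage (the
#'   estimate itself is refined to ~1e-9 by golden-section search).
#' @return list with `r`, `lod`, `phase` (`cc`/`cr`/`rr`; `cr` covers the
#'   indistinguishable cr/rc pair), `n_informative`.
#' @export
rf_intercross_pair <- function(calls_i, calls_j, grid_step = 0.001) {
  gi <- code_call(calls_i)
  gj <- code_call(calls_j)
  ok <- !is.na(gi) & !is.na(gj)
  if (!sum(ok)) return(list(r = NA_real_, lod = NA_real_, phase = "none",
                            n_informative = 0L))
  N9 <- matrix(0, 1, 9)
  idx <- 3L * gi[ok] + gj[ok] + 1L
  for (k in idx) N9[1, k] <- N9[1, k] + 1
  est <- ic_estimate(N9, grid_step = grid_step)
  list(r = est$r, lod = est$lod, phase = est$phase,
       n_informative = as.integer(sum(ok)))
}

#' Two-point estimate for a mixed testcross / intercross marker pair
#'
#' One marker is informative in a single parent (`lmxll` or `nnxnp`), the
#' other is `hkxhk`. The uninformative parent transmits 1:1
#' independently, and a heterozygous call at the `hkxhk` marker is
#' ambiguous for parental origin (class probability 1/4 whatever r), so
#' the likelihood is maximised by the testcross estimator on the progeny
#' with homozygous `hkxhk` calls. A pair of opposite-parent testcross
#' markers shares no meiosis: `lod = 0` and the pair is flagged.
#'
#' @param tc_calls progeny calls at the testcross marker.
#' @param hk_calls progeny calls at the `hkxhk` marker.
#' @param hom_parent_call genotype of the testcross marker's homozygous
#'   parent.
#' @return list with `r`, `lod`, `phase`, `n_informative`.
#' @export
rf_mixed_pair <- function(tc_calls, hk_calls, hom_parent_call = "AA") {
  a <- testcross_alleles(matrix(code_call(tc_calls), 1), code_call(hom_parent_call))
  g <- code_call(hk_calls)
  ok <- !is.na(a) & !is.na(g) & g != 1L
  N <- sum(ok)
  if (N == 0) return(list(r = NA_real_, lod = NA_real_, phase = "none",
                          n_informative = 0L))
  # informative-parent allele at the hkxhk marker: 0 for AA, 1 for BB
  b <- g[ok] / 2L
  R <- sum(a[ok] != b)
  Rm <- min(R, N - R)
  list(r = Rm / N, lod = lod_testcross(Rm, N),
       phase = if (R <= N - R) "coupling" else "repulsion",
       n_informative = as.integer(N))
}

# --- all-pairs table ------------------------------------------------------

#' All pairwise two-point linkage estimates among kept markers
#'
#' Computes recombination fraction, LOD, phase and informative-progeny
#' count for every marker pair among the kept markers of a QC table,
#' using the appropriate estimator per pattern combination.
#' Opposite-parent testcross pairs (`lmxll` vs `nnxnp`) carry no
#' two-point information and are recorded with `lod = 0` and phase
#' `"none"`.
#'
#' @param gm a [genotype_matrix()] (CP dataset).
#' @param qc a filtered [marker_qc()] table ([filter_markers()]); only
#'   rows with `kept == TRUE` enter.
#' @param grid_step global-search grid resolution for intercross pairs.
#' @return An object of class `pairwise_linkage`: a data.frame with
#'   columns `i`, `j` (indices into `attr(, "markers")`), `type`
#'   (`tt_f`, `tt_m`, `ii`, `mixed_f`, `mixed_m`, `none`), `r`, `lod`,
#'   `phase`, `n` and `discord` (observed discordant/recombinant-cell
#'   count for same-pattern pairs; used for co-segregation binning).
#'   Attributes: `markers` (ids), `patterns`.
#' @export
pairwise_linkage <- function(gm, qc, grid_step = 0.001) {
  keep <- qc$marker_id[qc$kept]
  if (length(keep) < 2) stop2("need at least two kept markers")
  pat <- stats::setNames(qc$pattern, qc$marker_id)[keep]
  pc <- parent_columns(gm)
  prog <- progeny_columns(gm)
  g <- gm$geno[keep, prog, drop = FALSE]

  idx_lm <- which(pat == "lmxll")
  idx_nn <- which(pat == "nnxnp")
  idx_hk <- which(pat == "hkxhk")

  hom_lm <- gm$geno[keep[idx_lm], pc["mother"], drop = TRUE]
  hom_nn <- gm$geno[keep[idx_nn], pc["father"], drop = TRUE]
  A_lm <- if (length(idx_lm))
    testcross_alleles(g[idx_lm, , drop = FALSE], hom_lm) else NULL
  A_nn <- if (length(idx_nn))
    testcross_alleles(g[idx_nn, , drop = FALSE], hom_nn) else NULL
  G_hk <- if (length(idx_hk)) g[idx_hk, , drop = FALSE] else NULL

  res <- list()

  tt_block <- function(A, idx, type) {
    if (length(idx) < 2) return(NULL)
    A0 <- indicator(A, 0L); A1 <- indicator(A, 1L)
    same <- tcrossprod(A0) + tcrossprod(A1)
    Nn <- tcrossprod(A0 + A1)
    ut <- which(upper.tri(Nn), arr.ind = TRUE)
    N <- Nn[ut]; S <- same[ut]; R <- N - S
    Rm <- pmin(R, N - R)
    r <- ifelse(N > 0, Rm / N, NA_real_)
    data.frame(i = idx[ut[, 1]], j = idx[ut[, 2]], type = type,
               r = r, lod = lod_testcross(Rm, N),
               phase = ifelse(N == 0, "none",
                              ifelse(R <= N - R, "coupling", "repulsion")),
               n = as.integer(N), discord = as.integer(R))
  }
  res$lm <- tt_block(A_lm, idx_lm, "tt_f")
  res$nn <- tt_block(A_nn, idx_nn, "tt_m")

  if (length(idx_hk) >= 2) {
    Gi <- lapply(0:2, function(v) indicator(G_hk, v))
    ut <- which(upper.tri(diag(length(idx_hk))), arr.ind = TRUE)
    N9 <- matrix(0, nrow(ut), 9)
    for (a in 0:2) for (b in 0:2) {
      M <- tcrossprod(Gi[[a + 1]], Gi[[b + 1]])
      N9[, 3L * a + b + 1L] <- M[ut]
    }
    Ntot <- rowSums(N9)
    nonzero <- Ntot > 0
    est <- data.frame(r = rep(NA_real_, nrow(ut)), lod = rep(NA_real_, nrow(ut)),
                      phase = rep("none", nrow(ut)))
    if (any(nonzero)) est[nonzero, ] <- ic_estimate(N9[nonzero, , drop = FALSE],
                                                    grid_step = grid_step)
    discord <- as.integer(Ntot - N9[, 1] - N9[, 5] - N9[, 9])
    res$hk <- data.frame(i = idx_hk[ut[, 1]], j = idx_hk[ut[, 2]], type = "ii",
                         r = est$r, lod = est$lod, phase = est$phase,
                         n = as.integer(Ntot), discord = discord)
  }

  mixed_block <- function(A, idx_t, type) {
    if (!length(idx_t) || !length(idx_hk)) return(NULL)
    A0 <- indicator(A, 0L); A1 <- indicator(A, 1L)
    H0 <- indicator(G_hk, 0L); H2 <- indicator(G_hk, 2L)
    n00 <- tcrossprod(A0, H0); n02 <- tcrossprod(A0, H2)
    n10 <- tcrossprod(A1, H0); n12 <- tcrossprod(A1, H2)
    N <- n00 + n02 + n10 + n12
    R <- n02 + n10
    ii <- as.vector(row(N)); jj <- as.vector(col(N))
    N <- as.vector(N); R <- as.vector(R)
    Rm <- pmin(R, N - R)
    data.frame(i = idx_t[ii], j = idx_hk[jj], type = type,
               r = ifelse(N > 0, Rm / N, NA_real_),
               lod = lod_testcross(Rm, N),
               phase = ifelse(N == 0, "none",
                              ifelse(R <= N - R, "coupling", "repulsion")),
               n = as.integer(N), discord = NA_integer_)
  }
  res$mf <- mixed_block(A_lm, idx_lm, "mixed_f")
  res$mm <- mixed_block(A_nn, idx_nn, "mixed_m")

  if (length(idx_lm) && length(idx_nn)) {
    grid <- expand.grid(a = idx_lm, b = idx_nn)
    res$fm <- data.frame(i = grid$a, j = grid$b, type = "none",
                         r = NA_real_, lod = 0, phase = "none",
                         n = 0L, discord = NA_integer_)
  }

  out <- do.call(rbind, res)
  # canonical orientation i < j
  swap <- out$i > out$j
  tmp <- out$i[swap]; out$i[swap] <- out$j[swap]; out$j[swap] <- tmp
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  attr(out, "markers") <- keep
  attr(out, "patterns") <- unname(pat)
  class(out) <- c("pairwise_linkage", "data.frame")
  out
}
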