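# union-find (plain root chase; component sizes here are small)
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

#' Group markers into linkage groups by pairwise LOD
#'
#' Single-linkage (transitive-closure) grouping: two markers join the
#' same group whenever some chain of pairs with `lod > lod_limit`
#' connects them. Groups with at most `min_group_size` members are
#' discarded. Group numbering is deterministic: decreasing size, ties by
#' smallest member id.
#'
#' @param pl a [pairwise_linkage()] table.
#' @param lod_limit LOD threshold for joining (default 11).
#' @param min_group_size retain groups with more than this many markers
#'   (default 15).
#' @param min_informative pairs with fewer informative progeny are
#'   ignored for grouping.
#' @param markers optional subset of marker ids to group (e.g. the
#'   male-map markers); defaults to all markers in `pl`.
#' @return list with `groups` (list of character vectors, named
#'   `LG1`...) and `assignment` (data.frame `marker_id`, `lg`; dropped
#'   markers have `lg = NA`).
#' @export
group_markers <- function(pl, lod_limit = 11, min_group_size = 15,
                          min_informative = 20, markers = NULL) {
  ids <- attr(pl, "markers")
  sel_mark <- if (is.null(markers)) seq_along(ids) else match(markers, ids)
  if (anyNA(sel_mark)) stop2("markers not present in pairwise table")
  in_set <- logical(length(ids)); in_set[sel_mark] <- TRUE

  edges <- pl[in_set[pl$i] & in_set[pl$j] &
                !is.na(pl$lod) & pl$lod > lod_limit &
                pl$n >= min_informative, c("i", "j")]
  parent <- uf_new(length(ids))
  for (k in seq_len(nrow(edges))) {
    a <- uf_find(parent, as.integer(edges$i[k]))
    b <- uf_find(parent, as.integer(edges$j[k]))
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(sel_mark, function(x) uf_find(parent, x), numeric(1))
  comp <- split(ids[sel_mark], root)
  comp <- comp[lengths(comp) > min_group_size]
  if (length(comp)) {
    first <- vapply(comp, function(m) min(m), "")
    ord <- order(-lengths(comp), first)
    comp <- comp[ord]
    names(comp) <- paste0("LG", seq_along(comp))
  }
  assignment <- data.frame(marker_id = ids[sel_mark], lg = NA_character_,
                           row.names = NULL)
  for (g in names(comp)) {
    assignment$lg[assignment$marker_id %in% comp[[g]]] <- g
  }
  list(groups = comp, assignment = assignment)
}

# dense per-LG matrices (r, n, discord, phase) from the pairwise table
lg_matrices <- function(pl, lg_markers) {
  ids <- attr(pl, "markers")
  loc <- match(lg_markers, ids)
  k <- length(loc)
  pos <- rep(NA_integer_, length(ids)); pos[loc] <- seq_len(k)
  rows <- which(!is.na(pos[pl$i]) & !is.na(pos[pl$j]))
  li <- pos[pl$i[rows]]; lj <- pos[pl$j[rows]]
  r_mat <- matrix(NA_real_, k, k)
  n_mat <- matrix(0L, k, k)
  lod_mat <- matrix(0, k, k)
  d_mat <- matrix(NA_integer_, k, k)
  ph_mat <- matrix(NA_character_, k, k)
  idx <- cbind(li, lj); idx2 <- cbind(lj, li)
  r_mat[idx] <- r_mat[idx2] <- pl$r[rows]
  n_mat[idx] <- n_mat[idx2] <- pl$n[rows]
  lod_mat[idx] <- lod_mat[idx2] <- ifelse(is.na(pl$lod[rows]), 0, pl$lod[rows])
  d_mat[idx] <- d_mat[idx2] <- pl$discord[rows]
  ph_mat[idx] <- ph_mat[idx2] <- pl$phase[rows]
  list(r = r_mat, n = n_mat, lod = lod_mat, discord = d_mat, phase = ph_mat,
       markers = lg_markers)
}

# connected components of an adjacency matrix (logical, symmetric)
graph_components <- function(adj) {
  n <- nrow(adj)
  parent <- uf_new(n)
  ee <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (q in seq_len(nrow(ee))) {
    a <- uf_find(parent, ee[q, 1])
    b <- uf_find(parent, ee[q, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), function(x) uf_find(parent, x), 0L)
}

# all-pairs shortest-path completion (Floyd-Warshall) of a distance
# matrix with missing entries
complete_distances <- function(D) {
  k <- nrow(D)
  D[is.na(D)] <- Inf
  diag(D) <- 0
  for (m in seq_len(k)) {
    D <- pmin(D, outer(D[, m], D[m, ], "+"))
  }
  if (any(!is.finite(D))) {
    mx <- max(D[is.finite(D)], 0)
    D[!is.finite(D)] <- 1.5 * mx + 10
  }
  D
}

path_length <- function(D, p) {
  if (length(p) < 2) return(0)
  sum(D[cbind(p[-length(p)], p[-1])])
}

# windowed path objective: sum of D over rank offsets 1..w, each offset
# down-weighted by 1/t. Individual two-point distances are noisy; summing
# over a window of offsets averages that noise, so moves that merely
# exploit a single lucky small distance do not improve this objective.
window_objective <- function(D, p, w = 6) {
  k <- length(p)
  total <- 0
  for (t in seq_len(min(w, k - 1))) {
    total <- total + sum(D[cbind(p[1:(k - t)], p[(1 + t):k])]) / t
  }
  total
}

# one 2-opt sweep over segment reversals: candidates are screened by the
# adjacent-sum delta and accepted only if the windowed objective improves
two_opt_sweep <- function(p, D, w = 6, cur = NULL, tol = 1e-9) {
  k <- length(p)
  if (is.null(cur)) cur <- window_objective(D, p, w)
  improved <- FALSE
  for (i in seq_len(k - 1)) {
    js <- (i + 1):k
    left <- if (i > 1) D[p[i - 1], p[js]] - D[p[i - 1], p[i]] else rep(0, length(js))
    right <- rep(0, length(js))
    inner <- js < k
    if (any(inner)) {
      jin <- js[inner]
      right[inner] <- D[p[i], p[jin + 1]] - D[cbind(p[jin], p[jin + 1])]
    }
    delta <- left + right
    for (b in order(delta)[seq_len(min(3, length(js)))]) {
      if (delta[b] >= -tol) break
      j <- js[b]
      p2 <- p
      p2[i:j] <- rev(p2[i:j])
      val <- window_objective(D, p2, w)
      if (val < cur - tol) {
        p <- p2; cur <- val; improved <- TRUE
        break
      }
    }
  }
  list(order = p, improved = improved, objective = cur)
}

# one or-opt sweep: relocate segments of 1..max_seg loci (forward or
# reversed) to their best adjacent-sum insertion point, accepting only
# windowed-objective improvements. Covers single-locus ripple insertion
# (segment length 1) and displaced/reversed block repair.
oropt_sweep <- function(p, D, max_seg = 10, w = 6, cur = NULL, tol = 1e-9) {
  k <- length(p)
  if (is.null(cur)) cur <- window_objective(D, p, w)
  improved <- FALSE
  if (k < 3) return(list(order = p, improved = FALSE, objective = cur))
  for (i in seq_len(k)) {
    for (l in seq_len(min(max_seg, k - 2L, k - i + 1L))) {
      j2 <- i + l - 1L
      s <- p[i:j2]
      q <- p[-(i:j2)]
      m <- length(q)
      rm_gain <- 0
      if (i > 1) rm_gain <- rm_gain + D[p[i - 1], s[1]]
      if (j2 < k) rm_gain <- rm_gain + D[s[l], p[j2 + 1]]
      if (i > 1 && j2 < k) rm_gain <- rm_gain - D[p[i - 1], p[j2 + 1]]
      # inserting into gap gj gives edges q[gj] -> first, last -> q[gj+1]
      ins_cost <- function(first, last) {
        ins <- numeric(m + 1)
        ins[1] <- D[last, q[1]]
        ins[m + 1] <- D[q[m], first]
        if (m > 1) {
          a <- q[1:(m - 1)]; b <- q[2:m]
          ins[2:m] <- D[cbind(a, rep(first, m - 1))] +
            D[cbind(rep(last, m - 1), b)] - D[cbind(a, b)]
        }
        ins
      }
      fwd <- ins_cost(s[1], s[l])
      rev_ <- if (l > 1) ins_cost(s[l], s[1]) else rep(Inf, m + 1)
      bf <- which.min(fwd); br <- which.min(rev_)
      use_rev <- rev_[br] < fwd[bf]
      best <- if (use_rev) br else bf
      cost <- if (use_rev) rev_[br] else fwd[bf]
      if (cost - rm_gain < -tol) {
        seg <- if (use_rev) rev(s) else s
        p2 <- append(q, seg, after = best - 1L)
        val <- window_objective(D, p2, w)
        if (val < cur - tol) {
          p <- p2; cur <- val; improved <- TRUE
          break
        }
      }
    }
  }
  list(order = p, improved = improved, objective = cur)
}

# per-locus additive error offsets from flanking triples.
# For collinear loci with per-locus call-error offsets e,
#   r_obs(a,b) ~ r_true(a,b) + e_a + e_b,  and under no interference
#   r_true(a,b) = r_true(a,j) + r_true(j,b) - 2 r_true(a,j) r_true(j,b),
# so (r1 + r2 - r3)/2 = e_j + r1_true * r2_true. The product term is
# removed with a plug-in estimate from a first pass: pass 1 estimates the
# offsets without it (slightly inflated), pass 2 subtracts the product of
# the pass-1-corrected fractions. Offsets are not floored at zero: the
# median fluctuates symmetrically around the truth, and truncation would
# bias every offset upward and systematically shrink the map.
estimate_locus_eps <- function(Rm, Nm, order, window = 4, min_informative = 20) {
  k <- length(order)
  avail <- function(a, b) {
    v <- Rm[order[a], order[b]]
    if (is.na(v) || Nm[order[a], order[b]] < min_informative) NA_real_ else v
  }
  one_pass <- function(eps_prev) {
    eps <- rep(NA_real_, k)
    for (j in seq_len(k)) {
      ests <- c()
      for (a in max(1, j - window):(j - 1)) {
        for (b in (j + 1):min(k, j + window)) {
          if (a < 1 || b > k || a >= j || b <= j) next
          r1 <- avail(a, j); r2 <- avail(j, b); r3 <- avail(a, b)
          if (anyNA(c(r1, r2, r3))) next
          prod_term <- if (is.null(eps_prev)) 0 else {
            max(r1 - eps_prev[a] - eps_prev[j], 0) *
              max(r2 - eps_prev[j] - eps_prev[b], 0)
          }
          ests <- c(ests, (r1 + r2 - r3) / 2 - prod_term)
        }
      }
      if (length(ests) >= 2) eps[j] <- stats::median(ests)
    }
    eps[is.na(eps)] <- 0
    eps
  }
  one_pass(one_pass(NULL))
}

#' Order the markers of one linkage group
#'
#' Pipeline: (1) markers with zero observed recombination and no
#' discordant calls are binned into loci; (2) locus-level recombination
#' fractions are aggregated (informative-count-weighted mean over member
#' pairs), converted to Kosambi distances and completed by all-pairs
#' shortest paths where a direct estimate is missing or unreliable;
#' (3) an initial order is obtained by seriation (first principal
#' coordinate of the completed distance matrix) and polished by
#' `n_iterations` rounds of 2-opt segment reversals plus single-locus
#' ripple insertion, minimising the sum of adjacent distances;
#' (4) orientation is normalised so the lexicographically smallest marker
#' id falls in the first half; (5) positions are the cumulative Kosambi
#' distances of adjacent locus estimates, optionally corrected for the
#' additive inflation genotyping error causes in two-point estimates
#' (per-locus offsets estimated from flanking triples).
#'
#' @param lg_markers character vector of marker ids of one linkage group.
#' @param pl a [pairwise_linkage()] table.
#' @param n_iterations improvement rounds (default 40).
#' @param min_informative minimum informative progeny for a pair to be
#'   used directly.
#' @param r_max direct estimates above this are treated as uninformative
#'   and replaced by shortest-path distances.
#' @param lod_direct minimum (locus-level) LOD for a pair's distance to
#'   be used directly rather than bridged by shortest paths.
#' @param knn neighbours kept per locus in the local distance graph.
#' @param window rank-offset window of the polish objective.
#' @param correct_errors apply the two-point error-inflation correction.
#' @return list with `loci` (list of member-id vectors in map order),
#'   `position_cm`, `r_adjacent` (corrected adjacent recombination
#'   fractions, `NA` where bridged by shortest path), `eps` (per-locus
#'   error offsets) and `markers_table` (long data.frame: `locus_index`,
#'   `marker_id`, `position_cm`, `pattern`).
#' @export
order_markers <- function(lg_markers, pl, n_iterations = 40,
                          min_informative = 20, r_max = 0.4,
                          lod_direct = 3, knn = 8, window = 6,
                          correct_errors = TRUE) {
  ids <- attr(pl, "markers")
  pats <- stats::setNames(attr(pl, "patterns"), ids)
  if (length(lg_markers) == 1) {
    return(list(loci = list(lg_markers), position_cm = 0,
                r_adjacent = numeric(0), eps = 0,
                markers_table = data.frame(locus_index = 1L,
                                           marker_id = lg_markers,
                                           position_cm = 0,
                                           pattern = unname(pats[lg_markers]))))
  }
  M <- lg_matrices(pl, sort(lg_markers))
  k <- length(M$markers)

  # --- co-segregation binning ---
  parent <- uf_new(k)
  bin_pairs <- which(!is.na(M$discord) & M$discord == 0 &
                       !is.na(M$r) & M$r == 0 &
                       M$n >= min_informative & upper.tri(M$r),
                     arr.ind = TRUE)
  for (e in seq_len(nrow(bin_pairs))) {
    a <- uf_find(parent, bin_pairs[e, 1])
    b <- uf_find(parent, bin_pairs[e, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(k), function(x) uf_find(parent, x), 0L)
  loci <- split(M$markers, root)           # member ids per locus
  loci <- lapply(loci, sort)
  L <- length(loci)
  locus_of <- match(root, sort(unique(root)))

  # --- locus-level aggregation (weight = informative count) ---
  Rsum <- matrix(0, L, L); Nsum <- matrix(0, L, L); Lmax <- matrix(0, L, L)
  ut <- which(upper.tri(M$r), arr.ind = TRUE)
  ok <- !is.na(M$r[ut]) & M$n[ut] > 0
  ut <- ut[ok, , drop = FALSE]
  la <- locus_of[ut[, 1]]; lb <- locus_of[ut[, 2]]
  w <- M$n[ut]; rv <- M$r[ut]; lv <- M$lod[ut]
  cross <- la != lb
  if (any(cross)) {
    ia <- pmin(la[cross], lb[cross]); ib <- pmax(la[cross], lb[cross])
    key <- (ia - 1) * L + ib
    rs <- rowsum(cbind(rv[cross] * w[cross], w[cross]), key)
    lmx <- tapply(lv[cross], key, max)
    kk <- as.integer(rownames(rs))
    ia2 <- (kk - 1) %/% L + 1; ib2 <- (kk - 1) %% L + 1
    Rsum[cbind(ia2, ib2)] <- Rsum[cbind(ib2, ia2)] <- rs[, 1]
    Nsum[cbind(ia2, ib2)] <- Nsum[cbind(ib2, ia2)] <- rs[, 2]
    Lmax[cbind(ia2, ib2)] <- Lmax[cbind(ib2, ia2)] <-
      lmx[match(kk, as.integer(names(lmx)))]
  }
  Rloc <- ifelse(Nsum > 0, Rsum / Nsum, NA_real_)

  # --- distances, completion, seriation ---
  # two-point estimates of weakly linked pairs scatter downward (their
  # phase-corrected r-hat can fluctuate well below truth), and taking
  # shortest paths over all of them lets such pairs act as metric
  # shortcuts that collapse the embedding. So the distance graph keeps,
  # per locus, only the knn smallest well-supported r-hat neighbours
  # (plus the symmetric counterparts); shortest paths over that local
  # graph rebuild long distances additively, Isomap-style.
  candidate <- !is.na(Rloc) & Rloc < r_max & Nsum >= min_informative &
    Lmax >= lod_direct
  direct <- candidate
  direct_strict <- candidate
  if (L > knn + 1) {
    keep <- matrix(FALSE, L, L)
    for (i in seq_len(L)) {
      cand_i <- which(candidate[i, ])
      if (!length(cand_i)) next
      nb <- cand_i[order(Rloc[i, cand_i])][seq_len(min(knn, length(cand_i)))]
      keep[i, nb] <- TRUE
    }
    # union kNN graph (richer local evidence, used for polishing)
    direct <- candidate & (keep | t(keep))
    # mutual kNN graph: an edge must be among the best options of *both*
    # endpoints, which excludes chance low-r pairs between distant loci
    # (interior loci always have closer genuine neighbours); used for the
    # seriation embedding, which folds under such shortcuts
    direct_strict <- candidate & keep & t(keep)
    # connectivity repair: reconnect components through the smallest
    # remaining candidate distances (genuine bridges across map gaps)
    repeat {
      comp <- graph_components(direct_strict)
      if (length(unique(comp)) == 1) break
      cand_edges <- which(candidate & !direct_strict & upper.tri(candidate),
                          arr.ind = TRUE)
      cand_edges <- cand_edges[comp[cand_edges[, 1]] != comp[cand_edges[, 2]], ,
                               drop = FALSE]
      if (!nrow(cand_edges)) break
      # bridge on the strongest linkage evidence, not the smallest r-hat:
      # the minimum over many cross-component r-hats is an extreme-value
      # statistic that favours a lucky distant pair over a genuine bridge
      b <- which.max(Lmax[cand_edges])
      direct_strict[cand_edges[b, 1], cand_edges[b, 2]] <- TRUE
      direct_strict[cand_edges[b, 2], cand_edges[b, 1]] <- TRUE
    }
    direct <- direct | direct_strict
  }
  D <- matrix(NA_real_, L, L)
  D[direct] <- kosambi_cm(Rloc[direct])
  D <- complete_distances(D)

  polish <- function(start, PD) {
    cur <- window_objective(PD, start, window)
    for (round in seq_len(n_iterations)) {
      s1 <- two_opt_sweep(start, PD, w = window, cur = cur)
      s2 <- oropt_sweep(s1$order, PD, w = window, cur = s1$objective)
      start <- s2$order
      cur <- s2$objective
      if (!s1$improved && !s2$improved) break
    }
    list(order = start, objective = cur)
  }

  if (L > 2) {
    Ds <- matrix(NA_real_, L, L)
    Ds[direct_strict] <- kosambi_cm(Rloc[direct_strict])
    Ds <- complete_distances(Ds)
    # two deterministic seriation starts (the strict mutual-kNN metric
    # embeds without shortcut folds; the richer union metric sometimes
    # resolves dense regions better), each polished under both metrics;
    # every candidate then gets a finishing pass under the union metric
    # so that all objectives are comparable
    starts <- list(order(stats::cmdscale(Ds, k = 1)[, 1], seq_len(L)),
                   order(stats::cmdscale(D, k = 1)[, 1], seq_len(L)))
    best <- NULL
    for (st in starts) {
      for (metric in list(D, Ds)) {
        cand <- polish(polish(st, metric)$order, D)
        if (is.null(best) || cand$objective < best$objective - 1e-9) best <- cand
      }
    }
    # iterated local search: deterministic double-bridge perturbations
    # (reorder four segments) escape fold-shaped local optima that no
    # single reversal or relocation can repair
    bridges <- list(c(0.25, 0.50, 0.75), c(0.20, 0.40, 0.70),
                    c(0.30, 0.55, 0.80), c(0.15, 0.50, 0.85),
                    c(0.10, 0.30, 0.60), c(0.35, 0.60, 0.85),
                    c(0.20, 0.60, 0.80), c(0.40, 0.65, 0.90))
    if (L >= 8) {
      for (fr in bridges) {
        cuts <- sort(unique(pmin(pmax(round(fr * L), 1), L - 1)))
        if (length(cuts) < 3) next
        p <- best$order
        pert <- c(p[1:cuts[1]], p[(cuts[2] + 1):cuts[3]],
                  p[(cuts[1] + 1):cuts[2]], p[(cuts[3] + 1):L])
        cand <- polish(pert, D)
        if (cand$objective < best$objective - 1e-9) best <- cand
      }
    }
    ord <- best$order
  } else ord <- seq_len(L)

  # canonical orientation: smallest marker id in the first half
  anchor_locus <- locus_of[1]  # M$markers is sorted, so index 1 is smallest id
  if (match(anchor_locus, ord) > (L + 1) / 2) ord <- rev(ord)

  # --- adjacent distances and positions ---
  if (L > 1) {
    adj <- cbind(ord[-L], ord[-1])
    r_adj <- Rloc[adj]
    r_adj[!direct[adj]] <- NA
    eps <- if (correct_errors)
      estimate_locus_eps(Rloc, Nsum, ord, min_informative = min_informative)
    else rep(0, L)
    # eps is positional (eps[j] belongs to the locus at map position j)
    r_corr <- pmax(r_adj - eps[-L] - eps[-1], 0)
    gaps <- D[adj]
    ok <- !is.na(r_corr)
    gaps[ok] <- kosambi_cm(pmin(r_corr[ok], 0.49999))
    pos <- c(0, cumsum(gaps))
  } else {
    r_corr <- numeric(0); pos <- 0; eps <- 0
  }

  loci_ordered <- loci[ord]
  tab <- do.call(rbind, lapply(seq_along(loci_ordered), function(i) {
    data.frame(locus_index = i, marker_id = loci_ordered[[i]],
               position_cm = pos[i],
               pattern = unname(pats[loci_ordered[[i]]]))
  }))
  rownames(tab) <- NULL
  list(loci = loci_ordered, position_cm = pos, r_adjacent = r_corr,
       eps = eps, markers_table = tab)
}

lg_summary_row <- function(lg_name, ord) {
  gaps <- diff(ord$position_cm)
  data.frame(lg = lg_name,
             n_markers = nrow(ord$markers_table),
             n_loci = length(ord$loci),
             length_cm = max(ord$position_cm),
             mean_gap_cm = if (length(gaps)) mean(gaps) else 0,
             max_gap_cm = if (length(gaps)) max(gaps) else 0,
             frac_gap_le5 = if (length(gaps)) mean(gaps <= 5) else 1)
}

#' Build male, female and integrated genetic maps
#'
#' The male map uses `lmxll` and `hkxhk` markers (paternal meioses), the
#' female map `nnxnp` and `hkxhk` (maternal), and the integrated map all
#' three patterns with mixed-pair bridging. Each map is grouped at
#' `lod_limit`, ordered per linkage group, and summarised.
#'
#' @param gm a [genotype_matrix()].
#' @param qc a filtered [marker_qc()] table.
#' @param pl optional precomputed [pairwise_linkage()] table.
#' @param lod_limit,min_group_size,min_informative see [group_markers()].
#' @param n_iterations,correct_errors see [order_markers()].
#' @return list of class `cp_maps` with elements `male`, `female`,
#'   `integrated` (each of class `genetic_map`: `lg` named list of
#'   [order_markers()] results, `table` long data.frame, `summary`) and
#'   `pairwise` (the shared pairwise table).
#' @export
build_maps <- function(gm, qc, pl = NULL, lod_limit = 11, min_group_size = 15,
                       min_informative = 20, n_iterations = 40,
                       correct_errors = TRUE) {
  if (is.null(pl)) pl <- pairwise_linkage(gm, qc)
  ids <- attr(pl, "markers")
  pats <- stats::setNames(attr(pl, "patterns"), ids)
  sets <- list(male = ids[pats %in% c("lmxll", "hkxhk")],
               female = ids[pats %in% c("nnxnp", "hkxhk")],
               integrated = ids)
  maps <- lapply(names(sets), function(map_name) {
    mk <- sets[[map_name]]
    if (length(mk) < 2) {
      warning("no informative markers for the ", map_name, " map", call. = FALSE)
      return(structure(list(lg = list(),
                            table = data.frame(), summary = data.frame(),
                            origin = map_name),
                       class = "genetic_map"))
    }
    grp <- group_markers(pl, lod_limit, min_group_size, min_informative,
                         markers = mk)
    ordered <- lapply(grp$groups, order_markers, pl = pl,
                      n_iterations = n_iterations,
                      min_informative = min_informative,
                      correct_errors = correct_errors)
    tab <- do.call(rbind, lapply(names(ordered), function(g) {
      cbind(lg = g, ordered[[g]]$markers_table)
    }))
    summ <- do.call(rbind, lapply(names(ordered), function(g)
      lg_summary_row(g, ordered[[g]])))
    structure(list(lg = ordered, table = tab, summary = summ,
                   origin = map_name, assignment = grp$assignment),
              class = "genetic_map")
  })
  names(maps) <- names(sets)
  structure(c(maps, list(pairwise = pl)), class = "cp_maps")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map (%s): %d linkage groups, %d markers, %.1f cM\n",
              x$origin %||% "?", length(x$lg),
              if (is.null(x$table) || !nrow(x$table)) 0 else nrow(x$table),
              if (is.null(x$summary) || !nrow(x$summary)) 0
              else sum(x$summary$length_cm)))
  invisible(x)
}

#' @export
print.cp_maps <- function(x, ...) {
  for (m in c("male", "female", "integrated")) print(x[[m]])
  invisible(x)
}

#' Summary statistics of a genetic map
#'
#' Per-LG marker and locus counts, map length, mean/max adjacent gap and
#' the fraction of adjacent gaps at most 5 cM, plus a `total` row
#' (lengths summed, gap statistics pooled over all adjacent gaps).
#'
#' @param map a `genetic_map` (one element of [build_maps()]).
#' @return data.frame.
#' @export
map_summary <- function(map) {
  s <- map$summary
  if (is.null(s) || !nrow(s)) return(s)
  gaps <- unlist(lapply(map$lg, function(l) diff(l$position_cm)))
  total <- data.frame(lg = "total", n_markers = sum(s$n_markers),
                      n_loci = sum(s$n_loci), length_cm = sum(s$length_cm),
                      mean_gap_cm = if (length(gaps)) mean(gaps) else 0,
                      max_gap_cm = if (length(gaps)) max(gaps) else 0,
                      frac_gap_le5 = if (length(gaps)) mean(gaps <= 5) else 1)
  rbind(s, total)
}
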