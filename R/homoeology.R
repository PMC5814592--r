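#' Filter a marker-to-wheat alignment hit table
#'
#' Drops hits above the e-value cutoff, then keeps the best hit per
#' marker per wheat subgenome (A, B, D) and flags each marker's overall
#' best hit. Ties are broken deterministically: lower e-value, higher
#' identity, chromosome name, position.
#'
#' @param hits data.frame with columns `marker_id`, `chrom` (1A..7D),
#'   `bp`, `e_value`, `identity`.
#' @param e_cutoff e-value cutoff (default 1e-05).
#' @return the retained rows with added columns `subgenome`, `group`
#'   (homoeologous group = leading digit) and `top_overall`.
#' @examples
#' h <- data.frame(marker_id = "m1", chrom = c("1A", "1B", "3B"),
#'                 bp = c(10, 20, 30), e_value = c(1e-30, 1e-25, 1e-03),
#'                 identity = 1)
#' filter_hits(h)
#' @export
filter_hits <- function(hits, e_cutoff = 1e-05) {
  req <- c("marker_id", "chrom", "bp", "e_value", "identity")
  if (!all(req %in% names(hits))) {
    stop2("hit table must have columns ", paste(req, collapse = ", "))
  }
  bad <- which(!(hits$chrom %in% WHEAT_CHROMOSOMES) | hits$bp < 0 |
                 !is.finite(hits$e_value) | hits$e_value <= 0)
  if (length(bad)) {
    stop2("malformed hit row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  h <- hits[hits$e_value <= e_cutoff, , drop = FALSE]
  if (!nrow(h)) {
    h$subgenome <- character(0); h$group <- integer(0)
    h$top_overall <- logical(0)
    return(h)
  }
  h$subgenome <- substr(h$chrom, 2, 2)
  h$group <- as.integer(substr(h$chrom, 1, 1))
  h <- h[order(h$marker_id, h$subgenome, h$e_value, -h$identity,
               h$chrom, h$bp), ]
  # best per (marker, subgenome)
  h <- h[!duplicated(h[, c("marker_id", "subgenome")]), ]
  h <- h[order(h$marker_id, h$e_value, -h$identity, h$chrom, h$bp), ]
  h$top_overall <- !duplicated(h$marker_id)
  rownames(h) <- NULL
  h
}

#' Assign linkage groups to wheat homoeologous groups
#'
#' For each linkage group, tallies the homoeologous group (leading digit
#' of the wheat chromosome, A/B/D subgenomes pooled) of its markers'
#' hits and assigns the argmax group; the corresponding P chromosome is
#' named `<group>P`. An ambiguity flag fires when the runner-up group
#' reaches `ambiguity_ratio` of the winner — the signature of a
#' chromosome rearrangement splitting a linkage group's hits between two
#' groups. Per-wheat-chromosome orientation is the sign of the rank
#' correlation between genetic and physical position. The assignment is
#' never silently overridden; resolve a flagged case with external
#' evidence (e.g. verified addition lines) via `overrides`.
#'
#' @param map a `genetic_map` (one element of [build_maps()]).
#' @param hits a [filter_hits()] table.
#' @param ambiguity_ratio runner-up/winner proportion triggering the flag.
#' @param use `"overall"` counts each marker's overall top hit;
#'   `"subgenome"` counts all per-subgenome top hits.
#' @param overrides optional data.frame (`lg`, `assigned_group`) applied
#'   after assignment (recorded in `overridden`).
#' @return list with `assignment` (data.frame: `lg`, `n_hit_markers`,
#'   `assigned_group`, `assigned_p`, `proportion`, `second_group`,
#'   `second_proportion`, `ambiguous`, `overridden`), `proportions`
#'   (LG x group matrix) and `orientation` (data.frame `lg`, `chrom`,
#'   `n`, `rho`, `orientation`).
#' @export
assign_homoeology <- function(map, hits, ambiguity_ratio = 0.5,
                              use = c("overall", "subgenome"),
                              overrides = NULL) {
  use <- match.arg(use)
  h <- if (use == "overall") hits[hits$top_overall, , drop = FALSE] else hits
  tab <- map$table
  if (is.null(tab) || !nrow(tab)) stop2("empty map")
  lgs <- unique(tab$lg)
  prop <- matrix(0, length(lgs), 7, dimnames = list(lgs, as.character(1:7)))
  rows <- list(); orient <- list()
  for (g in lgs) {
    mk <- tab$marker_id[tab$lg == g]
    hh <- h[h$marker_id %in% mk, , drop = FALSE]
    if (!nrow(hh)) {
      warning("linkage group ", g, " has no alignment hits; unassigned",
              call. = FALSE)
      rows[[g]] <- data.frame(lg = g, n_hit_markers = 0L,
                              assigned_group = NA_integer_,
                              assigned_p = NA_character_, proportion = NA_real_,
                              second_group = NA_integer_,
                              second_proportion = NA_real_,
                              ambiguous = NA, overridden = FALSE)
      next
    }
    counts <- table(factor(hh$group, levels = 1:7))
    p <- as.numeric(counts) / sum(counts)
    prop[g, ] <- p
    # tie-break: more distinct supporting wheat chromosomes, then smaller group
    support <- vapply(1:7, function(k)
      length(unique(hh$chrom[hh$group == k])), 0L)
    ord <- order(-p, -support, 1:7)
    win <- ord[1]; second <- ord[2]
    rows[[g]] <- data.frame(
      lg = g, n_hit_markers = length(unique(hh$marker_id)),
      assigned_group = win, assigned_p = paste0(win, "P"),
      proportion = p[win], second_group = second,
      second_proportion = p[second],
      ambiguous = p[second] >= ambiguity_ratio * p[win],
      overridden = FALSE)
    # orientation per wheat chromosome with >= 3 hit markers
    pos <- tab$position_cm[match(hh$marker_id, tab$marker_id)]
    for (ch in unique(hh$chrom)) {
      sel <- hh$chrom == ch
      if (sum(sel) < 3) next
      rho <- suppressWarnings(stats::cor(pos[sel], hh$bp[sel], method = "spearman"))
      if (is.na(rho)) next
      orient[[paste(g, ch)]] <- data.frame(
        lg = g, chrom = ch, n = sum(sel), rho = rho,
        orientation = if (rho >= 0) "forward" else "reverse")
    }
  }
  assignment <- do.call(rbind, rows)
  rownames(assignment) <- NULL
  if (!is.null(overrides)) {
    for (k in seq_len(nrow(overrides))) {
      i <- match(overrides$lg[k], assignment$lg)
      if (is.na(i)) next
      assignment$assigned_group[i] <- overrides$assigned_group[k]
      assignment$assigned_p[i] <- paste0(overrides$assigned_group[k], "P")
      assignment$overridden[i] <- TRUE
    }
  }
  list(assignment = assignment, proportions = prop,
       orientation = if (length(orient)) do.call(rbind, orient)
       else data.frame(lg = character(), chrom = character(), n = integer(),
                       rho = numeric(), orientation = character()))
}

# longest chain monotone in both ranks with a gap constraint, by O(n^2)
# dynamic programming; returns indices of the chain (into the input order)
monotone_chain <- function(bp_rank, direction = 1, max_rank_gap = 3) {
  n <- length(bp_rank)
  if (!n) return(integer(0))
  best_len <- rep(1L, n)
  prev <- rep(0L, n)
  gap <- max_rank_gap + 1
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (i - j > gap) next
      step <- direction * (bp_rank[i] - bp_rank[j])
      if (step <= 0 || step > gap) next
      if (best_len[j] + 1L > best_len[i]) {
        best_len[i] <- best_len[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(best_len)
  chain <- integer(best_len[end])
  k <- best_len[end]
  while (end != 0L) {
    chain[k] <- end
    end <- prev[end]
    k <- k - 1L
  }
  chain
}

#' Detect collinearity blocks and rearrangements
#'
#' For each (linkage group, wheat chromosome) pair, finds maximal marker
#' chains monotone in both map order and physical-position rank
#' (forward or reverse), allowing up to `max_rank_gap` skipped markers
#' between chain neighbours. Chains are extracted greedily (longest
#' first) until none of at least `min_block` markers remains. Retained
#' blocks on a wheat group other than the LG's assigned group are
#' reported as rearrangements; off-group markers not in any block are
#' small-fragment noise.
#'
#' @param map a `genetic_map`.
#' @param hits a [filter_hits()] table (overall top hits are used).
#' @param assignment optional [assign_homoeology()] result used to label
#'   rearrangements; computed on the fly if `NULL`.
#' @param min_block minimum markers per block.
#' @param max_rank_gap maximum skipped markers between chain neighbours.
#' @return list with `blocks` (data.frame: `lg`, `chrom`, `group`,
#'   `n_markers`, `cm_start`, `cm_end`, `bp_start`, `bp_end`,
#'   `orientation`, `rearranged`, `block_id`), `block_markers`
#'   (block_id -> marker ids) and `noise` (off-group markers outside
#'   blocks).
#' @export
detect_synteny_blocks <- function(map, hits, assignment = NULL,
                                  min_block = 5, max_rank_gap = 3) {
  h <- hits[hits$top_overall, , drop = FALSE]
  tab <- map$table
  if (is.null(assignment)) assignment <- assign_homoeology(map, hits)
  asg <- stats::setNames(assignment$assignment$assigned_group,
                         assignment$assignment$lg)
  blocks <- list(); members <- list(); noise <- list()
  bid <- 0L
  for (g in unique(tab$lg)) {
    mk_tab <- tab[tab$lg == g, ]
    hh <- h[h$marker_id %in% mk_tab$marker_id, , drop = FALSE]
    if (!nrow(hh)) next
    hh$cm <- mk_tab$position_cm[match(hh$marker_id, mk_tab$marker_id)]
    for (ch in sort(unique(hh$chrom))) {
      sub <- hh[hh$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$cm, sub$marker_id), ]
      in_block <- rep(FALSE, nrow(sub))
      repeat {
        avail <- which(!in_block)
        if (length(avail) < min_block) break
        s <- sub[avail, ]
        br <- rank(s$bp, ties.method = "first")
        fw <- monotone_chain(br, 1, max_rank_gap)
        rv <- monotone_chain(br, -1, max_rank_gap)
        chain <- if (length(fw) >= length(rv)) fw else rv
        orientation <- if (length(fw) >= length(rv)) "forward" else "reverse"
        if (length(chain) < min_block) break
        sel <- avail[chain]
        in_block[sel] <- TRUE
        bid <- bid + 1L
        grp <- as.integer(substr(ch, 1, 1))
        blocks[[bid]] <- data.frame(
          lg = g, chrom = ch, group = grp,
          n_markers = length(sel),
          cm_start = min(sub$cm[sel]), cm_end = max(sub$cm[sel]),
          bp_start = min(sub$bp[sel]), bp_end = max(sub$bp[sel]),
          orientation = orientation,
          rearranged = !is.na(asg[g]) && grp != asg[g],
          block_id = bid)
        members[[bid]] <- sub$marker_id[sel]
      }
      off <- if (is.na(asg[g])) sub[0, , drop = FALSE]
             else sub[!in_block & sub$group != asg[g], , drop = FALSE]
      if (nrow(off)) noise[[paste(g, ch)]] <- off[, c("marker_id", "chrom", "bp")]
    }
  }
  list(blocks = if (length(blocks)) do.call(rbind, blocks)
       else data.frame(),
       block_markers = members,
       noise = if (length(noise)) do.call(rbind, noise)
       else data.frame(marker_id = character(), chrom = character(),
                       bp = numeric()))
}

#' Rescale a genetic map to pseudo-physical coordinates
#'
#' Linearly maps each linkage group onto a fixed physical length so
#' genetic maps can be drawn against physical wheat chromosomes:
#' `position_bp = position_cm / length_cm * target_bp`.
#'
#' @param map a `genetic_map`.
#' @param target_bp pseudo-length of every chromosome (default 500 Mbp).
#' @return the map's long table with an added `position_bp` column
#'   (zero-length groups map entirely to 0).
#' @export
scale_map_for_comparison <- function(map, target_bp = 500e6) {
  tab <- map$table
  if (is.null(tab) || !nrow(tab)) return(tab)
  out <- do.call(rbind, lapply(split(tab, tab$lg), function(s) {
    len <- max(s$position_cm)
    s$position_bp <- if (len > 0) s$position_cm / len * target_bp else 0
    s
  }))
  rownames(out) <- NULL
  out[order(match(out$lg, unique(tab$lg)), out$locus_index), ]
}
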