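#' Heterozygosity and missingness profile of a derivative line
#'
#' Computes, for one line genotyped on the 21-chromosome wheat
#' background, the per-chromosome heterozygosity ratio (AB calls over
#' called markers), the per-chromosome missing rate on the
#' genome-specific marker subset (only those markers can reveal a
#' missing wheat chromosome — the other probes also hybridise to the
#' homoeologous copies), and sliding-window heterozygosity tracks
#' (default 50 Mb windows advancing by 1 Mb, 0-based half-open, last
#' window clipped at the chromosome end).
#'
#' @param gm a [genotype_matrix()] of role-`line` samples.
#' @param line_id which line (default: first sample).
#' @param marker_map data.frame (`marker`, `chrom`, `bp`,
#'   `genome_specific`), see [default_wheat_marker_map()].
#' @param window_bp,step_bp window and step size in bp.
#' @param min_window_markers windows with fewer called markers are
#'   flagged uninformative (`informative = FALSE`).
#' @param chrom_lengths named vector of chromosome lengths; defaults to
#'   the `chrom_lengths` attribute of `marker_map`, else max marker bp.
#' @return list of class `evidence_track`: `line_id`, `chromosomes`
#'   (data.frame `chrom`, `n_markers`, `n_called`, `het_ratio`,
#'   `n_specific`, `missing_rate`) and `windows` (data.frame `chrom`,
#'   `start`, `end`, `n_called`, `het_ratio`, `informative`).
#'   Ratios over zero called markers are `NA`.
#' @export
het_profile <- function(gm, line_id = NULL, marker_map,
                        window_bp = 50e6, step_bp = 1e6,
                        min_window_markers = 10, chrom_lengths = NULL) {
  if (window_bp < step_bp) stop2("window_bp must be at least step_bp")
  if (is.null(line_id)) line_id <- colnames(gm$geno)[1]
  g <- gm$geno[, line_id]
  mm <- marker_map[match(rownames(gm$geno), marker_map$marker), ]
  if (anyNA(mm$marker)) stop2("genotyped markers missing from marker_map")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- attr(marker_map, "chrom_lengths") %||%
      tapply(marker_map$bp, marker_map$chrom, max)
  }
  chroms <- intersect(WHEAT_CHROMOSOMES, unique(mm$chrom))

  chrom_rows <- list(); win_rows <- list()
  for (ch in chroms) {
    sel <- which(mm$chrom == ch)
    gi <- g[sel]
    called <- !is.na(gi)
    n_called <- sum(called)
    het <- if (n_called > 0) sum(gi == 1L, na.rm = TRUE) / n_called else NA_real_
    spec <- mm$genome_specific[sel]
    n_spec <- sum(spec)
    miss <- if (n_spec > 0) sum(is.na(gi[spec])) / n_spec else NA_real_
    chrom_rows[[ch]] <- data.frame(chrom = ch, n_markers = length(sel),
                                   n_called = n_called, het_ratio = het,
                                   n_specific = n_spec, missing_rate = miss)

    len <- unname(chrom_lengths[ch])
    starts <- if (len <= window_bp) 0 else seq(0, len - window_bp, by = step_bp)
    ends <- pmin(starts + window_bp, len)
    bp <- mm$bp[sel]
    ord <- order(bp)
    bp_s <- bp[ord]
    called_c <- cumsum(c(0, as.integer(called[ord])))
    het_c <- cumsum(c(0, as.integer(!is.na(gi[ord]) & gi[ord] == 1L)))
    lo <- findInterval(starts - 0.5, bp_s)       # markers with bp < start
    # half-open [start, end), except the clipped final window which closes
    # at the chromosome end so that end-position markers are not orphaned
    hi <- ifelse(ends >= len, findInterval(ends + 0.5, bp_s),
                 findInterval(ends - 0.5, bp_s))
    n_call_w <- called_c[hi + 1L] - called_c[lo + 1L]
    n_het_w <- het_c[hi + 1L] - het_c[lo + 1L]
    win_rows[[ch]] <- data.frame(
      chrom = ch, start = starts, end = ends, n_called = n_call_w,
      het_ratio = ifelse(n_call_w > 0, n_het_w / n_call_w, NA_real_),
      informative = n_call_w >= min_window_markers)
  }
  structure(list(line_id = line_id,
                 chromosomes = do.call(rbind, c(chrom_rows, make.row.names = FALSE)),
                 windows = do.call(rbind, c(win_rows, make.row.names = FALSE))),
            class = "evidence_track")
}

# robust z-threshold: values exceeding median + z_min * spread are "hot".
# The MAD spread is floored by the binomial sampling noise of the rates
# (a per-marker ratio over n markers cannot be resolved more finely than
# sqrt(p(1-p)/n)), so a chance low MAD over the 21 chromosomes cannot make
# the threshold tighter than the data support.
hot_by_mad <- function(x, z_min, n = NULL, min_spread = 1e-3) {
  ok <- !is.na(x)
  med <- stats::median(x[ok])
  se_floor <- if (!is.null(n) && any(n > 0, na.rm = TRUE)) {
    sqrt(max(med, 1e-4) * (1 - max(med, 1e-4)) / stats::median(n, na.rm = TRUE))
  } else 0
  spread <- max(stats::mad(x[ok]), se_floor, min_spread)
  !is.na(x) & x > med + z_min * spread
}

#' Call added P chromosomes from a heterozygosity profile
#'
#' Wheat chromosomes whose heterozygosity ratio exceeds a robust
#' threshold (median + `het_z_min` x MAD over the line's chromosomes)
#' are "hot"; each votes for its homoeologous group, and groups are
#' ranked by (number of hot homoeologs, mean excess heterozygosity).
#' With an external alien-pair count (e.g. from GISH: "42W + 4P" means
#' two added pairs) exactly that many top groups are called; otherwise
#' all groups with at least two hot homoeologs.
#'
#' @param track an [het_profile()] evidence track.
#' @param homoeology named vector group (1..7) -> P chromosome name, or
#'   an [assign_homoeology()] assignment; default identity (`"1P"`..).
#' @param expected_alien_count optional number of added P pairs.
#' @param het_z_min robust z threshold (default 5).
#' @return data.frame (`p_chromosome`, `group`, `n_hot`, `score`,
#'   `support`) of called additions, with attribute `hot_chromosomes`.
#'   Zero rows (plus the attribute) when nothing is hot.
#' @export
call_additions <- function(track, homoeology = NULL,
                           expected_alien_count = NULL, het_z_min = 5) {
  ptab <- homoeology_p_table(homoeology)
  ch <- track$chromosomes
  hot <- hot_by_mad(ch$het_ratio, het_z_min, n = ch$n_called)
  med <- stats::median(ch$het_ratio, na.rm = TRUE)
  groups <- as.integer(substr(ch$chrom, 1, 1))
  excess <- pmax(ch$het_ratio - med, 0)
  stat <- data.frame(group = 1:7,
                     n_hot = vapply(1:7, function(g) sum(hot & groups == g), 0L),
                     score = vapply(1:7, function(g) {
                       e <- excess[hot & groups == g]
                       if (length(e)) mean(e) else 0
                     }, 0))
  ord <- order(-stat$n_hot, -stat$score, stat$group)
  if (!is.null(expected_alien_count) && is.na(expected_alien_count)) {
    expected_alien_count <- NULL
  }
  called <- if (!is.null(expected_alien_count)) {
    if (expected_alien_count > 0) stat$group[ord][seq_len(expected_alien_count)]
    else integer(0)
  } else {
    stat$group[stat$n_hot >= 2]
  }
  called <- sort(called[stat$n_hot[match(called, stat$group)] > 0])
  out <- data.frame(
    p_chromosome = ptab[as.character(called)],
    group = called,
    n_hot = stat$n_hot[match(called, stat$group)],
    score = stat$score[match(called, stat$group)],
    support = vapply(called, function(g)
      paste(ch$chrom[hot & groups == g], collapse = ","), ""))
  rownames(out) <- NULL
  attr(out, "hot_chromosomes") <- ch$chrom[hot]
  out
}

#' Call substituted wheat chromosomes from missing-rate evidence
#'
#' Chromosomes whose genome-specific missing rate exceeds
#' median + `missing_z_min` x MAD are substitution candidates. A
#' candidate is called only when it is homoeologous to a called P
#' addition (its alien pair replaced it); candidates without such a
#' partner are reported as unexplained missingness, not called.
#'
#' @param track an [het_profile()] evidence track.
#' @param additions result of [call_additions()].
#' @param homoeology as in [call_additions()].
#' @param missing_z_min robust z threshold (default 5).
#' @return data.frame (`wheat_chrom`, `p_chromosome`, `missing_rate`)
#'   with attribute `unexplained` (character vector).
#' @export
call_substitutions <- function(track, additions, homoeology = NULL,
                               missing_z_min = 5) {
  ptab <- homoeology_p_table(homoeology)
  ch <- track$chromosomes
  hot <- hot_by_mad(ch$missing_rate, missing_z_min, n = ch$n_specific)
  cand <- ch$chrom[hot]
  grp <- as.integer(substr(cand, 1, 1))
  paired <- grp %in% additions$group
  out <- data.frame(wheat_chrom = cand[paired],
                    p_chromosome = ptab[as.character(grp[paired])],
                    missing_rate = ch$missing_rate[hot][paired])
  rownames(out) <- NULL
  attr(out, "unexplained") <- cand[!paired]
  out
}

homoeology_p_table <- function(homoeology) {
  if (is.null(homoeology)) {
    return(stats::setNames(paste0(1:7, "P"), 1:7))
  }
  if (is.data.frame(homoeology)) {           # assign_homoeology() assignment
    ok <- !is.na(homoeology$assigned_group)
    return(stats::setNames(homoeology$assigned_p[ok],
                           homoeology$assigned_group[ok]))
  }
  stats::setNames(names(homoeology), unname(homoeology))
}

#' Compose the identification label of a derivative line
#'
#' Deterministic label from the called sets, e.g. `"1P addition line"`,
#' `"1P and 2P addition line"`, `"6P/6D substitution line"` or
#' `"2P addition and 1P/1A substitution line"`.
#'
#' @param additions character vector of added P chromosomes.
#' @param substitutions `NULL` or data.frame with columns `p` (the P
#'   chromosome) and `wheat` (the substituted wheat chromosome).
#' @return a single character string (`"no alien chromosome detected"`
#'   when both sets are empty).
#' @export
introgression_label <- function(additions, substitutions = NULL) {
  subs <- if (is.null(substitutions) || !nrow(substitutions)) NULL
          else substitutions[order(substitutions$p), , drop = FALSE]
  pure_add <- sort(setdiff(additions, subs$p))
  parts <- character(0)
  if (length(pure_add)) {
    parts <- paste(paste(pure_add, collapse = " and "), "addition")
  }
  if (!is.null(subs)) {
    parts <- c(parts, paste0(subs$p, "/", subs$wheat, " substitution"))
  }
  if (!length(parts)) return("no alien chromosome detected")
  paste(paste(parts, collapse = " and "), "line")
}

#' Identify additions and substitutions across a panel of lines
#'
#' Profiles every line, calls added P chromosomes and substituted wheat
#' chromosomes, and assembles a characterisation report (one row per
#' line: composition metadata, additional alien chromosomes, missing
#' wheat chromosomes, identification result).
#'
#' @param gm a [genotype_matrix()] of `line` samples.
#' @param marker_map wheat marker scaffold.
#' @param homoeology as in [call_additions()].
#' @param expected_counts optional named integer vector (line id ->
#'   number of added alien pairs, from cytology).
#' @param compositions optional named character vector of chromosome
#'   compositions (metadata echoed into the report).
#' @param het_z_min,missing_z_min robust z thresholds.
#' @param window_bp,step_bp,min_window_markers window track parameters.
#' @return list with `report` (data.frame: `line_id`, `composition`,
#'   `additions`, `missing`, `label`) and `tracks` (named list of
#'   evidence tracks for plotting).
#' @export
batch_report <- function(gm, marker_map, homoeology = NULL,
                         expected_counts = NULL, compositions = NULL,
                         het_z_min = 5, missing_z_min = 5,
                         window_bp = 50e6, step_bp = 1e6,
                         min_window_markers = 10) {
  lines <- colnames(gm$geno)
  if (!length(lines)) {
    return(list(report = data.frame(line_id = character(),
                                    composition = character(),
                                    additions = character(),
                                    missing = character(),
                                    label = character()),
                tracks = list()))
  }
  rows <- list(); tracks <- list()
  for (ln in lines) {
    tr <- het_profile(gm, ln, marker_map, window_bp, step_bp,
                      min_window_markers)
    adds <- call_additions(tr, homoeology,
                           expected_alien_count = expected_counts[ln],
                           het_z_min = het_z_min)
    subs <- call_substitutions(tr, adds, homoeology, missing_z_min)
    sub_df <- if (nrow(subs)) data.frame(p = subs$p_chromosome,
                                         wheat = subs$wheat_chrom) else NULL
    rows[[ln]] <- data.frame(
      line_id = ln,
      composition = if (is.null(compositions)) NA_character_
                    else unname(compositions[ln]),
      additions = paste(sort(adds$p_chromosome), collapse = ","),
      missing = paste(sort(subs$wheat_chrom), collapse = ","),
      label = introgression_label(adds$p_chromosome, sub_df))
    tracks[[ln]] <- tr
  }
  list(report = do.call(rbind, c(rows, make.row.names = FALSE)),
       tracks = tracks)
}
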