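#' Default homoeology scheme
#'
#' The bijection between P-genome chromosomes and wheat homoeologous
#' groups assumed by the generators: `1P -> 1`, ..., `7P -> 7`.
#'
#' @param n number of chromosomes/groups.
#' @return Named integer vector mapping `"1P".."7P"` to groups `1..7`.
#' @export
default_homoeology_scheme <- function(n = 7) {
  stats::setNames(seq_len(n), paste0(seq_len(n), "P"))
}

#' Default structural rearrangement for simulated hit tables
#'
#' A segment covering the proximal 40% of chromosome 4P whose markers hit
#' wheat homoeologous group 2 instead of group 4 — the rearrangement
#' signature that makes the group-4 linkage group's hits split between
#' groups 4 and 2.
#'
#' @param truth a [sim_map_truth()] object.
#' @param chromosome source P chromosome.
#' @param fraction fraction of the chromosome (from 0 cM) rearranged.
#' @param target_group wheat homoeologous group receiving the segment.
#' @return A list with one rearrangement segment
#'   (`chromosome`, `start_cm`, `end_cm`, `target_group`), or an empty
#'   list when the chromosome is absent from `truth`.
#' @export
default_rearrangement <- function(truth, chromosome = "4P", fraction = 0.4,
                                  target_group = 2L) {
  i <- match(chromosome, truth$chromosomes$name)
  if (is.na(i)) return(list())
  list(list(chromosome = chromosome, start_cm = 0,
            end_cm = fraction * truth$chromosomes$length_cm[i],
            target_group = as.integer(target_group)))
}

#' Simulate a marker-to-wheat alignment hit table
#'
#' Emulates BLAST hits of SNP marker flanking sequences against a
#' hexaploid wheat assembly. Each marker receives a top hit on a wheat
#' chromosome of its true homoeologous group (subgenome A/B/D uniform),
#' with a physical position increasing along the chromosome with genetic
#' position so that collinearity blocks exist. Markers inside a
#' rearrangement segment hit the alternate group instead; a `noise_rate`
#' fraction hits a uniformly random wheat chromosome ("small-fragment"
#' noise). Secondary hits on the other two subgenomes and occasional
#' above-cutoff junk rows are emitted so that hit filtering is exercised.
#'
#' @param truth a [sim_map_truth()] object.
#' @param scheme named vector, P chromosome -> wheat group (bijection),
#'   see [default_homoeology_scheme()].
#' @param rearrangements list of segments (`chromosome`, `start_cm`,
#'   `end_cm`, `target_group`); segments on one chromosome must not
#'   overlap. Default: the 4P -> group 2 segment.
#' @param noise_rate probability a marker's top hit is random.
#' @param chrom_bp physical length assumed for every wheat chromosome.
#' @param secondary_rate probability of emitting each secondary-subgenome hit.
#' @param junk_rate probability of an extra above-cutoff row per marker.
#' @param seed integer seed.
#' @return A data.frame (`marker_id`, `chrom`, `bp`, `e_value`,
#'   `identity`) in the HitTable TSV dialect.
#' @examples
#' tr <- sim_map_truth(markers_per_chromosome = 10, seed = 1)
#' ht <- simulate_hit_table(tr, noise_rate = 0, rearrangements = list(), seed = 1)
#' head(ht)
#' @export
simulate_hit_table <- function(truth,
                               scheme = default_homoeology_scheme(nrow(truth$chromosomes)),
                               rearrangements = default_rearrangement(truth),
                               noise_rate = 0.15,
                               chrom_bp = 600e6,
                               secondary_rate = 0.7,
                               junk_rate = 0.1,
                               seed = 1) {
  pn <- truth$chromosomes$name
  if (!all(pn %in% names(scheme)) || anyDuplicated(scheme[pn])) {
    stop2("scheme must be a bijection from P chromosomes to groups")
  }
  # reject overlapping rearrangement segments on the same chromosome
  if (length(rearrangements)) {
    seg <- do.call(rbind, lapply(rearrangements, function(s)
      data.frame(chromosome = s$chromosome, start = s$start_cm, end = s$end_cm)))
    for (ch in unique(seg$chromosome)) {
      s <- seg[seg$chromosome == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
        stop2("overlapping rearrangement segments on ", ch)
      }
    }
  }
  set.seed(substream_seed(seed, "hit_table"))
  mk <- truth$markers
  lens <- stats::setNames(truth$chromosomes$length_cm, pn)

  group <- unname(scheme[mk$chromosome])
  in_rearr <- rep(FALSE, nrow(mk))
  rearr_to <- rep(NA_integer_, nrow(mk))
  rearr_frac <- rep(NA_real_, nrow(mk))   # position within the segment
  for (s in rearrangements) {
    sel <- mk$chromosome == s$chromosome &
      mk$true_cm >= s$start_cm & mk$true_cm < s$end_cm
    in_rearr[sel] <- TRUE
    rearr_to[sel] <- s$target_group
    rearr_frac[sel] <- (mk$true_cm[sel] - s$start_cm) / max(s$end_cm - s$start_cm, 1e-9)
  }
  group[in_rearr] <- rearr_to[in_rearr]

  is_noise <- stats::runif(nrow(mk)) < noise_rate
  sub <- sample(WHEAT_SUBGENOMES, nrow(mk), replace = TRUE)
  chrom <- paste0(group, sub)
  chrom[is_noise] <- sample(WHEAT_CHROMOSOMES, sum(is_noise), replace = TRUE)

  # physical position: monotone in cM for syntenic hits (small jitter),
  # rearranged segments land in the proximal 30% of the target chromosome
  frac <- mk$true_cm / pmax(lens[mk$chromosome], 1e-9)
  bp <- frac * chrom_bp
  bp[in_rearr] <- rearr_frac[in_rearr] * 0.3 * chrom_bp
  bp <- bp + stats::runif(nrow(mk), -5e5, 5e5)
  bp[is_noise] <- stats::runif(sum(is_noise), 0, chrom_bp)
  bp <- pmin(pmax(round(bp), 0), chrom_bp)

  top <- data.frame(marker_id = mk$id, chrom = chrom, bp = bp,
                    e_value = 10^-stats::runif(nrow(mk), 10, 50),
                    identity = stats::runif(nrow(mk), 0.95, 1))

  # weaker secondary hits on the other two subgenomes of the same group
  sec <- do.call(rbind, lapply(seq_len(nrow(mk)), function(i) {
    others <- setdiff(WHEAT_SUBGENOMES, sub[i])
    keep <- others[stats::runif(2) < secondary_rate]
    if (!length(keep) || is_noise[i]) return(NULL)
    data.frame(marker_id = mk$id[i],
               chrom = paste0(group[i], keep),
               bp = pmin(pmax(round(bp[i] + stats::runif(length(keep), -2e6, 2e6)), 0), chrom_bp),
               e_value = top$e_value[i] * 10^stats::runif(length(keep), 2, 8),
               identity = stats::runif(length(keep), 0.90, 0.99))
  }))

  junk_n <- stats::rbinom(1, nrow(mk), junk_rate)
  junk <- if (junk_n > 0) {
    data.frame(marker_id = sample(mk$id, junk_n),
               chrom = sample(WHEAT_CHROMOSOMES, junk_n, replace = TRUE),
               bp = round(stats::runif(junk_n, 0, chrom_bp)),
               e_value = 10^-stats::runif(junk_n, 0, 4.9),
               identity = stats::runif(junk_n, 0.7, 0.9))
  } else NULL

  out <- rbind(top, sec, junk)
  out <- out[order(out$marker_id, out$e_value), ]
  rownames(out) <- NULL
  out
}
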