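#' Define the true map underlying a simulated CP cross
#'
#' Builds the ground-truth chromosome/marker layout for the synthetic
#' CP (outbred F1) population: seven P-genome chromosomes carrying a mix
#' of the three informative CP segregation patterns (`hkxhk`: both parents
#' heterozygous; `lmxll`: father-only; `nnxnp`: mother-only).
#'
#' Defaults emulate the mapping population the pipeline targets: seven
#' linkage groups averaging 120 cM, with the pattern mix 45/27/28%
#' matching the relative frequencies observed on a wheat SNP array screen
#' of such a cross.
#'
#' @param n_chromosomes number of chromosomes (named `1P`, `2P`, ...).
#' @param markers_per_chromosome markers simulated per chromosome.
#' @param length_cm chromosome length(s) in cM (recycled).
#' @param pattern_mix named numeric vector of pattern proportions over
#'   `hkxhk`, `lmxll`, `nnxnp`; must sum to 1.
#' @param distorted_fraction fraction of markers flagged as subject to
#'   segregation distortion.
#' @param seed integer seed (marker placement and pattern assignment).
#' @return A list of class `sim_map_truth` with elements `chromosomes`
#'   (data.frame: `name`, `length_cm`) and `markers` (data.frame: `id`,
#'   `chromosome`, `true_cm`, `pattern`, `distorted`).
#' @examples
#' tr <- sim_map_truth(markers_per_chromosome = 20, seed = 1)
#' table(tr$markers$pattern)
#' @export
sim_map_truth <- function(n_chromosomes = 7,
                          markers_per_chromosome = 100,
                          length_cm = 120,
                          pattern_mix = c(hkxhk = 0.45, lmxll = 0.27, nnxnp = 0.28),
                          distorted_fraction = 0.05,
                          seed = 1) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 2)
  if (!setequal(names(pattern_mix), CP_PATTERNS) ||
      abs(sum(pattern_mix) - 1) > 1e-8) {
    stop2("pattern_mix must be named over ", paste(CP_PATTERNS, collapse = "/"),
          " and sum to 1")
  }
  length_cm <- rep_len(length_cm, n_chromosomes)
  if (any(length_cm < 0)) stop2("chromosome length_cm must be >= 0")
  set.seed(substream_seed(seed, "map_truth"))
  chromosomes <- data.frame(name = paste0(seq_len(n_chromosomes), "P"),
                            length_cm = length_cm)
  markers <- do.call(rbind, lapply(seq_len(n_chromosomes), function(c_i) {
    L <- length_cm[c_i]
    pos <- sort(stats::runif(markers_per_chromosome, 0, L))
    # guarantee >= 2 patterns per chromosome by cycling through a
    # randomly permuted pattern pool of the right mix
    pool <- sample(rep(CP_PATTERNS,
                       times = pmax(1, round(pattern_mix * markers_per_chromosome))))
    pool <- pool[seq_len(markers_per_chromosome)]
    data.frame(
      id = sprintf("M%s_%03d", chromosomes$name[c_i], seq_len(markers_per_chromosome)),
      chromosome = chromosomes$name[c_i],
      true_cm = pos,
      pattern = pool,
      distorted = stats::runif(markers_per_chromosome) < distorted_fraction
    )
  }))
  rownames(markers) <- NULL
  out <- list(chromosomes = chromosomes, markers = markers)
  class(out) <- "sim_map_truth"
  validate_map_truth(out)
  out
}

validate_map_truth <- function(truth) {
  if (anyDuplicated(truth$markers$id)) stop2("marker ids must be unique")
  if (any(truth$chromosomes$length_cm < 0)) stop2("negative chromosome length")
  m <- merge(truth$markers, truth$chromosomes,
             by.x = "chromosome", by.y = "name")
  if (any(m$true_cm < 0 | m$true_cm > m$length_cm)) {
    stop2("marker true_cm outside [0, length_cm]")
  }
  npat <- tapply(truth$markers$pattern, truth$markers$chromosome,
                 function(p) length(unique(p)))
  if (any(npat < 2)) {
    warning("some chromosome carries a single segregation pattern; ",
            "male and female maps cannot both cover it", call. = FALSE)
  }
  invisible(truth)
}

#' Simulation settings for a CP cross
#'
#' @param n_progeny number of F1 progeny (default 119, the size of the
#'   mapping population the pipeline targets).
#' @param genotyping_error_rate probability that a call is replaced by a
#'   uniformly chosen different call.
#' @param missing_rate probability that a progeny call is missing (`NC`).
#' @param distortion_strength transmission skew applied at markers flagged
#'   `distorted`: the favoured allele of the distorted meiosis is
#'   transmitted with probability `0.5 + distortion_strength/2`.
#' @param seed master seed for the cross.
#' @return A list of class `sim_cross_config`.
#' @export
sim_cross_config <- function(n_progeny = 119,
                             genotyping_error_rate = 0.01,
                             missing_rate = 0.15,
                             distortion_strength = 0.6,
                             seed = 1) {
  probs <- c(genotyping_error_rate, missing_rate)
  if (any(probs < 0 | probs >= 1)) stop2("rates must be in [0, 1)")
  if (n_progeny < 2) stop2("n_progeny must be >= 2")
  if (distortion_strength < 0 || distortion_strength > 1) {
    stop2("distortion_strength must be in [0, 1]")
  }
  structure(list(n_progeny = as.integer(n_progeny),
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate,
                 distortion_strength = distortion_strength,
                 seed = seed),
            class = "sim_cross_config")
}

# simulate one meiotic product along a chromosome: returns the haplotype
# index (0/1) transmitted at each position. Crossovers: Poisson(L/100),
# uniform positions, no interference.
sim_gamete <- function(positions, length_cm) {
  n_xo <- stats::rpois(1, length_cm / 100)
  start <- sample(0:1, 1)
  if (n_xo == 0L) return(rep.int(start, length(positions)))
  xo <- sort(stats::runif(n_xo, 0, length_cm))
  (start + findInterval(positions, xo)) %% 2L
}

#' Simulate genotypes for a CP mapping population
#'
#' Simulates an outbred F1 population from two heterozygous parents.
#' Parent genotypes follow each marker's segregation pattern
#' (`hkxhk`: both parents AB; `lmxll`: father AB, mother AA;
#' `nnxnp`: father AA, mother AB). Each progeny receives one paternal and
#' one maternal meiotic product per chromosome; crossover counts are
#' Poisson(length/100) with uniform positions and no interference.
#' Genotyping error then replaces calls by a uniformly chosen different
#' call, and missingness is applied independently; both affect progeny
#' only, so the parental rows carry the pattern truth.
#'
#' Markers flagged `distorted` in the truth skew the transmission of the
#' heterozygous parent's `A` allele (for `hkxhk`, the father's): the
#' transmitted allele is overridden to `A` with probability
#' `distortion_strength`, giving marginal transmission
#' `0.5 + distortion_strength/2`.
#'
#' @param truth a [sim_map_truth()] object.
#' @param cfg a [sim_cross_config()] object.
#' @return A list with `gm` (a [genotype_matrix()] with father, mother and
#'   progeny), and `truth`: `phase_father`/`phase_mother` (named 0/1
#'   vectors: allele carried on haplotype 0 at heterozygous markers),
#'   `crossovers` (per parent, per chromosome, list of crossover position
#'   vectors per progeny) and the input map truth.
#' @examples
#' tr <- sim_map_truth(markers_per_chromosome = 10, seed = 2)
#' sim <- simulate_cp_cross(tr, sim_cross_config(n_progeny = 20, seed = 2))
#' dim(sim$gm)
#' @export
simulate_cp_cross <- function(truth, cfg = sim_cross_config()) {
  stopifnot(inherits(truth, "sim_map_truth"), inherits(cfg, "sim_cross_config"))
  validate_map_truth(truth)
  if (any(truth$chromosomes$length_cm < 0)) stop2("negative chromosome length")
  if (cfg$n_progeny < 2) stop2("n_progeny must be >= 2")
  set.seed(substream_seed(cfg$seed, "cp_cross"))

  mk <- truth$markers
  n_prog <- cfg$n_progeny
  n_mark <- nrow(mk)
  prog_ids <- sprintf("F1_%03d", seq_len(n_prog))

  # parental phase: allele (0 = A, 1 = B) carried on haplotype 0, per marker
  phase_f <- ifelse(mk$pattern %in% c("hkxhk", "lmxll"),
                    sample(0:1, n_mark, replace = TRUE), NA_integer_)
  phase_m <- ifelse(mk$pattern %in% c("hkxhk", "nnxnp"),
                    sample(0:1, n_mark, replace = TRUE), NA_integer_)
  names(phase_f) <- names(phase_m) <- mk$id

  geno <- matrix(NA_integer_, n_mark, n_prog, dimnames = list(mk$id, prog_ids))
  xo_f <- xo_m <- list()

  for (c_i in seq_len(nrow(truth$chromosomes))) {
    chrom <- truth$chromosomes$name[c_i]
    L <- truth$chromosomes$length_cm[c_i]
    idx <- which(mk$chromosome == chrom)
    pos <- mk$true_cm[idx]
    pat <- mk$pattern[idx]
    dis <- mk$distorted[idx]

    all_f <- matrix(0L, length(idx), n_prog)  # transmitted paternal allele
    all_m <- matrix(0L, length(idx), n_prog)
    xo_f[[chrom]] <- vector("list", n_prog)
    xo_m[[chrom]] <- vector("list", n_prog)
    for (p in seq_len(n_prog)) {
      # record crossover points alongside the haplotype product
      n_xo <- stats::rpois(1, L / 100); xo <- sort(stats::runif(n_xo, 0, L))
      start <- sample(0:1, 1)
      h_f <- (start + findInterval(pos, xo)) %% 2L
      xo_f[[chrom]][[p]] <- xo
      n_xo <- stats::rpois(1, L / 100); xo <- sort(stats::runif(n_xo, 0, L))
      start <- sample(0:1, 1)
      h_m <- (start + findInterval(pos, xo)) %% 2L
      xo_m[[chrom]][[p]] <- xo

      # heterozygous parents transmit phase XOR haplotype; homozygous
      # parents transmit their fixed allele (A for lmxll mother / nnxnp father)
      f_allele <- ifelse(pat %in% c("hkxhk", "lmxll"),
                         (phase_f[idx] + h_f) %% 2L, 0L)
      m_allele <- ifelse(pat %in% c("hkxhk", "nnxnp"),
                         (phase_m[idx] + h_m) %% 2L, 0L)
      all_f[, p] <- f_allele
      all_m[, p] <- m_allele
    }

    # segregation distortion: favoured allele (A) of the distorted meiosis
    if (any(dis) && cfg$distortion_strength > 0) {
      d_idx <- which(dis)
      for (k in d_idx) {
        hit <- stats::runif(n_prog) < cfg$distortion_strength
        if (pat[k] %in% c("hkxhk", "lmxll")) all_f[k, hit] <- 0L
        else all_m[k, hit] <- 0L
      }
    }
    geno[idx, ] <- all_f + all_m
  }

  # genotyping error: replace by a uniformly chosen *different* call
  if (cfg$genotyping_error_rate > 0) {
    err <- which(stats::runif(length(geno)) < cfg$genotyping_error_rate)
    if (length(err)) {
      old <- geno[err]
      shift <- sample(1:2, length(err), replace = TRUE)
      geno[err] <- (old + shift) %% 3L
    }
  }
  if (cfg$missing_rate > 0) {
    geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_
  }

  father <- ifelse(mk$pattern %in% c("hkxhk", "lmxll"), 1L, 0L)
  mother <- ifelse(mk$pattern %in% c("hkxhk", "nnxnp"), 1L, 0L)
  calls <- cbind(Father = father, Mother = mother, geno)
  gm <- genotype_matrix(calls, c("father", "mother", rep("progeny", n_prog)))

  list(gm = gm,
       truth = list(map = truth, phase_father = phase_f, phase_mother = phase_m,
                    crossovers = list(father = xo_f, mother = xo_m)))
}
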