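#' Marker scaffold on the 21 wheat chromosomes
#'
#' Builds the wheat-background marker map used to simulate and profile
#' derivative lines: uniformly spaced markers on each of 1A..7D, with a
#' subset flagged as A/B/D genome-specific (those markers are the ones
#' used to detect a missing wheat chromosome).
#'
#' @param markers_per_chrom markers per wheat chromosome.
#' @param chrom_bp physical chromosome length in bp (all chromosomes).
#' @param specific_frac fraction of markers flagged genome-specific.
#' @param seed integer seed (which markers are genome-specific).
#' @return data.frame (`marker`, `chrom`, `bp`, `genome_specific`) with
#'   attribute `chrom_lengths` (named vector).
#' @export
default_wheat_marker_map <- function(markers_per_chrom = 300,
                                     chrom_bp = 600e6,
                                     specific_frac = 0.3,
                                     seed = 1) {
  set.seed(substream_seed(seed, "wheat_map"))
  out <- do.call(rbind, lapply(WHEAT_CHROMOSOMES, function(ch) {
    data.frame(marker = sprintf("W%s_%04d", ch, seq_len(markers_per_chrom)),
               chrom = ch,
               bp = round(seq(1, chrom_bp, length.out = markers_per_chrom)),
               genome_specific = stats::runif(markers_per_chrom) < specific_frac)
  }))
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- stats::setNames(rep(chrom_bp, 21), WHEAT_CHROMOSOMES)
  out
}

#' Specification of one simulated derivative line
#'
#' Describes the true composition of a wheat-alien derivative line:
#' which P chromosomes are added (as a disomic pair) and which wheat
#' chromosomes are substituted by their homoeologous P pair. Markers on
#' the three wheat homoeologs of an added P chromosome show elevated
#' heterozygous calls (array probes cross-hybridising with the alien
#' homoeolog), and markers on a substituted wheat chromosome show
#' elevated missingness.
#'
#' @param line_id line identifier.
#' @param additions character vector of added P chromosomes (`"1P"`..).
#' @param substitutions data.frame with columns `p` and `wheat`
#'   (e.g. `6P`, `6D`), or `NULL`. Each substituted wheat chromosome must
#'   be homoeologous to its paired P chromosome under `scheme`, and the
#'   paired P chromosome must be in `additions`.
#' @param baseline_het,homoeolog_het per-marker probability of an AB call
#'   off/on homoeologs of added P chromosomes.
#' @param baseline_missing,substituted_missing per-marker no-call
#'   probability off/on substituted wheat chromosomes.
#' @return A list of class `sim_line_spec`.
#' @export
line_spec <- function(line_id, additions = character(),
                      substitutions = NULL,
                      baseline_het = 0.01, homoeolog_het = 0.15,
                      baseline_missing = 0.05, substituted_missing = 0.6) {
  if (homoeolog_het <= baseline_het) stop2("homoeolog_het must exceed baseline_het")
  if (substituted_missing <= baseline_missing) {
    stop2("substituted_missing must exceed baseline_missing")
  }
  if (!is.null(substitutions)) {
    stopifnot(is.data.frame(substitutions), all(c("p", "wheat") %in% names(substitutions)))
    if (!all(substitutions$p %in% additions)) {
      stop2("every substitution's P chromosome must also be listed in additions")
    }
  }
  structure(list(line_id = line_id, additions = additions,
                 substitutions = substitutions,
                 baseline_het = baseline_het, homoeolog_het = homoeolog_het,
                 baseline_missing = baseline_missing,
                 substituted_missing = substituted_missing),
            class = "sim_line_spec")
}

#' A synthetic 35-line addition/substitution panel
#'
#' Line specifications mirroring the composition of a published panel of
#' wheat-*Agropyron cristatum* derivatives: 26 disomic addition lines
#' (1x1P, 6x2P, 7x4P, 1x5P, 4x6P, 7x7P), three double disomic additions
#' (two 1P+2P, one 2P+5P), substitution lines 3P/3B, 6P/6D, two 7P/7D and
#' 7P/7A, and one line combining a 2P addition with a 1P/1A substitution.
#'
#' @param ... default rate overrides passed to [line_spec()].
#' @return list of [line_spec()] objects (length 35) with a
#'   `composition` attribute per line (e.g. `"42W + 2P"`).
#' @export
example_line_panel <- function(...) {
  add <- function(id, p, comp = "42W + 2P") {
    s <- line_spec(id, additions = p, ...)
    attr(s, "composition") <- comp
    s
  }
  sub <- function(id, p, w, comp = "40W + 2P") {
    s <- line_spec(id, additions = p,
                   substitutions = data.frame(p = p, wheat = w), ...)
    attr(s, "composition") <- comp
    s
  }
  panel <- c(
    list(add("L01_1P", "1P")),
    lapply(sprintf("L%02d_2P", 2:7), add, p = "2P"),
    lapply(sprintf("L%02d_4P", 8:14), add, p = "4P"),
    list(add("L15_5P", "5P")),
    lapply(sprintf("L%02d_6P", 16:19), add, p = "6P"),
    lapply(sprintf("L%02d_7P", 20:26), add, p = "7P"),
    list(add("L27_1P2P", c("1P", "2P"), comp = "42W + 4P"),
         add("L28_1P2P", c("1P", "2P"), comp = "42W + 4P"),
         add("L29_2P5P", c("2P", "5P"), comp = "42W + 4P"),
         sub("L30_3P3B", "3P", "3B"),
         sub("L31_6P6D", "6P", "6D"),
         sub("L32_7P7D", "7P", "7D"),
         sub("L33_7P7D", "7P", "7D"),
         sub("L34_7P7A", "7P", "7A")),
    list({
      s <- line_spec("L35_2Padd_1P1Asub", additions = c("1P", "2P"),
                     substitutions = data.frame(p = "1P", wheat = "1A"), ...)
      attr(s, "composition") <- "40W + 4P"
      s
    })
  )
  panel
}

#' Ground-truth composition table of a line panel
#'
#' @param specs list of [line_spec()] objects.
#' @return data.frame (`line_id`, `composition`, `additions`,
#'   `missing`, `label`) with sets collapsed as comma-separated strings.
#' @export
panel_truth <- function(specs) {
  do.call(rbind, lapply(specs, function(s) {
    subs <- s$substitutions
    data.frame(line_id = s$line_id,
               composition = attr(s, "composition") %||% NA_character_,
               additions = paste(sort(s$additions), collapse = ","),
               missing = if (is.null(subs)) "" else paste(sort(subs$wheat), collapse = ","),
               label = introgression_label(
                 s$additions,
                 if (is.null(subs)) NULL else subs))
  }))
}

#' Simulate genotypes of wheat-alien derivative lines
#'
#' For each line, every wheat marker starts as a homozygous background
#' call (`AA`). Markers on the three wheat homoeologs of each added P
#' chromosome become `AB` with probability `homoeolog_het`
#' (`baseline_het` elsewhere); markers on each substituted wheat
#' chromosome become no-calls with probability `substituted_missing`
#' (`baseline_missing` elsewhere).
#'
#' @param specs list of [line_spec()] objects.
#' @param wheat_marker_map marker scaffold, see [default_wheat_marker_map()].
#' @param scheme homoeology scheme, see [default_homoeology_scheme()].
#' @param seed integer seed.
#' @return list with `gm` (a [genotype_matrix()], samples of role `line`)
#'   and `truth` (the [panel_truth()] table).
#' @examples
#' wm <- default_wheat_marker_map(markers_per_chrom = 40)
#' sim <- simulate_introgression_lines(list(line_spec("x", "6P")), wm, seed = 1)
#' @export
simulate_introgression_lines <- function(specs, wheat_marker_map = default_wheat_marker_map(),
                                         scheme = default_homoeology_scheme(),
                                         seed = 1) {
  set.seed(substream_seed(seed, "introgression_lines"))
  wm <- wheat_marker_map
  group_of_chrom <- as.integer(substr(wm$chrom, 1, 1))
  geno <- matrix(NA_integer_, nrow(wm), length(specs),
                 dimnames = list(wm$marker, vapply(specs, `[[`, "", "line_id")))
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    bad <- setdiff(s$additions, names(scheme))
    if (length(bad)) stop2("unknown chromosome in spec: ", paste(bad, collapse = ", "))
    if (!is.null(s$substitutions)) {
      if (!all(s$substitutions$wheat %in% WHEAT_CHROMOSOMES)) {
        stop2("unknown wheat chromosome in substitutions for ", s$line_id)
      }
      sub_group <- as.integer(substr(s$substitutions$wheat, 1, 1))
      if (!all(sub_group == unname(scheme[s$substitutions$p]))) {
        stop2("substituted wheat chromosome not homoeologous to its P pair (",
              s$line_id, ")")
      }
    }
    hot_groups <- unname(scheme[s$additions])
    p_het <- ifelse(group_of_chrom %in% hot_groups, s$homoeolog_het, s$baseline_het)
    g <- ifelse(stats::runif(nrow(wm)) < p_het, 1L, 0L)
    p_miss <- rep(s$baseline_missing, nrow(wm))
    if (!is.null(s$substitutions)) {
      p_miss[wm$chrom %in% s$substitutions$wheat] <- s$substituted_missing
    }
    g[stats::runif(nrow(wm)) < p_miss] <- NA_integer_
    geno[, k] <- g
  }
  gm <- genotype_matrix(geno, rep("line", length(specs)))
  list(gm = gm, truth = panel_truth(specs))
}
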