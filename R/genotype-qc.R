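#' Per-marker and per-sample call rates
#'
#' The call rate is the fraction of non-missing calls. Samples and
#' markers falling below their thresholds are flagged; a relaxed 80%
#' variant threshold (rather than the array default of 97%) is
#' appropriate when hybridising a wild relative to a wheat array.
#'
#' @param gm a [genotype_matrix()].
#' @param marker_threshold,sample_threshold call-rate thresholds.
#' @return list with data.frames `markers` (`marker_id`, `call_rate`,
#'   `below_threshold`) and `samples` (`sample_id`, `role`, `call_rate`,
#'   `below_threshold`).
#' @examples
#' tr <- sim_map_truth(markers_per_chromosome = 5, seed = 1)
#' sim <- simulate_cp_cross(tr, sim_cross_config(n_progeny = 10, seed = 1))
#' call_rates(sim$gm)$samples
#' @export
call_rates <- function(gm, marker_threshold = 0.8, sample_threshold = 0.8) {
  if (nrow(gm$geno) == 0 || ncol(gm$geno) == 0) stop2("empty genotype matrix")
  called <- !is.na(gm$geno)
  mr <- rowMeans(called)
  sr <- colMeans(called)
  list(markers = data.frame(marker_id = rownames(gm$geno), call_rate = mr,
                            below_threshold = mr < marker_threshold,
                            row.names = NULL),
       samples = data.frame(sample_id = colnames(gm$geno),
                            role = unname(gm$roles), call_rate = sr,
                            below_threshold = sr < sample_threshold,
                            row.names = NULL))
}

#' SNP performance categories from genotype calls
#'
#' Re-expresses the array performance categories at genotype level:
#' \describe{
#'   \item{CallRateBelowThreshold}{call rate below `call_rate_threshold`.}
#'   \item{MonoHighResolution}{a single genotype class observed (monomorphic).}
#'   \item{PolyHighResolution}{codominant polymorphic: both homozygote
#'     classes observed and at least `min_minor_carriers` samples carry
#'     the minor allele (a heterozygote counts as one carrier).}
#'   \item{NoMinorHomozygote}{polymorphic but dominant: exactly two
#'     genotype classes with one homozygote class absent.}
#'   \item{OffTargetVariant}{cannot be derived from calls (needs probe
#'     intensities); assigned only via the optional `otv_labels`
#'     pass-through.}
#'   \item{Other}{anything else.}
#' }
#'
#' @param gm a [genotype_matrix()].
#' @param call_rate_threshold variant call-rate threshold (default 0.8).
#' @param min_minor_carriers minimum samples carrying the minor allele
#'   for PolyHighResolution.
#' @param otv_labels optional character vector of marker ids externally
#'   labelled Off-Target Variant.
#' @return character vector of categories, named by marker id.
#' @export
classify_categories <- function(gm, call_rate_threshold = 0.8,
                                min_minor_carriers = 2, otv_labels = NULL) {
  g <- gm$geno
  called <- !is.na(g)
  cr <- rowMeans(called)
  n0 <- rowSums(g == 0L, na.rm = TRUE)
  n1 <- rowSums(g == 1L, na.rm = TRUE)
  n2 <- rowSums(g == 2L, na.rm = TRUE)
  n_classes <- (n0 > 0) + (n1 > 0) + (n2 > 0)
  # allele counts -> minor allele carriers (samples with >= 1 copy)
  a_count <- 2 * n0 + n1
  b_count <- 2 * n2 + n1
  minor_carriers <- ifelse(a_count <= b_count, n0 + n1, n2 + n1)

  out <- rep("Other", nrow(g))
  out[cr < call_rate_threshold] <- "CallRateBelowThreshold"
  ok <- cr >= call_rate_threshold
  out[ok & n_classes == 1] <- "MonoHighResolution"
  out[ok & n0 > 0 & n2 > 0 & minor_carriers >= min_minor_carriers] <- "PolyHighResolution"
  out[ok & n_classes == 2 & (n0 == 0 | n2 == 0)] <- "NoMinorHomozygote"
  out[ok & n_classes == 0] <- "Other" # all NoCall yet above threshold: impossible, kept for clarity
  if (!is.null(otv_labels)) out[rownames(g) %in% otv_labels] <- "OffTargetVariant"
  stats::setNames(out, rownames(g))
}

#' @rdname classify_categories
#' @param marker single marker id.
#' @export
classify_category <- function(gm, marker, call_rate_threshold = 0.8,
                              min_minor_carriers = 2, otv_labels = NULL) {
  if (!marker %in% rownames(gm$geno)) stop2("unknown marker: ", marker)
  unname(classify_categories(gm, call_rate_threshold, min_minor_carriers,
                             otv_labels)[marker])
}

#' CP segregation pattern of one marker
#'
#' Classifies the parental genotype combination into the JoinMap-style CP
#' codes: `AB x AB -> hkxhk`, `AB x hom -> lmxll` (father informative),
#' `hom x AB -> nnxnp` (mother informative), both parents homozygous ->
#' `uninformative`. Progeny calls impossible under the pattern (e.g. a
#' `BB` child of an `lmxll` marker whose mother is `AA`) are counted and
#' reported, not fatal.
#'
#' When a parent call is missing the pattern is inferred only if the
#' progeny classes force it (all three genotype classes present forces
#' `hkxhk` when no parent contradicts it); otherwise the marker is
#' classified `other` with reason "parent NoCall".
#'
#' @param father_call,mother_call parent calls (`"AA"`, `"AB"`, `"BB"`,
#'   `"NC"`/`NA`).
#' @param progeny_calls character vector of progeny calls.
#' @return list with `pattern` (one of `hkxhk`, `lmxll`, `nnxnp`,
#'   `uninformative`, `other`), `n_inconsistent` and `reason`.
#' @examples
#' classify_pattern("AB", "AA", c("AA", "AB", "AA"))$pattern  # lmxll
#' @export
classify_pattern <- function(father_call, mother_call, progeny_calls) {
  f <- code_call(father_call)
  m <- code_call(mother_call)
  p <- code_call(progeny_calls)
  classify_pattern_coded(f, m, p)
}

classify_pattern_coded <- function(f, m, p) {
  classes <- sort(unique(p[!is.na(p)]))
  if (is.na(f) || is.na(m)) {
    forces_hk <- length(classes) == 3 &&
      (is.na(f) || f == 1L) && (is.na(m) || m == 1L)
    if (forces_hk) {
      return(list(pattern = "hkxhk", n_inconsistent = 0L, reason = "inferred from progeny"))
    }
    return(list(pattern = "other", n_inconsistent = 0L, reason = "parent NoCall"))
  }
  het_f <- f == 1L
  het_m <- m == 1L
  if (het_f && het_m) {
    pattern <- "hkxhk"; bad <- 0L
  } else if (het_f) {
    pattern <- "lmxll"
    # mother homozygous: progeny cannot carry two copies of the allele
    # the mother does not have
    bad <- sum(p == (2L - m), na.rm = TRUE)
  } else if (het_m) {
    pattern <- "nnxnp"
    bad <- sum(p == (2L - f), na.rm = TRUE)
  } else {
    return(list(pattern = "uninformative", n_inconsistent = 0L,
                reason = "both parents homozygous"))
  }
  list(pattern = pattern, n_inconsistent = as.integer(bad), reason = "")
}

#' Chi-square test for segregation distortion
#'
#' Goodness of fit of the progeny genotype counts against the Mendelian
#' expectation of the marker's CP pattern: 1:2:1 over AA/AB/BB for
#' `hkxhk` (df = 2), 1:1 over the two segregating classes for `lmxll`
#' and `nnxnp` (df = 1). No-calls (and pattern-impossible calls for the
#' testcross patterns) are excluded.
#'
#' @param pattern one of `hkxhk`, `lmxll`, `nnxnp`.
#' @param progeny_calls character or coded progeny calls.
#' @return list with `chi2`, `p_value` and `n` (called progeny used).
#' @examples
#' distortion_test("lmxll", rep(c("AA", "AB"), c(60, 40)))  # chi2 = 4
#' @export
distortion_test <- function(pattern, progeny_calls) {
  p <- if (is.character(progeny_calls)) code_call(progeny_calls) else progeny_calls
  if (!pattern %in% CP_PATTERNS) stop2("pattern must be informative")
  if (pattern == "hkxhk") {
    obs <- c(sum(p == 0L, na.rm = TRUE), sum(p == 1L, na.rm = TRUE),
             sum(p == 2L, na.rm = TRUE))
    n <- sum(obs)
    if (n == 0) return(list(chi2 = NA_real_, p_value = NA_real_, n = 0L))
    expd <- n * c(0.25, 0.5, 0.25)
    chi2 <- sum((obs - expd)^2 / expd)
    df <- 2
  } else {
    # segregating classes: heterozygotes vs the homozygote class of the
    # homozygous parent (the majority homozygote class; the other
    # homozygote is pattern-impossible and excluded)
    n0 <- sum(p == 0L, na.rm = TRUE)
    n2 <- sum(p == 2L, na.rm = TRUE)
    obs <- c(max(n0, n2), sum(p == 1L, na.rm = TRUE))
    n <- sum(obs)
    if (n == 0) return(list(chi2 = NA_real_, p_value = NA_real_, n = 0L))
    expd <- n * c(0.5, 0.5)
    chi2 <- sum((obs - expd)^2 / expd)
    df <- 1
  }
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       n = as.integer(n))
}

#' Full per-marker QC table for a CP dataset
#'
#' Combines call rate, performance category, segregation pattern and the
#' distortion test into one MarkerQC table.
#'
#' @param gm a [genotype_matrix()] with father, mother and progeny.
#' @inheritParams classify_categories
#' @return data.frame with columns `marker_id`, `call_rate`, `category`,
#'   `pattern`, `n_inconsistent`, `chi2`, `p_value`, `missing_progeny`
#'   (missing fraction among progeny) and `reason` (empty; filled by
#'   [filter_markers()]).
#' @export
marker_qc <- function(gm, call_rate_threshold = 0.8, min_minor_carriers = 2,
                      otv_labels = NULL) {
  pc <- parent_columns(gm)
  prog <- progeny_columns(gm)
  if (!length(prog)) stop2("no progeny samples")
  cr <- call_rates(gm, marker_threshold = call_rate_threshold)$markers
  category <- classify_categories(gm, call_rate_threshold, min_minor_carriers,
                                  otv_labels)
  g <- gm$geno
  n <- nrow(g)
  pattern <- character(n); n_inc <- integer(n)
  chi2 <- rep(NA_real_, n); pval <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cl <- classify_pattern_coded(g[i, pc["father"]], g[i, pc["mother"]], g[i, prog])
    pattern[i] <- cl$pattern
    n_inc[i] <- cl$n_inconsistent
    if (cl$pattern %in% CP_PATTERNS) {
      dt <- distortion_test(cl$pattern, g[i, prog])
      chi2[i] <- dt$chi2; pval[i] <- dt$p_value
    }
  }
  data.frame(marker_id = rownames(g), call_rate = cr$call_rate,
             category = unname(category), pattern = pattern,
             n_inconsistent = n_inc, chi2 = chi2, p_value = pval,
             missing_progeny = rowMeans(is.na(g[, prog, drop = FALSE])),
             kept = FALSE, reason = "", row.names = NULL)
}

#' Filter markers for map construction
#'
#' Keeps markers that are PolyHighResolution or NoMinorHomozygote, carry
#' an informative CP pattern, pass the segregation-distortion test at
#' `distortion_p_min` and have at most `missing_limit` missing progeny
#' calls. Every excluded marker is annotated with the first failing
#' reason, and a per-reason attrition table is attached.
#'
#' @param qc a [marker_qc()] table.
#' @param distortion_p_min minimum distortion p-value (the
#'   "data tolerance"); default 0.001.
#' @param missing_limit maximum missing fraction among progeny.
#' @return the QC table with `kept`/`reason` filled; attribute
#'   `attrition` holds a data.frame of reason counts (in filter order,
#'   ending with `kept`).
#' @export
filter_markers <- function(qc, distortion_p_min = 0.001, missing_limit = 0.2) {
  if (nrow(qc) == 0) {
    attr(qc, "attrition") <- data.frame(reason = character(), n = integer())
    return(qc)
  }
  reason <- rep("", nrow(qc))
  reason[!(qc$category %in% c("PolyHighResolution", "NoMinorHomozygote"))] <- "category"
  step2 <- reason == "" & !(qc$pattern %in% CP_PATTERNS)
  reason[step2] <- ifelse(qc$pattern[step2] == "other", "parent NoCall",
                          "uninformative pattern")
  step3 <- reason == "" & (is.na(qc$p_value) | qc$p_value < distortion_p_min)
  reason[step3] <- "distortion"
  step4 <- reason == "" & qc$missing_progeny > missing_limit
  reason[step4] <- "missing"
  qc$kept <- reason == ""
  qc$reason <- reason
  counts <- table(factor(ifelse(reason == "", "kept", reason),
                         levels = c("category", "uninformative pattern",
                                    "parent NoCall", "distortion", "missing",
                                    "kept")))
  attr(qc, "attrition") <- data.frame(reason = names(counts),
                                      n = as.integer(counts))
  qc
}
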