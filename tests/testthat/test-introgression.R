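tiny_map <- function(markers_per_chrom = 60, chrom_bp = 600e6) {
  default_wheat_marker_map(markers_per_chrom = markers_per_chrom,
                           chrom_bp = chrom_bp, seed = 51)
}

line_gm <- function(calls, wm) {
  genotype_matrix(matrix(calls, ncol = 1,
                         dimnames = list(wm$marker, "L1")), "line")
}

test_that("window heterozygosity is the AB share of called markers", {
  wm <- tiny_map(50)
  calls <- rep(0L, nrow(wm))
  on_1a <- which(wm$chrom == "1A")
  calls[on_1a[1:10]] <- 1L
  gm <- line_gm(calls, wm)
  tr <- het_profile(gm, "L1", wm, window_bp = 600e6, step_bp = 600e6,
                    min_window_markers = 10)
  w1a <- tr$windows[tr$windows$chrom == "1A", ]
  expect_equal(nrow(w1a), 1)
  expect_equal(w1a$het_ratio, 10 / 50)
  expect_equal(w1a$n_called, 50)
  # a line with no AB calls has zero ratios everywhere
  tr0 <- het_profile(line_gm(rep(0L, nrow(wm)), wm), "L1", wm)
  expect_true(all(tr0$chromosomes$het_ratio == 0))
})

test_that("chromosome ratio equals the weighted mean of disjoint windows", {
  wm <- tiny_map(80)
  set.seed(52)
  calls <- ifelse(runif(nrow(wm)) < 0.1, 1L, 0L)
  calls[runif(nrow(wm)) < 0.2] <- NA_integer_
  gm <- genotype_matrix(matrix(calls, ncol = 1,
                               dimnames = list(wm$marker, "L1")), "line")
  tr <- het_profile(gm, "L1", wm, window_bp = 100e6, step_bp = 100e6,
                    min_window_markers = 1)
  for (ch in c("1A", "5B", "7D")) {
    w <- tr$windows[tr$windows$chrom == ch & tr$windows$n_called > 0, ]
    agg <- sum(w$het_ratio * w$n_called) / sum(w$n_called)
    expect_equal(agg, tr$chromosomes$het_ratio[tr$chromosomes$chrom == ch],
                 tolerance = 1e-12)
  }
})

test_that("a chromosome with no called markers is flagged undefined", {
  wm <- tiny_map(20)
  calls <- rep(0L, nrow(wm))
  calls[wm$chrom == "4D"] <- NA_integer_
  tr <- het_profile(line_gm(calls, wm), "L1", wm)
  expect_true(is.na(tr$chromosomes$het_ratio[tr$chromosomes$chrom == "4D"]))
})

test_that("windows advance by step, are clipped, and flag sparse spans", {
  wm <- tiny_map(30, chrom_bp = 130e6)
  tr <- het_profile(line_gm(rep(0L, nrow(wm)), wm), "L1", wm,
                    window_bp = 50e6, step_bp = 20e6, min_window_markers = 10)
  w <- tr$windows[tr$windows$chrom == "1A", ]
  expect_equal(w$start, seq(0, 80e6, by = 20e6))
  expect_true(all(w$end <= 130e6))
  expect_true(all(w$end - w$start <= 50e6))
  expect_true(is.logical(w$informative))
})

test_that("a hot-set of homoeologs with an expected count calls the top groups", {
  # hand-built track: 2D plus 5A/5B/5D hot (the double-addition signature
  # with partial group-2 evidence)
  het <- rep(0.01, 21)
  names(het) <- WHEAT_CHROMOSOMES
  het[c("5A", "5B", "5D")] <- 0.15
  het["2D"] <- 0.12
  track <- structure(list(
    line_id = "dbl",
    chromosomes = data.frame(chrom = WHEAT_CHROMOSOMES, n_markers = 300,
                             n_called = 280, het_ratio = unname(het),
                             n_specific = 90, missing_rate = 0.05),
    windows = data.frame()), class = "evidence_track")
  adds <- call_additions(track, expected_alien_count = 2)
  expect_setequal(adds$p_chromosome, c("2P", "5P"))
  # without the external count, only groups with >= 2 hot homoeologs call
  adds2 <- call_additions(track)
  expect_equal(adds2$p_chromosome, "5P")
})

test_that("substitutions require a homoeologous called addition", {
  het <- rep(0.01, 21); names(het) <- WHEAT_CHROMOSOMES
  het[c("6A", "6B", "6D")] <- 0.15
  miss <- rep(0.05, 21); names(miss) <- WHEAT_CHROMOSOMES
  miss["6D"] <- 0.6
  miss["3A"] <- 0.55   # hot missingness with no 3P addition
  track <- structure(list(
    line_id = "sub",
    chromosomes = data.frame(chrom = WHEAT_CHROMOSOMES, n_markers = 300,
                             n_called = 280, het_ratio = unname(het),
                             n_specific = 90, missing_rate = unname(miss)),
    windows = data.frame()), class = "evidence_track")
  adds <- call_additions(track)
  subs <- call_substitutions(track, adds)
  expect_equal(subs$wheat_chrom, "6D")
  expect_equal(subs$p_chromosome, "6P")
  expect_equal(attr(subs, "unexplained"), "3A")
})

test_that("identification labels follow the reporting conventions", {
  expect_equal(introgression_label("1P"), "1P addition line")
  expect_equal(introgression_label(c("2P", "1P")), "1P and 2P addition line")
  expect_equal(introgression_label("6P", data.frame(p = "6P", wheat = "6D")),
               "6P/6D substitution line")
  expect_equal(introgression_label(c("1P", "2P"),
                                   data.frame(p = "1P", wheat = "1A")),
               "2P addition and 1P/1A substitution line")
  expect_equal(introgression_label(character()), "no alien chromosome detected")
})

test_that("the synthetic panel is recovered line by line", {
  wm <- default_wheat_marker_map(markers_per_chrom = 250, seed = 53)
  panel <- example_line_panel()
  sim <- simulate_introgression_lines(panel, wm, seed = 53)
  comp <- vapply(panel, function(s) attr(s, "composition"), "")
  names(comp) <- vapply(panel, `[[`, "", "line_id")
  rep_ <- batch_report(sim$gm, wm, expected_counts = expected_alien_pairs(comp),
                       compositions = comp)
  expect_equal(rep_$report$additions, sim$truth$additions)
  expect_equal(rep_$report$missing, sim$truth$missing)
  expect_equal(rep_$report$label, sim$truth$label)
})

test_that("a null line and an empty panel are handled gracefully", {
  wm <- default_wheat_marker_map(markers_per_chrom = 200, seed = 54)
  sim <- simulate_introgression_lines(
    list(line_spec("null", additions = character())), wm, seed = 54)
  rep_ <- batch_report(sim$gm, wm)
  expect_equal(rep_$report$additions, "")
  expect_equal(rep_$report$label, "no alien chromosome detected")
  empty <- batch_report(sim$gm[, 0], wm)
  expect_equal(nrow(empty$report), 0)
  expect_named(empty$report,
               c("line_id", "composition", "additions", "missing", "label"))
})

test_that("recall degrades as the heterozygosity signal fades", {
  wm <- default_wheat_marker_map(markers_per_chrom = 150, seed = 55)
  recall <- vapply(c(0.15, 0.05, 0.02, 0.012), function(hh) {
    hits <- vapply(55:58, function(sd) {
      specs <- lapply(1:7, function(g)
        line_spec(paste0("L", g), paste0(g, "P"), homoeolog_het = hh))
      sim <- simulate_introgression_lines(specs, wm, seed = sd)
      rep_ <- batch_report(sim$gm, wm)
      mean(rep_$report$additions == sim$truth$additions)
    }, 0)
    mean(hits)
  }, 0)
  expect_true(all(diff(recall) <= 1e-9))
  expect_equal(recall[1], 1)
})
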