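test_that("map truth respects its invariants and rejects bad input", {
  tr <- sim_map_truth(markers_per_chromosome = 20, seed = 1)
  expect_equal(nrow(tr$chromosomes), 7)
  expect_false(anyDuplicated(tr$markers$id) > 0)
  m <- merge(tr$markers, tr$chromosomes, by.x = "chromosome", by.y = "name")
  expect_true(all(m$true_cm >= 0 & m$true_cm <= m$length_cm))
  npat <- tapply(tr$markers$pattern, tr$markers$chromosome,
                 function(p) length(unique(p)))
  expect_true(all(npat >= 2))
  expect_error(sim_map_truth(length_cm = -5), "length_cm")
  expect_error(sim_map_truth(pattern_mix = c(hkxhk = 1, lmxll = 0.5, nnxnp = 0)),
               "sum to 1")
})

test_that("cross configuration validates rates and sizes", {
  expect_error(sim_cross_config(n_progeny = 1), "n_progeny")
  expect_error(sim_cross_config(missing_rate = 1), "rates")
  expect_silent(sim_cross_config())
})

test_that("a 0 cM chromosome segregates without recombination", {
  tr <- sim_map_truth(n_chromosomes = 1, markers_per_chromosome = 12,
                      length_cm = 0, distorted_fraction = 0, seed = 4)
  tr$markers$pattern <- "lmxll" # single meiosis: gamete product is binary
  sim <- suppressWarnings(simulate_cp_cross(tr, sim_cross_config(
    n_progeny = 50, genotyping_error_rate = 0, missing_rate = 0, seed = 4)))
  g <- sim$gm$geno[, progeny_cols <- which(sim$gm$roles == "progeny")]
  # paternal allele = call (0 -> A, 1 -> B); phase-aligned rows must be
  # identical or complementary across all markers for every progeny
  phase <- sim$truth$phase_father[rownames(g)]
  aligned <- (g + phase) %% 2L
  expect_true(all(apply(aligned, 2, function(col) length(unique(col)) == 1)))
})

test_that("an lmxll marker never yields BB progeny without error", {
  tr <- sim_map_truth(n_chromosomes = 1, markers_per_chromosome = 10,
                      distorted_fraction = 0, seed = 5)
  tr$markers$pattern <- "lmxll"
  sim <- suppressWarnings(simulate_cp_cross(tr, sim_cross_config(
    n_progeny = 200, genotyping_error_rate = 0, missing_rate = 0, seed = 5)))
  prog <- sim$gm$geno[, sim$gm$roles == "progeny"]
  expect_true(all(prog %in% c(0L, 1L)))
})

test_that("recombinant fraction at 10 cM matches the map-function scale", {
  tr <- list(chromosomes = data.frame(name = "1P", length_cm = 10),
             markers = data.frame(id = c("a", "b"), chromosome = "1P",
                                  true_cm = c(0, 10), pattern = "hkxhk",
                                  distorted = FALSE))
  class(tr) <- "sim_map_truth"
  sim <- suppressWarnings(simulate_cp_cross(tr, sim_cross_config(
    n_progeny = 2000, genotyping_error_rate = 0, missing_rate = 0, seed = 7)))
  # recover recombinant meioses from the phased truth
  pf <- sim$truth$phase_father; pm <- sim$truth$phase_mother
  prog <- sim$gm$geno[, sim$gm$roles == "progeny"]
  # count recombination per meiosis via crossover points stored in truth
  xo_f <- sim$truth$crossovers$father[["1P"]]
  xo_m <- sim$truth$crossovers$mother[["1P"]]
  rec <- function(xo) vapply(xo, function(x) sum(x >= 0 & x < 10) %% 2L, 0L)
  frac <- mean(c(rec(xo_f), rec(xo_m)))
  se <- sqrt(0.0987 * (1 - 0.0987) / 4000)
  expect_lt(abs(frac - kosambi_inverse(10)), 3 * se)
  # and the generating process is exactly Haldane
  expect_lt(abs(frac - haldane_inverse(10)), 3 * se)
})

test_that("undistorted markers segregate at Mendelian ratios", {
  tr <- sim_map_truth(n_chromosomes = 2, markers_per_chromosome = 50,
                      distorted_fraction = 0, seed = 8)
  sim <- simulate_cp_cross(tr, sim_cross_config(
    n_progeny = 119, genotyping_error_rate = 0, missing_rate = 0, seed = 8))
  qc <- marker_qc(sim$gm)
  alpha <- 0.05
  rate <- mean(qc$p_value < alpha, na.rm = TRUE)
  expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / nrow(qc)) + 0.01)
})

test_that("distorted markers skew transmission as configured", {
  tr <- sim_map_truth(n_chromosomes = 1, markers_per_chromosome = 6,
                      distorted_fraction = 0, seed = 9)
  tr$markers$pattern <- "lmxll"
  tr$markers$distorted <- TRUE
  s <- 0.6
  sim <- suppressWarnings(simulate_cp_cross(tr, sim_cross_config(
    n_progeny = 500, genotyping_error_rate = 0, missing_rate = 0,
    distortion_strength = s, seed = 9)))
  prog <- sim$gm$geno[, sim$gm$roles == "progeny"]
  frac_a <- mean(prog == 0L)
  expect_lt(abs(frac_a - (0.5 + s / 2)), 3 * sqrt(0.21 / length(prog)) + 0.01)
})

test_that("generators are byte-identical under a fixed seed", {
  tr1 <- sim_map_truth(markers_per_chromosome = 15, seed = 3)
  tr2 <- sim_map_truth(markers_per_chromosome = 15, seed = 3)
  expect_identical(tr1, tr2)
  s1 <- simulate_cp_cross(tr1, sim_cross_config(n_progeny = 30, seed = 3))
  s2 <- simulate_cp_cross(tr2, sim_cross_config(n_progeny = 30, seed = 3))
  expect_identical(s1, s2)
  h1 <- simulate_hit_table(tr1, seed = 3)
  h2 <- simulate_hit_table(tr2, seed = 3)
  expect_identical(h1, h2)
  wm <- default_wheat_marker_map(markers_per_chrom = 30)
  l1 <- simulate_introgression_lines(list(line_spec("x", "6P")), wm, seed = 3)
  l2 <- simulate_introgression_lines(list(line_spec("x", "6P")), wm, seed = 3)
  expect_identical(l1, l2)
})

test_that("hit tables place markers on their true homoeologous group", {
  tr <- sim_map_truth(markers_per_chromosome = 40, seed = 10)
  ht <- simulate_hit_table(tr, noise_rate = 0, rearrangements = list(),
                           junk_rate = 0, seed = 10)
  hits <- filter_hits(ht)
  top <- hits[hits$top_overall, ]
  truth_grp <- as.integer(sub("P", "", tr$markers$chromosome))
  expect_equal(top$group[match(tr$markers$id, top$marker_id)], truth_grp)
})

test_that("hit-table noise dilutes the true-group proportion as expected", {
  tr <- sim_map_truth(n_chromosomes = 2, markers_per_chromosome = 250, seed = 11)
  noise <- 0.2
  ht <- simulate_hit_table(tr, noise_rate = noise, rearrangements = list(),
                           junk_rate = 0, seed = 11)
  hits <- filter_hits(ht)
  top <- hits[hits$top_overall, ]
  truth_grp <- as.integer(sub("P", "", tr$markers$chromosome))
  agree <- top$group[match(tr$markers$id, top$marker_id)] == truth_grp
  expected <- (1 - noise) + noise / 21
  se <- sqrt(expected * (1 - expected) / length(agree))
  expect_lt(abs(mean(agree) - expected), 3 * se)
})

test_that("the default rearrangement sends ~40% of 4P hits to group 2", {
  tr <- sim_map_truth(markers_per_chromosome = 200, seed = 12)
  ht <- simulate_hit_table(tr, noise_rate = 0, junk_rate = 0, seed = 12)
  hits <- filter_hits(ht)
  top <- hits[hits$top_overall, ]
  on4p <- top[top$marker_id %in% tr$markers$id[tr$markers$chromosome == "4P"], ]
  prop2 <- mean(on4p$group == 2)
  # marker positions are uniform, so the proximal 40% of the chromosome
  # holds ~40% of markers
  expect_lt(abs(prop2 - 0.4), 3 * sqrt(0.4 * 0.6 / nrow(on4p)))
  expect_error(simulate_hit_table(tr, rearrangements = list(
    list(chromosome = "4P", start_cm = 0, end_cm = 50, target_group = 2L),
    list(chromosome = "4P", start_cm = 40, end_cm = 80, target_group = 5L))),
    "overlap")
})

test_that("introgression lines show the configured het/missing signal", {
  wm <- default_wheat_marker_map(markers_per_chrom = 400, seed = 13)
  spec <- line_spec("sub6", additions = "6P",
                    substitutions = data.frame(p = "6P", wheat = "6D"))
  sim <- simulate_introgression_lines(list(spec), wm, seed = 13)
  tr <- het_profile(sim$gm, "sub6", wm)
  ch <- tr$chromosomes
  het <- setNames(ch$het_ratio, ch$chrom)
  expect_lt(abs(het[["6A"]] - 0.15), 0.05)
  expect_lt(abs(het[["6B"]] - 0.15), 0.05)
  expect_lt(abs(het[["1A"]] - 0.01), 0.02)
  miss <- setNames(ch$missing_rate, ch$chrom)
  expect_lt(abs(miss[["6D"]] - 0.6), 0.12)
  expect_lt(miss[["1A"]], 0.15)
})

test_that("a null line shows no elevated chromosome", {
  wm <- default_wheat_marker_map(markers_per_chrom = 300, seed = 14)
  sim <- simulate_introgression_lines(
    list(line_spec("null", additions = character())), wm, seed = 14)
  ch <- het_profile(sim$gm, "null", wm)$chromosomes
  se <- 3 * sqrt(0.01 * 0.99 / 280)
  expect_true(all(ch$het_ratio < 0.01 + se + 0.01))
})

test_that("line specs are validated", {
  expect_error(line_spec("x", "6P", baseline_het = 0.2, homoeolog_het = 0.1),
               "exceed")
  expect_error(line_spec("x", character(),
                         substitutions = data.frame(p = "6P", wheat = "6D")),
               "additions")
  wm <- default_wheat_marker_map(markers_per_chrom = 10)
  expect_error(simulate_introgression_lines(
    list(line_spec("x", "9P")), wm), "unknown chromosome")
  expect_error(simulate_introgression_lines(
    list(line_spec("x", "6P", substitutions = data.frame(p = "6P", wheat = "5D"))),
    wm), "homoeologous")
})

test_that("the 35-line panel mirrors the published composition counts", {
  panel <- example_line_panel()
  expect_length(panel, 35)
  tru <- panel_truth(panel)
  adds <- strsplit(tru$additions, ",")
  expect_equal(sum(lengths(adds) == 1 & tru$missing == ""), 26)  # disomic additions
  expect_equal(sum(lengths(adds) == 2 & tru$missing == ""), 3)   # double additions
  expect_equal(sum(lengths(adds) == 1 & tru$missing != ""), 5)   # substitutions
  expect_equal(sum(lengths(adds) == 2 & tru$missing != ""), 1)   # addition + substitution
  expect_true("6P/6D substitution line" %in% tru$label)
  expect_true("2P addition and 1P/1A substitution line" %in% tru$label)
})
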