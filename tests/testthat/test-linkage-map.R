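# build a minimal pairwise_linkage object by hand
fake_pl <- function(markers, patterns, edges) {
  # edges: data.frame(i, j, r, lod, n, discord)
  out <- data.frame(i = as.integer(edges$i), j = as.integer(edges$j),
                    type = rep("tt_f", nrow(edges)), r = edges$r,
                    lod = edges$lod, phase = rep("coupling", nrow(edges)),
                    n = as.integer(edges$n), discord = as.integer(edges$discord))
  attr(out, "markers") <- markers
  attr(out, "patterns") <- patterns
  class(out) <- c("pairwise_linkage", "data.frame")
  out
}

test_that("grouping is transitive and respects the LOD threshold", {
  pl <- fake_pl(c("A", "B", "C"), rep("lmxll", 3),
                data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                           r = c(0.05, 0.05, 0.1), lod = c(12, 12, 3),
                           n = 100, discord = c(5, 5, 10)))
  grp <- group_markers(pl, lod_limit = 11, min_group_size = 2)
  expect_length(grp$groups, 1)
  expect_setequal(grp$groups[[1]], c("A", "B", "C"))

  grp2 <- group_markers(pl, lod_limit = 13, min_group_size = 0)
  expect_length(grp2$groups, 3)

  # all edges at or below the limit -> nothing above min_group_size
  pl3 <- fake_pl(c("A", "B"), rep("lmxll", 2),
                 data.frame(i = 1, j = 2, r = 0.3, lod = 11, n = 100,
                            discord = 30))
  expect_length(group_markers(pl3, lod_limit = 11, min_group_size = 1)$groups, 0)
})

test_that("group numbering is deterministic: size first, then smallest id", {
  pl <- fake_pl(c("a1", "a2", "z1", "z2", "z3"),
                rep("lmxll", 5),
                data.frame(i = c(1, 3, 4), j = c(2, 4, 5),
                           r = 0.01, lod = 20, n = 100, discord = 1))
  grp <- group_markers(pl, min_group_size = 1)
  expect_equal(names(grp$groups), c("LG1", "LG2"))
  expect_setequal(grp$groups$LG1, c("z1", "z2", "z3"))   # larger group first
  expect_setequal(grp$groups$LG2, c("a1", "a2"))
})

test_that("a three-locus order follows the recombination distances", {
  edges <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                      r = c(0.05, 0.05, 0.10), lod = c(20, 20, 15),
                      n = 100, discord = c(5, 5, 10))
  pl <- fake_pl(c("A", "B", "C"), rep("lmxll", 3), edges)
  om <- order_markers(c("A", "B", "C"), pl, correct_errors = FALSE)
  mid <- om$markers_table$marker_id[2]
  expect_equal(mid, "B")
  expect_equal(max(om$position_cm), 2 * kosambi_cm(0.05), tolerance = 1e-9)
  expect_equal(round(max(om$position_cm), 2), 10.03)
})

test_that("co-segregating markers collapse into one locus at gap 0", {
  edges <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                      r = c(0, 0.1, 0.1), lod = c(30, 12, 12),
                      n = c(100, 100, 100), discord = c(0, 10, 10))
  pl <- fake_pl(c("A", "B", "C"), rep("lmxll", 3), edges)
  om <- order_markers(c("A", "B", "C"), pl, correct_errors = FALSE)
  expect_length(om$loci, 2)
  bin <- om$loci[[which(vapply(om$loci, length, 0L) == 2)]]
  expect_setequal(bin, c("A", "B"))
  tab <- om$markers_table
  expect_equal(tab$position_cm[tab$marker_id == "A"],
               tab$position_cm[tab$marker_id == "B"])
})

test_that("a single-marker group maps to position zero", {
  pl <- fake_pl("A", "lmxll", data.frame(i = integer(), j = integer(),
                                         r = numeric(), lod = numeric(),
                                         n = integer(), discord = integer()))
  om <- order_markers("A", pl)
  expect_equal(om$position_cm, 0)
  expect_equal(om$markers_table$marker_id, "A")
})

test_that("ordering output is canonical: positions start at zero, non-decreasing", {
  tr <- sim_map_truth(n_chromosomes = 1, markers_per_chromosome = 40,
                      length_cm = 60, distorted_fraction = 0, seed = 31)
  sim <- simulate_cp_cross(tr, sim_cross_config(n_progeny = 119, seed = 31))
  qc <- filter_markers(marker_qc(sim$gm))
  pl <- pairwise_linkage(sim$gm, qc)
  grp <- group_markers(pl)
  om <- order_markers(grp$groups[[1]], pl)
  expect_equal(om$position_cm[1], 0)
  expect_true(all(diff(om$position_cm) >= 0))
  # locus bins partition the group's markers
  expect_setequal(unlist(om$loci), grp$groups[[1]])
  # the smallest marker id sits in the first half (orientation rule)
  anchor <- min(grp$groups[[1]])
  idx <- which(vapply(om$loci, function(l) anchor %in% l, TRUE))
  expect_lte(idx, (length(om$loci) + 1) / 2)
})

test_that("error-free dense data recovers order and map length", {
  tr <- sim_map_truth(n_chromosomes = 2, markers_per_chromosome = 60,
                      length_cm = 100, distorted_fraction = 0, seed = 32)
  sim <- simulate_cp_cross(tr, sim_cross_config(
    n_progeny = 2000, genotyping_error_rate = 0, missing_rate = 0, seed = 32))
  qc <- filter_markers(marker_qc(sim$gm))
  pl <- pairwise_linkage(sim$gm, qc)
  grp <- group_markers(pl)
  expect_length(grp$groups, 2)
  for (g in names(grp$groups)) {
    om <- order_markers(grp$groups[[g]], pl)
    tp <- tr$markers$true_cm[match(om$markers_table$marker_id, tr$markers$id)]
    expect_gte(abs(cor(om$markers_table$position_cm, tp, method = "spearman")),
               0.99)
    expect_lt(abs(max(om$position_cm) - 100) / 100, 0.10)
  }
})

test_that("build_maps assembles the three map variants with shared hk markers", {
  tr <- sim_map_truth(n_chromosomes = 2, markers_per_chromosome = 50,
                      length_cm = 80, distorted_fraction = 0, seed = 33)
  sim <- simulate_cp_cross(tr, sim_cross_config(n_progeny = 119, seed = 33))
  qc <- filter_markers(marker_qc(sim$gm))
  maps <- build_maps(sim$gm, qc)
  expect_length(maps$integrated$lg, 2)
  pats <- stats::setNames(attr(maps$pairwise, "patterns"),
                          attr(maps$pairwise, "markers"))
  male_pats <- unique(maps$male$table$pattern)
  expect_true(all(male_pats %in% c("lmxll", "hkxhk")))
  female_pats <- unique(maps$female$table$pattern)
  expect_true(all(female_pats %in% c("nnxnp", "hkxhk")))
  hk <- names(pats)[pats == "hkxhk"]
  in_all <- hk %in% maps$male$table$marker_id &
    hk %in% maps$female$table$marker_id &
    hk %in% maps$integrated$table$marker_id
  expect_gt(mean(in_all), 0.9)
})

test_that("a dataset without father-informative markers yields an empty male map", {
  n <- 60
  rows <- do.call(rbind, lapply(1:20, function(k) {
    c("AA", "AB", rep(c("AA", "AB"), n / 2))
  }))
  rownames(rows) <- sprintf("nn%02d", 1:20)
  colnames(rows) <- c("F", "M", paste0("p", 1:n))
  gm <- genotype_matrix(rows, c("father", "mother", rep("progeny", n)))
  qc <- filter_markers(marker_qc(gm))
  expect_warning(maps <- build_maps(gm, qc, min_group_size = 5),
                 "male")
  expect_length(maps$male$lg, 0)
  expect_gt(length(maps$female$lg), 0)
})

test_that("map summary reports the share of adjacent gaps at most 5 cM", {
  fake_map <- structure(list(
    lg = list(LG1 = list(position_cm = c(0, 1, 3, 9),
                         loci = list("a", "b", "c", "d"),
                         markers_table = data.frame(
                           locus_index = 1:4, marker_id = c("a", "b", "c", "d"),
                           position_cm = c(0, 1, 3, 9), pattern = "lmxll"))),
    summary = data.frame(lg = "LG1", n_markers = 4, n_loci = 4, length_cm = 9,
                         mean_gap_cm = 3, max_gap_cm = 6, frac_gap_le5 = 2 / 3),
    origin = "integrated"), class = "genetic_map")
  s <- map_summary(fake_map)
  expect_equal(s$frac_gap_le5[s$lg == "LG1"], 2 / 3)
  expect_equal(s$frac_gap_le5[s$lg == "total"], 2 / 3)
  expect_equal(s$length_cm[s$lg == "total"], 9)
})
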