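make_gm <- function(progeny, father = "AB", mother = "AA", id = "m1") {
  calls <- matrix(c(father, mother, progeny), nrow = 1,
                  dimnames = list(id, c("F", "M", paste0("p", seq_along(progeny)))))
  genotype_matrix(calls, c("father", "mother", rep("progeny", length(progeny))))
}

test_that("call rates count the non-missing fraction and flag the threshold", {
  calls <- matrix("AA", 3, 121,
                  dimnames = list(c("a", "b", "c"), paste0("s", 1:121)))
  calls[2, 1:30] <- "NC"
  calls[3, ] <- "NC"
  gm <- genotype_matrix(calls, c("father", "mother", rep("progeny", 119)))
  cr <- call_rates(gm)
  expect_equal(cr$markers$call_rate, c(1, 91 / 121, 0))
  expect_equal(cr$markers$below_threshold, c(FALSE, TRUE, TRUE))
  expect_error(call_rates(gm[0, ]), "empty")
})

test_that("performance categories follow the genotype-level rules", {
  n <- 121
  mono <- rep("AA", n)
  nmh <- c(rep("AA", 80), rep("AB", 35), rep("NC", 6))      # call rate ~0.95
  poly <- c(rep("AA", 119), "AB", "BB")
  low <- c(rep("AA", 90), rep("NC", 31))                    # call rate < 0.8
  calls <- rbind(mono = mono, nmh = nmh, poly = poly, low = low)
  colnames(calls) <- paste0("s", 1:n)
  gm <- genotype_matrix(calls, c("father", "mother", rep("progeny", n - 2)))
  cats <- classify_categories(gm)
  expect_equal(unname(cats), c("MonoHighResolution", "NoMinorHomozygote",
                               "PolyHighResolution", "CallRateBelowThreshold"))
  expect_equal(classify_category(gm, "poly"), "PolyHighResolution")
  # OTV is pass-through only
  expect_equal(unname(classify_categories(gm, otv_labels = "mono")["mono"]),
               "OffTargetVariant")
})

test_that("CP segregation patterns are classified from the parent pair", {
  expect_equal(classify_pattern("AB", "AB", c("AA", "AB", "BB"))$pattern, "hkxhk")
  expect_equal(classify_pattern("AB", "AA", c("AA", "AB", "NC"))$pattern, "lmxll")
  expect_equal(classify_pattern("AA", "AB", c("AA", "AB"))$pattern, "nnxnp")
  expect_equal(classify_pattern("AA", "BB", c("AB", "AB"))$pattern, "uninformative")
  # impossible progeny are counted, not fatal
  cl <- classify_pattern("AB", "AA", c("AA", "AB", "BB", "BB"))
  expect_equal(cl$pattern, "lmxll")
  expect_equal(cl$n_inconsistent, 2L)
})

test_that("pattern inference with a missing parent is conservative", {
  # three progeny classes force hkxhk when the known parent is AB
  expect_equal(classify_pattern("AB", "NC", c("AA", "AB", "BB"))$pattern, "hkxhk")
  # two classes are ambiguous -> dropped with reason
  cl <- classify_pattern("AB", "NC", c("AA", "AB", "AA"))
  expect_equal(cl$pattern, "other")
  expect_match(cl$reason, "NoCall")
})

test_that("pattern classification is invariant to a consistent allele swap", {
  swap <- function(x) ifelse(x == "AA", "BB", ifelse(x == "BB", "AA", x))
  prog <- c("AA", "AB", "AA", "AB", "BB")
  for (par in list(c("AB", "AB"), c("AB", "AA"), c("AA", "AB"))) {
    a <- classify_pattern(par[1], par[2], prog)
    b <- classify_pattern(swap(par[1]), swap(par[2]), swap(prog))
    expect_equal(a$pattern, b$pattern)
    expect_equal(a$n_inconsistent, b$n_inconsistent)
  }
})

test_that("distortion test reproduces the chi-square closed forms", {
  t0 <- distortion_test("lmxll", rep(c("AA", "AB"), c(60, 60)))
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p_value, 1)
  t1 <- distortion_test("lmxll", rep(c("AA", "AB"), c(60, 40)))
  expect_equal(t1$chi2, 4)
  expect_equal(t1$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(t1$p_value, 4), 0.0455)
  t2 <- distortion_test("hkxhk", rep(c("AA", "AB", "BB"), c(30, 60, 30)))
  expect_equal(t2$chi2, 0)
  expect_equal(t2$p_value, 1)
  # works whichever homozygote class segregates
  t3 <- distortion_test("lmxll", rep(c("BB", "AB"), c(60, 40)))
  expect_equal(t3$chi2, 4)
  # no called progeny -> undefined
  expect_true(is.na(distortion_test("lmxll", rep("NC", 5))$chi2))
})

test_that("filter_markers keeps informative well-behaved markers with reasons", {
  n <- 40
  good <- function() c("AB", "AA", rep(c("AA", "AB"), n / 2))
  rows <- rbind(
    k1 = good(), k2 = good(), k3 = good(), k4 = good(), k5 = good(),
    d1 = c("AB", "AA", rep("AA", n)),                    # all one class: distorted
    d2 = c("AB", "AA", rep(c("AA", "AB"), c(n - 2, 2))), # strong distortion
    d3 = c("AB", "AA", rep(c("AA", "AB"), c(2, n - 2))), # strong distortion
    u1 = c("AA", "BB", rep("AB", n)),                    # uninformative
    u2 = c("AA", "AA", rep("AA", n)))                    # uninformative + mono
  colnames(rows) <- c("F", "M", paste0("p", 1:n))
  gm <- genotype_matrix(rows, c("father", "mother", rep("progeny", n)))
  qc <- filter_markers(marker_qc(gm))
  expect_equal(sum(qc$kept), 5)
  expect_setequal(qc$marker_id[qc$kept], paste0("k", 1:5))
  expect_equal(sort(unique(qc$reason[qc$reason != ""])),
               sort(unique(c("distortion", "category", "uninformative pattern"))))
  att <- attr(qc, "attrition")
  expect_equal(sum(att$n), nrow(qc))
  # every marker gets exactly one category; counts sum to the total
  expect_equal(sum(table(qc$category)), nrow(qc))
})

test_that("filtering an empty QC table yields an empty result", {
  qc <- filter_markers(marker_qc(make_gm(c("AA", "AB")))[0, ])
  expect_equal(nrow(qc), 0)
})

test_that("null distortion rejection rate is calibrated at both designs", {
  set.seed(11)
  m <- 800
  n <- 119
  p_tt <- replicate(m, {
    calls <- sample(c(0L, 1L), n, replace = TRUE)
    distortion_test("lmxll", calls)$p_value
  })
  p_ic <- replicate(m, {
    calls <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    distortion_test("hkxhk", calls)$p_value
  })
  for (alpha in c(0.05, 0.01)) {
    se3 <- 3 * sqrt(alpha * (1 - alpha) / m)
    expect_lt(abs(mean(p_tt < alpha) - alpha), se3 + 0.01) # chi2 is discrete at n=119
    expect_lt(abs(mean(p_ic < alpha) - alpha), se3 + 0.01)
  }
})
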