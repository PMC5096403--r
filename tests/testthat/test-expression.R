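toy_hits <- function(fragment, status, candidates) {
  data.frame(fragment = fragment, status = status,
             n_candidate_placements = vapply(strsplit(candidates, ","),
                                             function(x) sum(nzchar(x)), 0L),
             candidates = candidates)
}

test_that("counting rules: pair = 1, singleton = 1, broken pair = 0", {
  hits <- rbind(
    toy_hits(paste0("p", 1:10), "pair_both_mapped", rep("X", 10)),
    toy_hits("s1", "singleton_mapped", "X"),
    toy_hits("b1", "broken_pair", ""),
    toy_hits("u1", "unmapped", ""))
  cf <- countFragments(hits, c(X = 1000, Y = 1000))
  expect_equal(unname(cf$counts["X"]), 11L)
  expect_equal(unname(cf$counts["Y"]), 0L)
  expect_equal(sum(cf$counts), 11L)  # broken + unmapped contribute nothing
})

test_that("multimap assignment follows the unique-count/length weights", {
  # unique evidence 300 vs 100, equal lengths -> 3:1 assignment
  hits <- rbind(
    toy_hits(paste0("ua", 1:300), "pair_both_mapped", rep("A", 300)),
    toy_hits(paste0("ub", 1:100), "pair_both_mapped", rep("B", 100)),
    toy_hits(paste0("m", 1:10000), "pair_both_mapped", rep("A,B", 10000)))
  cf <- countFragments(hits, c(A = 1500, B = 1500), seed = 99)
  multi <- cf$assignment[grepl("^m", cf$assignment$fragment), ]
  nA <- sum(multi$assigned == "A")
  # binomial 99% envelope around p = 0.75 with n = 10000
  p <- 0.75; n <- 10000
  expect_gt(nA, n * p - 2.58 * sqrt(n * p * (1 - p)))
  expect_lt(nA, n * p + 2.58 * sqrt(n * p * (1 - p)))
})

test_that("length normalization enters the multimap weights", {
  hits <- rbind(
    toy_hits(paste0("ua", 1:100), "pair_both_mapped", rep("A", 100)),
    toy_hits(paste0("ub", 1:100), "pair_both_mapped", rep("B", 100)),
    toy_hits(paste0("m", 1:4000), "pair_both_mapped", rep("A,B", 4000)))
  # same unique counts but A is twice as long -> weights 1:2
  cf <- countFragments(hits, c(A = 2000, B = 1000), seed = 7)
  multi <- cf$assignment[grepl("^m", cf$assignment$fragment), ]
  frac_B <- mean(multi$assigned == "B")
  expect_gt(frac_B, 2 / 3 - 0.03)
  expect_lt(frac_B, 2 / 3 + 0.03)
})

test_that("strict matching is end-to-end and mismatch-free on either strand", {
  set.seed(71)
  hA <- random_dna(400)
  hB <- mutateCodonsForTest(hA, 12)
  homeologs <- c(A = hA, B = hB)
  r1 <- substr(hA, 51, 150); r2 <- revcomp(substr(hA, 251, 350))
  pr <- make_pairs(r1, r2, prefix = "ok")
  hits <- strictMap(pairs = pr, homeologs = homeologs)
  expect_equal(hits$status, "pair_both_mapped")
  # one mismatch anywhere -> that mate unmapped -> broken pair
  bad1 <- r1
  substr(bad1, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                  substr(bad1, 50, 50))[1]
  prb <- make_pairs(bad1, r2, prefix = "bad")
  hb <- strictMap(pairs = prb, homeologs = homeologs)
  expect_equal(hb$status, "broken_pair")
})

test_that("fragment counts conserve the QC-passing total", {
  cfg <- small_config(cds_length_codons = 200, seed = 17)
  tr <- evolveSubgenomes(cfg)
  hom <- tr[[1]]$homeologs
  rd <- simulateReads(hom, setNames(rep(80, 3), names(hom)), cfg, seed = 2)
  hits <- strictMap(pairs = rd$pairs, homeologs = hom)
  cf <- countFragments(hits, nchar(hom), seed = 3)
  tally <- cf$status_tally
  expect_equal(sum(cf$counts) +
                 sum(tally[c("broken_pair", "unmapped")], na.rm = TRUE),
               nrow(hits))
  expect_lte(sum(cf$counts), nrow(rd$origin))
})

test_that("size factors match the independent median-of-ratios oracle", {
  set.seed(81)
  for (i in 1:50) {
    # odd row count: the ratio-space and log-space medians then coincide
    # exactly, so the comparison is tolerance-free
    m <- matrix(rnbinom(12 * 21, mu = exp(runif(252, 2, 6)), size = 5),
                21, 12)
    m[m == 0] <- 1L  # keep rows zero-free so both definitions apply
    rownames(m) <- paste0("g", 1:21); colnames(m) <- paste0("s", 1:12)
    ours <- medianOfRatios(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
  }
})

test_that("size factors scale with library size and renormalize to one", {
  m <- matrix(rpois(60, 100) + 1L, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(medianOfRatios(same)), rep(1, 3))
  doubled <- cbind(m, 2L * m[, 6, drop = FALSE])
  colnames(doubled) <- paste0("s", 1:7)
  sf <- medianOfRatios(doubled)
  expect_equal(unname(sf[7] / sf[6]), 2, tolerance = 1e-12)
  # normalization idempotence under the geometric-mean-1 convention:
  # factors of the normalized layer are all exactly 1
  hc <- normalizeCounts(homeologCounts(m))
  expect_equal(unname(medianOfRatios(normalizedCounts(hc), rescale = TRUE)),
               rep(1, 6), tolerance = 1e-9)
  # and the literal factors of the normalized layer are a single constant
  lit <- medianOfRatios(normalizedCounts(hc))
  expect_lt(max(lit) - min(lit), 1e-12)
  all_zero_row <- m; all_zero_row[, 1] <- 0L
  expect_error(medianOfRatios(all_zero_row), "zero-free")
})

test_that("the closed-form VST behaves at its limits and stabilizes variance", {
  expect_equal(vstClosedForm(0, 0.1), 0)
  x <- c(0, 1, 10, 1000)
  expect_lt(max(abs(vstClosedForm(x, 1e-10) - 2 * sqrt(x))), 1e-5)
  expect_error(vstClosedForm(-1, 0.1), "non-negative")
  # variance flatness across a 100-fold mean range
  set.seed(91)
  alpha <- 0.05
  vars <- vapply(c(50, 500, 5000), function(mu)
    var(vstClosedForm(rnbinom(10000, mu = mu, size = 1 / alpha), alpha)), 0)
  expect_lt(max(vars) / min(vars), 2)
})

test_that("row standardization divides by the mean and flags degenerates", {
  m <- rbind(a = c(2, 4, 6), b = c(5, 5, 5), z = c(0, 0, 0))
  out <- standardizeRows(m)
  expect_equal(unname(out["a", ]), c(0.5, 1.0, 1.5))
  expect_equal(unname(out["b", ]), rep(1, 3))
  expect_equal(unname(out["z", ]), rep(0, 3))
  expect_equal(unname(attr(out, "degenerate")), c(FALSE, FALSE, TRUE))
  expect_equal(unname(rowMeans(out)[c("a", "b")]), c(1, 1))
})

test_that("ordination separates stage groups and MDS agrees with PCA", {
  set.seed(95)
  early <- matrix(rnorm(60, 5, 0.1), 10, 6)
  late <- matrix(rnorm(60, 9, 0.1), 10, 6)
  m <- cbind(early[, 1:3], late[, 1:3])
  colnames(m) <- paste0("s", 1:6); rownames(m) <- paste0("g", 1:10)
  ord <- ordinateSamples(m)
  expect_gt(ord$variance_fraction[1], 0.5)
  # classical MDS of Euclidean distances equals PCA scores up to sign
  for (k in 1:2) {
    agreement <- abs(cor(ord$pca_scores[, k], ord$mds_points[, k]))
    expect_gt(agreement, 0.999)
  }
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(max(suppressWarnings(ordinateSamples(same))$distances), 0)
  expect_error(ordinateSamples(m[, 1:2]), "3 samples")
})

test_that("tocol correlations recover designed affine links exactly", {
  counts <- rbind(up = rep(c(1, 2, 4, 8), each = 3),
                  down = rep(9 - c(1, 2, 4, 8), each = 3))
  colnames(counts) <- paste0(rep(paste0("daa", c(7, 14, 21, 28)), each = 3),
                             "_R", 1:3)
  stages <- rep(paste0("daa", c(7, 14, 21, 28)), each = 3)
  tocols <- data.frame(stage = paste0("daa", c(7, 14, 21, 28)),
                       T3 = 3 + 2 * c(1, 2, 4, 8))
  co <- correlateWithTocols(counts, stages, tocols)
  expect_equal(unname(co$r["up", "T3"]), 1)
  expect_equal(unname(co$r["down", "T3"]), -1)
  expect_error(correlateWithTocols(counts, stages, tocols[1:2, ]),
               "3 stages")
})

test_that("designed correlations survive simulation noise across seeds", {
  hit_pos <- 0L; hit_neg <- 0L
  for (s in 1:10) {
    cfg <- simulationConfig(n_genes = 7, seed = s)
    ex <- simulateExpression(cfg)
    stages <- unique(ex$sample_sheet$stage)
    sm <- vapply(stages, function(st)
      mean(ex$expected["HPPD_1", ex$sample_sheet$stage == st]), 0)
    toc <- simulateTocols(sm, cfg, noise_frac = 0.1,
                          seed = deriveSeed(s, 77))
    hc <- vstCounts(normalizeCounts(homeologCounts(ex$counts)))
    co <- correlateWithTocols(normalizedCounts(hc), sampleStages(hc), toc)
    if (co$r["HPPD_1", "T3"] > 0.9) hit_pos <- hit_pos + 1L
    if (co$r["VTE4_2", "T3"] < -0.9) hit_neg <- hit_neg + 1L
  }
  expect_gte(hit_pos, 9L)
  expect_gte(hit_neg, 9L)
})
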