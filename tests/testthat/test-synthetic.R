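test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(ks_A_vs_D = 0.2), "ordering")
  expect_error(simulationConfig(omega = 0), "omega")
  expect_error(simulationConfig(coverage = 0), "coverage")
  expect_error(simulationConfig(ks_template = 2, ks_C_vs_AD = 1.8,
                                ks_A_vs_D = 0.5), "saturated")
})

test_that("zero divergence between copies 2 and 3 yields identical sequences", {
  cfg <- small_config()
  cfg$ks_A_vs_D <- 0  # bypass constructor ordering check deliberately
  tr <- evolveSubgenomes(cfg)
  hom <- tr[[1]]$homeologs
  expect_identical(unname(hom[2]), unname(hom[3]))
})

test_that("realized Ks hits the configured targets and ordering", {
  ks23 <- c(); ks1 <- c(); sym <- c()
  for (seed in 1:6) {
    cfg <- simulationConfig(n_genes = 1, cds_length_codons = 400,
                            seed = seed)
    tr <- evolveSubgenomes(cfg)
    k <- tr[[1]]$realized_ks
    ks23 <- c(ks23, k["GGR_2", "GGR_3"])
    ks1 <- c(ks1, mean(k["GGR_1", c("GGR_2", "GGR_3")]))
    sym <- c(sym, abs(k["GGR_1", "GGR_2"] - k["GGR_1", "GGR_3"]) /
               mean(k["GGR_1", c("GGR_2", "GGR_3")]))
    # ordering invariant: _2~_3 < _1 < template
    expect_lt(k["GGR_2", "GGR_3"], mean(k["GGR_1", c("GGR_2", "GGR_3")]))
    expect_lt(mean(k["GGR_1", c("GGR_2", "GGR_3")]),
              mean(k["template", 1:3]))
  }
  expect_gt(mean(ks23), 0.011)
  expect_lt(mean(ks23), 0.016)
  expect_gt(mean(ks1), 0.08)
  expect_lt(mean(ks1), 0.12)
  # near-symmetry of the ((2,3),1) topology
  expect_lt(mean(sym), 0.2)
})

test_that("the generator is deterministic given (config, seed)", {
  cfg <- small_config(seed = 5)
  a <- evolveSubgenomes(cfg)
  b <- evolveSubgenomes(cfg)
  expect_identical(a, b)
  ra <- simulateReads(a[[1]]$homeologs,
                      setNames(rep(50, 3), names(a[[1]]$homeologs)), cfg)
  rb <- simulateReads(b[[1]]$homeologs,
                      setNames(rep(50, 3), names(b[[1]]$homeologs)), cfg)
  expect_identical(readSequences(ra$pairs), readSequences(rb$pairs))
  ea <- simulateExpression(cfg); eb <- simulateExpression(cfg)
  expect_identical(ea$counts, eb$counts)
})

test_that("error-free reads are exact substrings of their source homeolog", {
  cfg <- small_config(seed = 3)
  tr <- evolveSubgenomes(cfg)
  hom <- tr[[1]]$homeologs
  rd <- simulateReads(hom, setNames(rep(40, 3), names(hom)), cfg)
  seqs <- readSequences(rd$pairs)
  src_of <- sub("_frag.*$", "", names(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    src <- hom[[src_of[i]]]
    expect_true(grepl(s, src, fixed = TRUE) ||
                  grepl(revcomp(s), src, fixed = TRUE))
  }
})

test_that("zero expected count yields zero reads; totals track Poisson", {
  cfg <- small_config(seed = 2)
  tr <- evolveSubgenomes(cfg)
  hom <- tr[[1]]$homeologs
  mu <- setNames(c(200, 0, 200), names(hom))
  totals <- matrix(0, 10, 3)
  for (s in 1:10) {
    rd <- simulateReads(hom, mu, cfg, seed = s)
    org <- rd$origin
    n <- table(factor(org$homeolog, levels = names(hom)))
    totals[s, ] <- as.integer(n)
  }
  expect_true(all(totals[, 2] == 0))
  # realized counts within 3 sigma of Poisson(200)
  expect_true(all(abs(totals[, c(1, 3)] - 200) <= 3 * sqrt(200)))
})

test_that("read counts sum to the number of recorded fragment origins", {
  cfg <- small_config(seed = 8)
  tr <- evolveSubgenomes(cfg)
  hom <- tr[[1]]$homeologs
  rd <- simulateReads(hom, setNames(rep(60, 3), names(hom)), cfg)
  expect_equal(length(rd$pairs), 2L * nrow(rd$origin))
})

test_that("read_length larger than the CDS is a config error", {
  cfg <- small_config()
  tr <- evolveSubgenomes(cfg)
  cfg$read_length <- 10000L
  expect_error(simulateReads(tr[[1]]$homeologs,
                             setNames(rep(10, 3), names(tr[[1]]$homeologs)),
                             cfg), "CDS length")
})

test_that("expression bias construction gives exact expected ratios", {
  cfg <- simulationConfig(n_genes = 5, seed = 4)
  ex <- simulateExpression(cfg)
  e <- ex$expected
  expect_equal(unname(e["VTE2_1", ] / e["VTE2_2", ]),
               rep(7, ncol(e)))
  expect_equal(unname(e["HGGT_1", ] / e["VTE2_2", ]),
               rep(15, ncol(e)))
  # all multipliers 1 and flat trends: all homeologs of a gene equal
  expect_equal(e["GGR_1", ], e["GGR_2", ])
})

test_that("negative multipliers are rejected", {
  cfg <- simulationConfig(n_genes = 2, seed = 1)
  bs <- defaultBiasSpec(c("GGR", "HPPD"))
  bs$multiplier[1] <- -1
  expect_error(simulateExpression(cfg, bs), "non-negative")
})

test_that("NB-sampled 7:1 ratio stays in the Monte-Carlo envelope", {
  ratios <- vapply(1:10, function(s) {
    cfg <- simulationConfig(n_genes = 5, dispersion = 0.05, seed = s)
    bs <- defaultBiasSpec(pathwayGeneNames(5))
    bs$baseline[bs$gene == "VTE2"] <- 1000
    ex <- simulateExpression(cfg, bs)
    tot <- rowSums(ex$counts)
    mean(tot[c("VTE2_1", "VTE2_3")]) / tot[["VTE2_2"]]
  }, 0)
  expect_true(all(ratios > 5.5 & ratios < 8.5))
})

test_that("tocol curves track the linked profile with the designed sign", {
  cfg <- simulationConfig(seed = 11)
  sm <- c(50, 120, 400, 700)  # rising stage means
  toc <- simulateTocols(sm, cfg, sign = 1, noise_frac = 0)
  expect_equal(cor(toc$T3, sm), 1)
  expect_equal(cor(toc$T, sm), 1)
  neg <- simulateTocols(sm, cfg, sign = -1, noise_frac = 0)
  expect_equal(cor(neg$T3, sm), -1)
  expect_true(all(toc$T3 >= toc$T))  # tocotrienol dominance
  expect_true(all(diff(toc$total) > 0))  # monotone accumulation
  cfg3 <- simulationConfig(seed = 1); cfg3$n_stages <- 2L
  expect_error(simulateTocols(c(1, 2), cfg3, seed = 1), "3 stages")
})

test_that("noisy tocol links stay strongly correlated across seeds", {
  cfg <- simulationConfig(seed = 1)
  sm <- c(50, 120, 400, 700)
  r <- vapply(1:10, function(s)
    cor(simulateTocols(sm, cfg, noise_frac = 0.1, seed = s)$T3, sm), 0)
  expect_gte(sum(r > 0.9), 9)
})

test_that("the truth-set writer emits all advertised plain-text outputs", {
  cfg <- small_config(cds_length_codons = 100L, coverage = 5,
                      long_coverage = 1)
  dir <- withr::local_tempdir()
  ts <- simulateTruthSet(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "true_homeologs.fasta")))
  expect_true(file.exists(file.path(dir, "templates.fasta")))
  expect_true(file.exists(file.path(dir, "true_counts.tsv")))
  expect_true(file.exists(file.path(dir, "tocol_profile.tsv")))
  expect_true(file.exists(file.path(dir, "truth_manifest.json")))
  fa <- readFasta(file.path(dir, "true_homeologs.fasta"))
  expect_equal(sort(names(fa)), sort(names(ts$genes[[1]]$homeologs)))
})
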