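test_that("exact substrings of a template pass the homology filter", {
  set.seed(21)
  tmpl <- c(geneA = random_dna(600))
  reads <- c(r1 = substr(tmpl[[1]], 101, 200),
             r2 = revcomp(substr(tmpl[[1]], 301, 400)))
  hf <- homologyFilter(reads, tmpl)
  expect_setequal(hf$by_template$geneA, c("r1", "r2"))
  expect_length(hf$discarded, 0)
})

test_that("random reads against an unrelated template are almost all discarded", {
  set.seed(22)
  tmpl <- c(geneA = random_dna(1200))
  reads <- setNames(vapply(1:10000, function(i) random_dna(100), ""),
                    paste0("r", 1:10000))
  hf <- homologyFilter(reads, tmpl)
  fp <- length(hf$by_template$geneA) / 10000
  expect_lt(fp, 0.01)
})

test_that("reads from a 10%-diverged homeolog are retained", {
  set.seed(23)
  cfg <- small_config(cds_length_codons = 300)
  tr <- evolveSubgenomes(cfg)
  tmpl <- setNames(tr[[1]]$template, "GGR")
  h1 <- tr[[1]]$homeologs[[1]]
  starts <- seq(1, nchar(h1) - 100, by = 37)
  reads <- setNames(substring(h1, starts, starts + 99),
                    paste0("r", seq_along(starts)))
  hf <- homologyFilter(reads, tmpl)
  expect_gte(length(hf$by_template$GGR) / length(reads), 0.9)
  expect_error(homologyFilter(reads, character(0)), "empty template")
})

test_that("strict mapping places error-free reads at their exact origin", {
  set.seed(24)
  ref <- c(ref = random_dna(500))
  reads <- c(a = substr(ref[[1]], 51, 150),
             b = revcomp(substr(ref[[1]], 201, 300)))
  pu <- mapReads(reads, ref, strictParams())
  pl <- placements(pu)
  expect_equal(nrow(pl), 2L)
  expect_equal(pl$start[pl$read_id == "a"], 50L)   # 0-based
  expect_equal(pl$end[pl$read_id == "a"], 150L)
  expect_equal(pl$strand[pl$read_id == "b"], "-")
  expect_equal(pl$mismatches, c(0L, 0L))
})

test_that("reads exceeding the mismatch budget go unmapped", {
  set.seed(25)
  ref <- c(ref = random_dna(400))
  r <- substr(ref[[1]], 101, 200)
  ch <- strsplit(r, "")[[1]]
  pos <- sample(100, 26)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  bad <- paste(ch, collapse = "")
  # keep one clean seed window so candidates exist, identity still < 0.75
  pu <- mapReads(c(x = bad), ref, mappingParams(0.75, 0.75))
  expect_equal(nrow(placements(pu)), 0L)
  expect_equal(pu@n_unmapped, 1L)
})

test_that("50x error-free coverage leaves no low-depth columns", {
  for (seed in 1:3) {
    cfg <- small_config(cds_length_codons = 150, coverage = 50, seed = seed)
    tr <- evolveSubgenomes(cfg)
    hom <- tr[[1]]$homeologs
    L <- nchar(hom[[1]])
    nfrag <- cfg$coverage * L / (2 * cfg$read_length)
    rd <- simulateReads(hom, setNames(rep(nfrag, 3), names(hom)), cfg,
                        seed = seed)
    pu <- mapReads(rd$pairs, setNames(tr[[1]]$template, "g"),
                   mappingParams(), seed = seed)
    # uniform fragment starts taper off at the reference ends, so the
    # depth guarantee applies to the interior
    interior <- seq(cfg$read_length, L - cfg$read_length)
    expect_true(all(pileupDepth(pu)[interior] >= 10))
    expect_true(all(pileupDepth(pu) > 0))
  }
})

test_that("consensus calling follows majority, tie and zero-depth rules", {
  counts <- matrix(0L, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 1] <- 9L; counts["C", 1] <- 1L     # majority A
  counts["A", 2] <- 5L; counts["C", 2] <- 5L     # tie -> A (alphabetical)
  # column 3 depth 0 -> keep reference base
  pu <- new("Pileup", refname = "r", reference = "GGT", counts = counts,
            placements = data.frame(), n_unmapped = 0L)
  expect_equal(unname(callConsensus(pu)), "AAT")
})

test_that("iterative assembly reaches a fixed point on template-derived reads", {
  set.seed(26)
  tmpl <- c(g = random_dna(400))
  starts <- rep(seq(1, 301, by = 10), each = 3)
  reads <- setNames(substring(tmpl[[1]], starts, starts + 99),
                    paste0("r", seq_along(starts)))
  out <- iterateToConvergence(reads, tmpl)
  expect_true(out$converged)
  expect_equal(unname(out$consensus), tmpl[[1]])
  # first mapping cycle already reproduces the template, so no change is
  # ever observed
  expect_equal(out$history$changed_positions[nrow(out$history)], 0L)
})

test_that("assembly converges to the majority mixture and is deterministic", {
  cfg <- small_config(cds_length_codons = 200, coverage = 50, seed = 31)
  tr <- evolveSubgenomes(cfg)
  hom <- tr[[1]]$homeologs
  L <- nchar(hom[[1]])
  nfrag <- cfg$coverage * L / (2 * cfg$read_length)
  rd <- simulateReads(hom, setNames(rep(nfrag, 3), names(hom)), cfg,
                      seed = 31)
  tmpl <- setNames(tr[[1]]$template, "g")
  a <- iterateToConvergence(readSequences(rd$pairs), tmpl, seed = 7)
  b <- iterateToConvergence(readSequences(rd$pairs), tmpl, seed = 7)
  expect_true(a$converged)
  expect_identical(a$consensus, b$consensus)
  expect_identical(a$pileup@counts, b$pileup@counts)
  # fixed point: remap to the converged consensus and re-call
  pu <- mapReads(readSequences(rd$pairs), a$consensus, seed = 99)
  expect_equal(unname(callConsensus(pu)), unname(a$consensus))
  # majority-mixture: at every position >= 2 of 3 homeologs agree with it
  cons <- strsplit(unname(a$consensus), "")[[1]]
  hm <- do.call(rbind, strsplit(unname(hom), ""))
  agree <- colSums(hm == matrix(cons, 3, L, byrow = TRUE))
  expect_gte(mean(agree >= 2), 0.99)
})

test_that("changed positions shrink along iterations in most runs", {
  drops <- 0L; steps <- 0L
  for (seed in 41:45) {
    cfg <- small_config(cds_length_codons = 120, coverage = 40, seed = seed)
    tr <- evolveSubgenomes(cfg)
    hom <- tr[[1]]$homeologs
    nfrag <- cfg$coverage * nchar(hom[[1]]) / (2 * cfg$read_length)
    rd <- simulateReads(hom, setNames(rep(nfrag, 3), names(hom)), cfg,
                        seed = seed)
    out <- iterateToConvergence(readSequences(rd$pairs),
                                setNames(tr[[1]]$template, "g"), seed = seed)
    ch <- out$history$changed_positions
    if (length(ch) > 1) {
      steps <- steps + length(ch) - 1L
      drops <- drops + sum(diff(ch) <= 0)
    }
  }
  expect_gte(drops / steps, 0.9)
})
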