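make_pileup <- function(reference, counts, placements = NULL) {
  if (is.null(placements))
    placements <- data.frame(read_id = character(0), start = integer(0),
                             end = integer(0), strand = character(0),
                             mismatches = integer(0), bases = character(0))
  new("Pileup", refname = "g", reference = reference, counts = counts,
      placements = placements, n_unmapped = 0L)
}

test_that("variant classification follows depth, frequency and count rules", {
  counts <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 1] <- 30L                          # invariant
  counts["A", 2] <- 20L; counts["G", 2] <- 10L   # biallelic
  counts["A", 3] <- 12L; counts["C", 3] <- 10L; counts["G", 3] <- 8L  # tri
  counts["A", 4] <- 28L; counts["C", 4] <- 2L    # minor allele fails both
  pu <- make_pileup("AAAA", counts)
  v <- callVariantColumns(pu)
  expect_equal(v$position, c(1L, 2L))
  expect_equal(v$class, c("biallelic", "triallelic"))
  # low depth suppresses calls
  v2 <- callVariantColumns(pu, min_depth = 50)
  expect_equal(nrow(v2), 0L)
})

test_that("perfectly linked alleles phase into exactly two clusters", {
  # two variant columns, AB vs ab reads
  ref <- strrep("A", 20)
  reads <- data.frame(
    read_id = paste0("r", 1:8),
    start = 0L, end = 20L, strand = "+", mismatches = 0L,
    bases = rep(c(paste0("C", strrep("A", 9), "G", strrep("A", 9)),
                  paste0("T", strrep("A", 9), "T", strrep("A", 9))), 4))
  counts <- matrix(0L, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["C", 1] <- 4L; counts["T", 1] <- 4L
  counts["G", 11] <- 4L; counts["T", 11] <- 4L
  counts["A", 2:10] <- 8L; counts["A", 12:20] <- 8L
  pu <- make_pileup(ref, counts, reads)
  v <- callVariantColumns(pu, min_depth = 5)
  expect_equal(nrow(v), 2L)
  ph <- phaseReads(pu, v)
  expect_equal(length(ph$clusters), 2L)
  sizes <- sort(vapply(ph$clusters, `[[`, 0L, "size"))
  expect_equal(sizes, c(4L, 4L))
})

test_that("fragments spanning no variant stay unassigned", {
  ref <- strrep("A", 30)
  reads <- data.frame(
    read_id = c("x", "y"),
    start = c(0L, 20L), end = c(10L, 30L), strand = "+", mismatches = 0L,
    bases = c(paste0("C", strrep("A", 9)), strrep("A", 10)))
  counts <- matrix(0L, 4, 30, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["C", 1] <- 5L; counts["T", 1] <- 5L
  pu <- make_pileup(ref, counts, reads)
  v <- callVariantColumns(pu, min_depth = 4)
  ph <- phaseReads(pu, v)
  expect_true("y" %in% ph$unassigned)
  expect_error(phaseReads(pu, v[0, ]), "at least one variant")
})

test_that("three simulated homeologs phase into three truth-matching clusters", {
  for (seed in 1:3) {
    cfg <- small_config(cds_length_codons = 250, coverage = 50, seed = seed)
    tr <- evolveSubgenomes(cfg)
    hom <- tr[[1]]$homeologs
    nfrag <- cfg$coverage * nchar(hom[[1]]) / (2 * cfg$read_length)
    rd <- simulateReads(hom, setNames(rep(nfrag, 3), names(hom)), cfg,
                        seed = seed)
    asm <- iterateToConvergence(rd$pairs, setNames(tr[[1]]$template, "GGR"),
                                seed = seed)
    v <- callVariantColumns(asm$pileup)
    # error-free high coverage: no false calls, and every truth SNP away
    # from the low-depth reference edges is recovered
    expect_true(all((v$position + 1L) %in% tr[[1]]$snp_positions))
    L <- nchar(hom[[1]])
    interior <- tr[[1]]$snp_positions[
      tr[[1]]$snp_positions > cfg$read_length &
        tr[[1]]$snp_positions <= L - cfg$read_length]
    expect_true(all(interior %in% (v$position + 1L)))
    ph <- phaseReads(asm$pileup, v)
    hs <- reconstructHomeologs(ph, asm$pileup, gene = "GGR")
    expect_equal(length(homeologMembers(hs)), 3L)
    rec <- homeologRecovery(hs, hom)
    expect_gte(rec$mean_identity, 0.99)
    expect_true(rec$label_1_correct)
  }
})

test_that("cluster membership is a partition of variant-spanning fragments", {
  cfg <- small_config(cds_length_codons = 200, coverage = 40, seed = 10)
  tr <- evolveSubgenomes(cfg)
  hom <- tr[[1]]$homeologs
  nfrag <- cfg$coverage * nchar(hom[[1]]) / (2 * cfg$read_length)
  rd <- simulateReads(hom, setNames(rep(nfrag, 3), names(hom)), cfg,
                      seed = 10)
  asm <- iterateToConvergence(rd$pairs, setNames(tr[[1]]$template, "g"),
                              seed = 10)
  v <- callVariantColumns(asm$pileup)
  ph <- phaseReads(asm$pileup, v)
  members <- unlist(lapply(ph$clusters, `[[`, "fragments"))
  expect_equal(anyDuplicated(members), 0L)
  all_frags <- unique(sub("/[12]$", "", placements(asm$pileup)$read_id))
  expect_equal(sort(c(members, ph$unassigned)), sort(all_frags))
})

test_that("reconstructed homeologs differ only at called variant columns", {
  cfg <- small_config(cds_length_codons = 200, coverage = 50, seed = 12)
  tr <- evolveSubgenomes(cfg)
  hom <- tr[[1]]$homeologs
  nfrag <- cfg$coverage * nchar(hom[[1]]) / (2 * cfg$read_length)
  rd <- simulateReads(hom, setNames(rep(nfrag, 3), names(hom)), cfg,
                      seed = 12)
  asm <- iterateToConvergence(rd$pairs, setNames(tr[[1]]$template, "g"),
                              seed = 12)
  v <- callVariantColumns(asm$pileup)
  ph <- phaseReads(asm$pileup, v)
  hs <- reconstructHomeologs(ph, asm$pileup, gene = "g")
  mem <- as.character(homeologMembers(hs))
  if (length(mem) >= 2) {
    mat <- do.call(rbind, strsplit(mem, ""))
    diffcols <- which(apply(mat, 2, function(cl) length(unique(cl)) > 1))
    expect_true(all(diffcols %in% (v$position + 1L)))
  }
})

test_that("a single cluster yields a one-member set labelled _1", {
  ref <- strrep("A", 20)
  reads <- data.frame(read_id = paste0("r", 1:6), start = 0L, end = 20L,
                      strand = "+", mismatches = 0L,
                      bases = c(rep(paste0("C", strrep("A", 19)), 5),
                                rep(paste0("T", strrep("A", 19)), 1)))
  counts <- matrix(0L, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["C", 1] <- 5L; counts["T", 1] <- 5L
  counts["A", 2:20] <- 10L
  pu <- make_pileup(ref, counts, reads)
  v <- callVariantColumns(pu, min_depth = 4, min_allele_count = 5)
  ph <- phaseReads(pu, v)
  keep <- which(vapply(ph$clusters, `[[`, 0L, "size") >= 5L)
  ph$clusters <- ph$clusters[keep]
  hs <- reconstructHomeologs(ph, pu, gene = "g", min_completeness = 0.5)
  expect_equal(names(homeologMembers(hs)), "g_1")
})

test_that("SNP summaries add up across genes", {
  v1 <- data.frame(class = c(rep("biallelic", 10)))
  v2 <- data.frame(class = c(rep("biallelic", 5), "triallelic"))
  out <- summarizeSnps(list(g1 = v1, g2 = v2))
  expect_equal(out$total[out$gene == "TOTAL"], 16)
  expect_equal(out$biallelic[out$gene == "TOTAL"], 15)
  expect_equal(out$triallelic[out$gene == "TOTAL"], 1)
  empty <- summarizeSnps(list(g = data.frame(class = character(0))))
  expect_equal(empty$total[empty$gene == "TOTAL"], 0)
})
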