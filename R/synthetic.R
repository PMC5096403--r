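## Ground-truthed hexaploid transcriptome simulator.
##
## Three homeolog copies per gene evolve on the tree ((2,3),1) with an
## outgroup ortholog template: copies 2 and 3 are recently diverged
## (default true synonymous rate 0.0137), copy 1 is ~7x more diverged
## (default 0.10) and the related-species template further still (0.30).
## Synonymous changes are placed at third positions within synonymous codon
## classes and nonsynonymous changes at rate omega x the synonymous rate; a
## calibration loop adjusts substitution counts until the realized NG86 dS
## matches the targets.

#' Simulation configuration
#'
#' @param n_genes number of genes (default 5; the first genes take the
#'   tocochromanol-pathway names GGR, HPPD, HGGT, VTE1, VTE2, VTE3, VTE4).
#' @param cds_length_codons codons per CDS (default 400).
#' @param ks_A_vs_D true synonymous divergence between homeologs 2 and 3.
#' @param ks_C_vs_AD true synonymous divergence of homeolog 1 from 2/3.
#' @param ks_template divergence of the related-species ortholog template.
#' @param omega nonsynonymous/synonymous rate ratio in (0, 1].
#' @param coverage mean per-homeolog short-read depth.
#' @param read_length short-read length (bases).
#' @param insert_size paired-end fragment length.
#' @param error_rate per-base substitution error probability.
#' @param low_quality_tail fraction of short reads receiving a sub-Q20
#'   3' tail (exercises the quality trimmer).
#' @param ambiguous_base_rate fraction of reads receiving one N.
#' @param long_coverage mean long single-end read depth.
#' @param n_stages developmental stages (default 4: daa7/14/21/28).
#' @param n_replicates replicates per stage (default 3).
#' @param dispersion negative-binomial dispersion of observed counts.
#' @param seed global RNG seed; every module stream derives from it.
#' @return a validated \code{SimulationConfig} list.
#' @export
simulationConfig <- function(n_genes = 5L, cds_length_codons = 400L,
                             ks_A_vs_D = 0.0137, ks_C_vs_AD = 0.10,
                             ks_template = 0.30, omega = 0.1,
                             coverage = 50, read_length = 100L,
                             insert_size = 300L, error_rate = 0.01,
                             low_quality_tail = 0.10,
                             ambiguous_base_rate = 0.01,
                             long_coverage = 5,
                             n_stages = 4L, n_replicates = 3L,
                             dispersion = 0.05, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              cds_length_codons = as.integer(cds_length_codons),
              ks_A_vs_D = ks_A_vs_D, ks_C_vs_AD = ks_C_vs_AD,
              ks_template = ks_template, omega = omega,
              coverage = coverage, read_length = as.integer(read_length),
              insert_size = as.integer(insert_size), error_rate = error_rate,
              low_quality_tail = low_quality_tail,
              ambiguous_base_rate = ambiguous_base_rate,
              long_coverage = long_coverage,
              n_stages = as.integer(n_stages),
              n_replicates = as.integer(n_replicates),
              dispersion = dispersion, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  with(cfg, {
    if (ks_A_vs_D < 0 || ks_C_vs_AD < 0 || ks_template < 0)
      stop("divergence targets must be >= 0", call. = FALSE)
    if (!(ks_A_vs_D < ks_C_vs_AD && ks_C_vs_AD < ks_template))
      stop("divergence ordering ks_A_vs_D < ks_C_vs_AD < ks_template ",
           "violated", call. = FALSE)
    if (ks_template > 1.5)
      stop("requested template divergence is saturated at this length",
           call. = FALSE)
    if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
    if (omega <= 0 || omega > 1) stop("omega must be in (0, 1]", call. = FALSE)
    if (n_genes < 1 || cds_length_codons < 30)
      stop("need >= 1 gene and >= 30 codons", call. = FALSE)
  })
  invisible(cfg)
}

pathwayGeneNames <- function(n) {
  base <- c("GGR", "HPPD", "HGGT", "VTE1", "VTE2", "VTE3", "VTE4")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("GENE%d", seq(length(base) + 1L, n)))
}

stageLabels <- function(n_stages) paste0("daa", seq_len(n_stages) * 7L)

## codon mutation alternatives (cached)
mutationAlternatives <- function() {
  if (!is.null(.ng86_cache$alts)) return(.ng86_cache$alts)
  codons <- allCodons()
  aa <- codonAA()
  syn3 <- lapply(codons, function(cd) {
    if (aa[cd] == "*") return(character(0))
    alts <- paste0(substr(cd, 1, 2), setdiff(DNA_BASES_, substr(cd, 3, 3)))
    alts[aa[alts] == aa[cd]]
  })
  nonsyn <- lapply(codons, function(cd) {
    if (aa[cd] == "*") return(character(0))
    out <- character(0)
    for (pos in 1:3) for (b in setdiff(DNA_BASES_, substr(cd, pos, pos))) {
      alt <- cd
      substr(alt, pos, pos) <- b
      if (aa[alt] != "*" && aa[alt] != aa[cd]) out <- c(out, alt)
    }
    out
  })
  names(syn3) <- names(nonsyn) <- codons
  .ng86_cache$alts <- list(syn3 = syn3, nonsyn = nonsyn)
  .ng86_cache$alts
}

randomCDS <- function(n_codons) {
  codons <- allCodons()
  sense <- codons[codonAA()[codons] != "*"]
  sample(sense, n_codons, replace = TRUE)
}

mutateCodons <- function(codons, n_syn, n_nonsyn) {
  alts <- mutationAlternatives()
  for (i in seq_len(n_syn)) {
    eligible <- which(lengths(alts$syn3[codons]) > 0L)
    j <- eligible[sample.int(length(eligible), 1L)]
    opts <- alts$syn3[[codons[j]]]
    codons[j] <- opts[sample.int(length(opts), 1L)]
  }
  for (i in seq_len(n_nonsyn)) {
    j <- sample.int(length(codons), 1L)
    opts <- alts$nonsyn[[codons[j]]]
    codons[j] <- opts[sample.int(length(opts), 1L)]
  }
  codons
}

## invert Jukes-Cantor: observed proportion for a target distance
jcForward <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Evolve homeolog triples and an ortholog template
#'
#' Simulates, per gene, an ancestral CDS and evolves three homeolog copies
#' on the tree ((2,3),1) plus an outgroup template. Substitution counts per
#' branch start from the Jukes-Cantor-inverted targets and are calibrated
#' by remeasuring realized NG86 dS and rescaling (up to 5 rounds, 8%
#' tolerance), so the true pairwise Ks is a controlled quantity.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with one element per gene: \code{template},
#'   \code{homeologs} (named \code{<gene>_1/_2/_3}), \code{snp_positions}
#'   (1-based positions where the three copies are not identical),
#'   \code{realized_ks} (pairwise dS matrix over homeologs + template).
#' @export
evolveSubgenomes <- function(config) {
  validateConfig(config)
  L <- config$cds_length_codons
  genes <- pathwayGeneNames(config$n_genes)
  out <- vector("list", config$n_genes)
  names(out) <- genes
  for (g in seq_len(config$n_genes)) {
    set.seed(deriveSeed(config$seed, 1000L + g))
    anc <- randomCDS(L)
    S <- unname(ng86Sites(paste(anc, collapse = ""))["S"])
    # initial branch substitution counts (syn), from JC-inverted proportions
    d23 <- max(jcForward(config$ks_A_vs_D) * S / 2, 0)
    d1 <- max(jcForward(config$ks_C_vs_AD) * S - d23, 0)
    dt <- max(jcForward(config$ks_template) * S - (d1 + d23) / 2, 0)
    nsyn <- c(h2 = d23, h3 = d23, h1 = d1, tmpl = dt)
    best <- NULL
    for (round in 1:5) {
      set.seed(deriveSeed(config$seed, 2000L + g * 10L + round))
      n <- round(nsyn)
      nn <- round(config$omega * n * 3)  # N/S ~ 3 for random codons
      h2 <- mutateCodons(anc, n[["h2"]], nn[["h2"]])
      h3 <- mutateCodons(anc, n[["h3"]], nn[["h3"]])
      h1 <- mutateCodons(anc, n[["h1"]], nn[["h1"]])
      tm <- mutateCodons(anc, n[["tmpl"]], nn[["tmpl"]])
      seqs <- c(paste(h1, collapse = ""), paste(h2, collapse = ""),
                paste(h3, collapse = ""), paste(tm, collapse = ""))
      names(seqs) <- c(paste0(genes[g], "_", 1:3), "template")
      ks <- ksDistanceMatrix(seqs)
      r23 <- ks[2, 3]
      r1 <- mean(ks[1, 2:3])
      rt <- mean(ks[4, 1:3])
      best <- list(seqs = seqs, ks = ks)
      ok23 <- config$ks_A_vs_D == 0 ||
        abs(r23 - config$ks_A_vs_D) <= 0.08 * config$ks_A_vs_D
      ok1 <- abs(r1 - config$ks_C_vs_AD) <= 0.08 * config$ks_C_vs_AD
      okt <- abs(rt - config$ks_template) <= 0.10 * config$ks_template
      if (ok23 && ok1 && okt) break
      adj <- function(cur, target, realized)
        if (target == 0 || realized <= 0) cur
        else cur * min(max(target / realized, 0.5), 2)
      nsyn[c("h2", "h3")] <- adj(nsyn[["h2"]], config$ks_A_vs_D, r23)
      nsyn[["h1"]] <- adj(nsyn[["h1"]], config$ks_C_vs_AD - config$ks_A_vs_D / 2,
                          r1 - r23 / 2)
      nsyn[["tmpl"]] <- adj(nsyn[["tmpl"]],
                            config$ks_template - (config$ks_C_vs_AD +
                                                    config$ks_A_vs_D) / 2,
                            rt - (r1 + r23) / 2)
    }
    seqs <- best$seqs
    hom <- seqs[1:3]
    mat <- do.call(rbind, strsplit(unname(hom), "", fixed = TRUE))
    snp <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
    out[[g]] <- list(template = unname(seqs[["template"]]),
                     homeologs = hom,
                     snp_positions = snp,
                     realized_ks = best$ks)
  }
  out
}

phredString <- function(q) intToUtf8(q + 33L)

#' Simulate sequencing reads from homeolog sequences
#'
#' Draws Poisson fragment counts per homeolog around the expected counts,
#' uniform fragment positions on either strand, substitution errors at the
#' configured rate, and a two-state quality model (high ~Q38 body, ~Q12
#' 3' tails on a configurable fraction of reads) that exercises the Q20
#' trimmer. Read ids record the true source homeolog.
#'
#' @param homeologs named character vector of source sequences.
#' @param expected_counts named numeric, expected fragments per homeolog
#'   (names matching \code{homeologs}).
#' @param config a \code{\link{simulationConfig}}.
#' @param seed RNG seed (default derived from the config seed).
#' @param long also simulate long single-end reads (lengths 90 to
#'   min(861, CDS length)) at \code{long_coverage}.
#' @return list: \code{pairs} (\linkS4class{ReadSet} of mate-linked short
#'   reads), \code{long} (\linkS4class{ReadSet} or NULL), \code{origin}
#'   (data.frame fragment id -> true homeolog).
#' @export
simulateReads <- function(homeologs, expected_counts, config,
                          seed = deriveSeed(config$seed, 3000L),
                          long = TRUE) {
  if (any(nchar(homeologs) < config$insert_size))
    stop("insert_size exceeds CDS length", call. = FALSE)
  if (config$read_length > min(nchar(homeologs)))
    stop("read_length exceeds CDS length", call. = FALSE)
  set.seed(seed)
  rl <- config$read_length
  ids_l <- list(); seqs_l <- list(); mates_l <- list()
  origin <- list()
  for (h in names(homeologs)) {
    mu <- expected_counts[[h]]
    n <- if (mu > 0) rpois(1L, mu) else 0L
    if (n == 0L) next
    src <- homeologs[[h]]
    L <- nchar(src)
    starts <- sample.int(L - config$insert_size + 1L, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    frag_ids <- sprintf("%s_frag%05d", h, seq_len(n))
    frags <- substring(src, starts, starts + config$insert_size - 1L)
    neg <- strands == "-"
    if (any(neg)) frags[neg] <- reverseComplement_(frags[neg])
    r1 <- substring(frags, 1L, rl)
    r2 <- reverseComplement_(substring(frags, config$insert_size - rl + 1L,
                                       config$insert_size))
    id1 <- paste0(frag_ids, "/1"); id2 <- paste0(frag_ids, "/2")
    ids_l[[h]] <- as.vector(rbind(id1, id2))
    seqs_l[[h]] <- as.vector(rbind(r1, r2))
    mates_l[[h]] <- as.vector(rbind(id2, id1))
    origin[[h]] <- data.frame(fragment = frag_ids, homeolog = h,
                              start = starts, strand = strands)
  }
  ids <- unlist(ids_l, use.names = FALSE)
  seqs <- unlist(seqs_l, use.names = FALSE)
  mates <- unlist(mates_l, use.names = FALSE)
  if (is.null(ids)) { ids <- character(0); seqs <- character(0)
                      mates <- character(0) }
  n_reads <- length(seqs)
  quals <- list()
  if (n_reads) {
    seqs <- addSequencingErrors(seqs, config$error_rate)
    seqs <- addAmbiguousBases(seqs, config$ambiguous_base_rate)
    quals <- drawQualities(seqs, config$low_quality_tail)
  }
  pairs <- new("ReadSet", id = ids, sequence = seqs, quality = quals,
               mate = mates, platform = "short_paired")
  long_set <- NULL
  if (long && config$long_coverage > 0) {
    lids <- character(0); lseqs <- character(0)
    max_len <- min(861L, min(nchar(homeologs)))
    for (h in names(homeologs)) {
      L <- nchar(homeologs[[h]])
      n <- rpois(1L, config$long_coverage * L / ((90 + max_len) / 2))
      if (n == 0L) next
      lens <- sample(90:max_len, n, replace = TRUE)
      starts <- vapply(lens, function(l)
        sample.int(L - l + 1L, 1L), 1L)
      for (i in seq_len(n)) {
        s <- substr(homeologs[[h]], starts[i], starts[i] + lens[i] - 1L)
        if (runif(1) < 0.5) s <- reverseComplement_(s)
        lids <- c(lids, sprintf("%s_long%05d", h, i))
        lseqs <- c(lseqs, s)
      }
    }
    if (length(lseqs)) {
      lseqs <- addSequencingErrors(lseqs, config$error_rate)
      lseqs <- addAmbiguousBases(lseqs, config$ambiguous_base_rate)
      lquals <- drawQualities(lseqs, config$low_quality_tail)
      long_set <- new("ReadSet", id = lids, sequence = lseqs,
                      quality = lquals,
                      mate = rep(NA_character_, length(lids)),
                      platform = "long_single")
    }
  }
  origin_df <- if (length(origin))
    do.call(rbind, c(origin, list(make.row.names = FALSE))) else NULL
  list(pairs = pairs, long = long_set, origin = origin_df)
}

addSequencingErrors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, error_rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) {
      alt <- setdiff(DNA_BASES_, ch[p])
      ch[p] <- alt[sample.int(3L, 1L)]
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

addAmbiguousBases <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  hit <- runif(length(seqs)) < rate
  if (!any(hit)) return(seqs)
  seqs[hit] <- vapply(seqs[hit], function(s) {
    p <- sample.int(nchar(s), 1L)
    substr(s, p, p) <- "N"
    s
  }, "", USE.NAMES = FALSE)
  seqs
}

drawQualities <- function(seqs, low_quality_tail) {
  lens <- nchar(seqs)
  lapply(seq_along(seqs), function(i) {
    q <- pmin(pmax(38L + sample(-2:2, lens[i], replace = TRUE), 2L), 41L)
    if (runif(1) < low_quality_tail) {
      tail_len <- min(sample(5:30, 1L), lens[i] - 1L)
      idx <- seq(lens[i] - tail_len + 1L, lens[i])
      q[idx] <- pmin(pmax(12L + sample(-3:3, tail_len, replace = TRUE), 2L),
                     19L)
    }
    as.integer(q)
  })
}

#' Default homeolog expression bias specification
#'
#' Encodes the study conditions the simulator emulates: near-equal homeolog
#' expression for most genes; a 7:1:7 homeolog bias for VTE2; HGGT baseline
#' 15-fold above VTE2; HPPD homeologs rising sigmoidally with seed
#' development (the tocol-linked profile); VTE4_1 elevated and rising,
#' VTE4_2/_3 declining (the anti-linked profiles).
#'
#' @param genes character vector of gene names.
#' @return data.frame with columns gene, homeolog, baseline, multiplier,
#'   trend (flat/increasing/decreasing).
#' @export
defaultBiasSpec <- function(genes) {
  baseline <- c(GGR = 300, HPPD = 400, HGGT = 1500, VTE1 = 300, VTE2 = 100,
                VTE3 = 300, VTE4 = 200)
  rows <- lapply(genes, function(g) {
    b <- if (g %in% names(baseline)) baseline[[g]] else 300
    mult <- c(1, 1, 1)
    trend <- rep("flat", 3L)
    if (g == "VTE2") mult <- c(7, 1, 7)
    if (g == "HPPD") trend <- rep("increasing", 3L)
    if (g == "VTE4") { mult <- c(5, 1, 1)
                       trend <- c("increasing", "decreasing", "decreasing") }
    data.frame(gene = g, homeolog = 1:3, baseline = b, multiplier = mult,
               trend = trend)
  })
  do.call(rbind, rows)
}

sigmoidStageShape <- function(n_stages) {
  k <- seq_len(n_stages)
  stats::plogis((k - (n_stages + 1) / 2) * 1.6)
}

trendFactor <- function(trend, n_stages) {
  s <- sigmoidStageShape(n_stages)
  switch(trend,
         flat = rep(1, n_stages),
         increasing = 0.15 + 2.85 * s,
         decreasing = 0.15 + 2.85 * (1 - s),
         stop("unknown trend: ", trend, call. = FALSE))
}

#' Simulate a homeolog-specific expression matrix
#'
#' Expected counts are baseline x homeolog multiplier x stage trend factor x
#' per-sample library-size factor; observed counts are negative-binomial
#' draws around the expectation with the configured dispersion (Poisson in
#' the zero-dispersion limit).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param bias_spec data.frame as \code{\link{defaultBiasSpec}} (the
#'   default).
#' @param seed RNG seed (default derived from the config seed).
#' @return list: \code{expected} and \code{counts} (homeolog x sample
#'   matrices), \code{sample_sheet} (sample, stage, replicate),
#'   \code{library_factors} (true per-sample scalings), \code{bias_spec}.
#' @export
simulateExpression <- function(config,
                               bias_spec = defaultBiasSpec(
                                 pathwayGeneNames(config$n_genes)),
                               seed = deriveSeed(config$seed, 4000L)) {
  if (any(bias_spec$multiplier < 0) || any(bias_spec$baseline < 0))
    stop("baselines and multipliers must be non-negative", call. = FALSE)
  set.seed(seed)
  stages <- stageLabels(config$n_stages)
  samples <- as.vector(outer(stages, paste0("R", seq_len(config$n_replicates)),
                             paste, sep = "_"))
  sample_stage <- rep(stages, times = config$n_replicates)
  lib <- exp(rnorm(length(samples), 0, 0.15))
  lib <- lib / exp(mean(log(lib)))  # geometric mean 1
  names(lib) <- samples
  rows <- paste0(bias_spec$gene, "_", bias_spec$homeolog)
  expected <- matrix(0, nrow(bias_spec), length(samples),
                     dimnames = list(rows, samples))
  for (i in seq_len(nrow(bias_spec))) {
    tf <- trendFactor(bias_spec$trend[i], config$n_stages)
    names(tf) <- stages
    expected[i, ] <- bias_spec$baseline[i] * bias_spec$multiplier[i] *
      tf[sample_stage] * lib
  }
  counts <- expected
  if (config$dispersion > 1e-10) {
    counts[] <- rnbinom(length(expected), mu = expected,
                        size = 1 / config$dispersion)
  } else {
    counts[] <- rpois(length(expected), expected)
  }
  storage.mode(counts) <- "integer"
  list(expected = expected, counts = counts,
       sample_sheet = data.frame(sample = samples, stage = sample_stage,
                                 replicate = rep(paste0("R",
                                   seq_len(config$n_replicates)),
                                   each = config$n_stages)),
       library_factors = lib, bias_spec = bias_spec)
}

#' Simulate tocochromanol accumulation profiles
#'
#' Builds monotone sigmoidal tocopherol (T) and tocotrienol (T3) curves over
#' the developmental stages as an affine function of a designated homeolog's
#' stage-mean expression plus Gaussian noise, with tocotrienol dominance
#' (T3 > T), so the designed Pearson correlations are recoverable from the
#' data.
#'
#' @param stage_means numeric vector (one value per stage): the linked
#'   homeolog's stage-mean expression.
#' @param config a \code{\link{simulationConfig}}.
#' @param sign +1 (curves rise with the profile) or -1 (fall).
#' @param noise_frac Gaussian noise sd as a fraction of each curve's range.
#' @param seed RNG seed.
#' @return data.frame: stage, T, T3, total (concentrations, micrograms per
#'   gram).
#' @export
simulateTocols <- function(stage_means, config, sign = 1, noise_frac = 0.1,
                           seed = deriveSeed(config$seed, 5000L)) {
  if (config$n_stages < 3L)
    stop("correlation undefined with fewer than 3 stages", call. = FALSE)
  if (length(stage_means) != config$n_stages)
    stop("stage_means must have one value per stage", call. = FALSE)
  set.seed(seed)
  u <- (stage_means - min(stage_means)) /
    max(max(stage_means) - min(stage_means), .Machine$double.eps)
  if (sign < 0) u <- 1 - u
  t3_range <- 17; t_range <- 7
  T3 <- 4 + t3_range * u + rnorm(length(u), 0, noise_frac * t3_range)
  Tt <- 2 + t_range * u + rnorm(length(u), 0, noise_frac * t_range)
  T3 <- pmax(T3, 0); Tt <- pmax(Tt, 0)
  data.frame(stage = stageLabels(config$n_stages), T = Tt, T3 = T3,
             total = Tt + T3)
}

#' Generate the full ground-truthed synthetic dataset
#'
#' Runs sequence evolution, read simulation (pooled short pairs + long
#' reads at the configured coverages, for assembly), expression simulation
#' and tocol simulation, and optionally writes everything to disk (FASTA,
#' FASTQ, TSV, JSON manifest). Fully deterministic given (config, seed).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param dir optional output directory.
#' @param tocol_link homeolog id whose stage means the tocol curves track.
#' @param tocol_noise noise fraction for the tocol curves.
#' @return list: \code{genes} (per-gene truth from
#'   \code{\link{evolveSubgenomes}}), \code{reads} (per-gene read sets),
#'   \code{expression}, \code{tocols}, \code{config}, and \code{files}
#'   when written.
#' @export
simulateTruthSet <- function(config, dir = NULL, tocol_link = "HPPD_1",
                             tocol_noise = 0.1) {
  genes <- evolveSubgenomes(config)
  reads <- vector("list", length(genes))
  names(reads) <- names(genes)
  for (g in seq_along(genes)) {
    hom <- genes[[g]]$homeologs
    L <- nchar(hom[[1]])
    n_frag <- config$coverage * L / (2 * config$read_length)
    reads[[g]] <- simulateReads(hom, setNames(rep(n_frag, 3L), names(hom)),
                                config,
                                seed = deriveSeed(config$seed, 3000L + g))
  }
  expr <- simulateExpression(config)
  link_row <- if (tocol_link %in% rownames(expr$expected)) tocol_link
              else rownames(expr$expected)[1]
  stages <- stageLabels(config$n_stages)
  stage_means <- vapply(stages, function(st)
    mean(expr$expected[link_row, grep(paste0("^", st, "_"),
                                      colnames(expr$expected))]), 0)
  tocols <- simulateTocols(stage_means, config, sign = 1,
                           noise_frac = tocol_noise)
  out <- list(genes = genes, reads = reads, expression = expr,
              tocols = tocols, tocol_link = link_row, config = config)
  if (!is.null(dir)) out$files <- writeTruthSet(out, dir)
  out
}

writeTruthSet <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  hom_all <- unlist(lapply(truth$genes, function(g) g$homeologs))
  names(hom_all) <- unlist(lapply(truth$genes, function(g) names(g$homeologs)))
  tmpl <- vapply(truth$genes, function(g) g$template, "")
  names(tmpl) <- paste0(names(truth$genes), "_template")
  files$homeologs <- writeFasta(hom_all, file.path(dir, "true_homeologs.fasta"))
  files$templates <- writeFasta(tmpl, file.path(dir, "templates.fasta"))
  for (g in names(truth$reads)) {
    rs <- truth$reads[[g]]$pairs
    r1 <- rs[grepl("/1$", rs@id)]; r2 <- rs[grepl("/2$", rs@id)]
    files[[paste0(g, "_R1")]] <- writeFastq(r1,
      file.path(dir, paste0(g, "_R1.fastq")))
    files[[paste0(g, "_R2")]] <- writeFastq(r2,
      file.path(dir, paste0(g, "_R2.fastq")))
    if (!is.null(truth$reads[[g]]$long))
      files[[paste0(g, "_long")]] <- writeFastq(truth$reads[[g]]$long,
        file.path(dir, paste0(g, "_long.fastq")))
  }
  files$true_counts <- writeTable(truth$expression$counts,
                                  file.path(dir, "true_counts.tsv"))
  toc <- as.matrix(truth$tocols[, c("T", "T3", "total")])
  rownames(toc) <- truth$tocols$stage
  files$tocols <- writeTable(toc, file.path(dir, "tocol_profile.tsv"))
  ss <- truth$expression$sample_sheet
  write.table(ss, file.path(dir, "sample_sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files$sample_sheet <- file.path(dir, "sample_sheet.tsv")
  manifest <- list(
    config = unclass(truth$config),
    genes = lapply(truth$genes, function(g)
      list(snp_positions = g$snp_positions,
           realized_ks = as.list(as.data.frame(g$realized_ks)))),
    tocol_link = truth$tocol_link)
  jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  files$manifest <- file.path(dir, "truth_manifest.json")
  files
}
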