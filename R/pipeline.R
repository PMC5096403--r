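#' Percent identity between equal-length sequences
#'
#' @param a,b character scalars of equal length.
#' @return fraction of identical positions.
#' @export
percentIdentity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length", call. = FALSE)
  1 - pDistance(a, b)
}

#' Compare reconstructed homeologs with simulation truth
#'
#' Greedily matches each labelled member to the truth homeolog with the
#' highest identity (without replacement) and reports per-member identity
#' plus whether the \code{_1} label landed on the most divergent truth copy.
#'
#' @param hset a \linkS4class{HomeologSet}.
#' @param truth_homeologs named character vector (truth \code{<gene>_1/2/3}).
#' @return list: \code{table} (member, matched_truth, identity),
#'   \code{mean_identity}, \code{label_1_correct}.
#' @export
homeologRecovery <- function(hset, truth_homeologs) {
  members <- as.character(homeologMembers(hset))
  names(members) <- names(homeologMembers(hset))
  avail <- names(truth_homeologs)
  rows <- list()
  for (m in names(members)) {
    ids <- vapply(avail, function(t)
      percentIdentity(members[[m]], truth_homeologs[[t]]), 0)
    best <- avail[which.max(ids)]
    rows[[m]] <- data.frame(member = m, matched_truth = best,
                            identity = max(ids))
    avail <- setdiff(avail, best)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  lab1 <- tab$matched_truth[grepl("_1$", tab$member)]
  list(table = tab, mean_identity = mean(tab$identity),
       label_1_correct = length(lab1) == 1L && grepl("_1$", lab1))
}

#' Homeolog-bias ratios from a count matrix
#'
#' \code{vte2_homeolog_ratio}: mean of the VTE2_1 and VTE2_3 totals over
#' the VTE2_2 total (the within-gene homeolog bias).
#' \code{hggt_vte2_ratio}: mean HGGT homeolog total over the VTE2_2
#' (unbiased homeolog) total -- the between-gene basal ratio.
#'
#' @param counts matrix with rownames including VTE2_1..3 and HGGT_1..3.
#' @return named numeric vector of the two ratios.
#' @export
biasRatios <- function(counts) {
  need <- c(paste0("VTE2_", 1:3), paste0("HGGT_", 1:3))
  if (!all(need %in% rownames(counts)))
    stop("count matrix lacks VTE2/HGGT homeolog rows", call. = FALSE)
  tot <- rowSums(counts)
  c(vte2_homeolog_ratio =
      unname(mean(tot[c("VTE2_1", "VTE2_3")]) / tot[["VTE2_2"]]),
    hggt_vte2_ratio =
      unname(mean(tot[paste0("HGGT_", 1:3)]) / tot[["VTE2_2"]]))
}

#' Run the full pipeline on a synthetic dataset
#'
#' Orchestrates simulate -> qc -> assemble -> phase -> molev (Ks, dating,
#' tree) -> quant (strict counting, normalization, VST, ordination) ->
#' correlate, with per-stage toggles, dependency checks, derived seeds and
#' a JSON-serializable run manifest. Deterministic given (config, seed).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param out_dir optional directory for stage outputs (files written only
#'   when given).
#' @param stages named logical toggles (simulate, qc, assemble, phase,
#'   molev, quant, correlate); later stages require their inputs.
#' @param bootstrap_replicates bootstrap replicates for the subgenome tree
#'   (0 disables the bootstrap).
#' @param quant_scale factor applied to expected per-sample fragment counts
#'   before read-level quantification (keeps read simulation tractable).
#' @return list with per-stage results and \code{manifest}.
#' @export
runPipeline <- function(config = simulationConfig(), out_dir = NULL,
                        stages = c(simulate = TRUE, qc = TRUE,
                                   assemble = TRUE, phase = TRUE,
                                   molev = TRUE, quant = TRUE,
                                   correlate = TRUE),
                        bootstrap_replicates = 100L,
                        quant_scale = 0.25) {
  t0 <- Sys.time()
  res <- list(config = config)
  manifest <- list(seed = config$seed, stages = list(), warnings = list())
  need <- function(dep, stage) {
    if (is.null(res[[dep]]))
      stop("stage '", stage, "' requires missing input from stage '", dep,
           "'", call. = FALSE)
  }
  record <- function(name, params = NULL) {
    manifest$stages[[name]] <<- list(status = "complete", params = params,
                                     elapsed_s = round(as.numeric(
                                       Sys.time() - t0, units = "secs"), 2))
  }

  if (isTRUE(stages[["simulate"]])) {
    res$simulate <- simulateTruthSet(config,
                                     dir = if (!is.null(out_dir))
                                       file.path(out_dir, "simulate"))
    record("simulate", unclass(config))
  }

  if (isTRUE(stages[["qc"]])) {
    need("simulate", "qc")
    res$qc <- lapply(res$simulate$reads, function(rd)
      runReadQC(rd$pairs, rd$long))
    record("qc")
  }

  if (isTRUE(stages[["assemble"]])) {
    need("qc", "assemble")
    res$assemble <- list()
    for (g in names(res$simulate$genes)) {
      qcg <- res$qc[[g]]
      reads <- c(readSequences(qcg$paired),
                 if (!is.null(qcg$singletons)) readSequences(qcg$singletons),
                 if (!is.null(qcg$long)) readSequences(qcg$long))
      template <- setNames(res$simulate$genes[[g]]$template, g)
      hf <- homologyFilter(reads, template)
      reads <- reads[names(reads) %in% hf$by_template[[g]]]
      res$assemble[[g]] <- iterateToConvergence(
        reads, template, seed = deriveSeed(config$seed, 6000L +
                                             match(g, names(res$simulate$genes))))
      if (!res$assemble[[g]]$converged)
        manifest$warnings[[length(manifest$warnings) + 1L]] <-
          paste("assembly did not converge for", g)
    }
    record("assemble")
  }

  if (isTRUE(stages[["phase"]])) {
    need("assemble", "phase")
    res$phase <- list(); res$variants <- list(); res$homeologs <- list()
    for (g in names(res$assemble)) {
      pu <- res$assemble[[g]]$pileup
      v <- callVariantColumns(pu)
      res$variants[[g]] <- v
      if (nrow(v) == 0L) {
        manifest$warnings[[length(manifest$warnings) + 1L]] <-
          paste("no variant columns for", g)
        next
      }
      ph <- phaseReads(pu, v)
      res$phase[[g]] <- ph
      res$homeologs[[g]] <- reconstructHomeologs(ph, pu, gene = g)
    }
    res$snp_summary <- summarizeSnps(res$variants)
    record("phase")
  }

  if (isTRUE(stages[["molev"]])) {
    need("homeologs", "molev")
    per_gene <- list()
    aligns <- list()
    for (g in names(res$homeologs)) {
      hs <- res$homeologs[[g]]
      mem <- as.character(homeologMembers(hs))
      names(mem) <- sub(paste0("^", g, "_"), "As_", names(homeologMembers(hs)))
      if (length(mem) < 3L) next
      # artifactual in-frame stops at miscalled columns would break codon
      # rate estimation; exclude those codon columns like gapped positions
      masked <- maskStopCodonColumns(mem)
      if (masked$n_removed > 0L)
        manifest$warnings[[length(manifest$warnings) + 1L]] <-
          paste(g, ":", masked$n_removed,
                "stop-containing codon column(s) excluded from Ks")
      mem <- masked$seqs
      pairs <- list(c("As_3", "As_2"), c("As_1", "As_2"), c("As_1", "As_3"))
      for (p in pairs) {
        d <- ng86Distance(mem[[p[1]]], mem[[p[2]]])
        per_gene[[length(per_gene) + 1L]] <-
          cbind(data.frame(gene = g, pair = paste(p, collapse = "-")), d)
      }
      aligns[[g]] <- mem
    }
    ks_genes <- do.call(rbind, per_gene)
    if (is.null(ks_genes)) stop("molev: no complete homeolog triples",
                                call. = FALSE)
    ks_avg <- do.call(rbind, lapply(split(ks_genes, ks_genes$pair),
      function(df) data.frame(pair = df$pair[1], n_genes = nrow(df),
                              ks = averageKs(df$dS))))
    ks_avg$mya <- divergenceTime(ks_avg$ks)
    rownames(ks_avg) <- NULL
    res$ks <- list(per_gene = ks_genes, averaged = ks_avg)
    if (length(aligns) >= 1L) {
      dm <- Reduce(`+`, lapply(aligns, ksDistanceMatrix)) / length(aligns)
      res$tree <- upgmaTree(dm)
      if (bootstrap_replicates > 0L)
        res$bootstrap <- bootstrapSupport(aligns, bootstrap_replicates,
                                          seed = deriveSeed(config$seed, 7000L))
    }
    record("molev", list(lambda = 6.1e-9,
                         bootstrap_replicates = bootstrap_replicates))
  }

  if (isTRUE(stages[["quant"]])) {
    need("homeologs", "quant")
    refs <- unlist(lapply(res$homeologs, function(hs)
      as.character(homeologMembers(hs))))
    names(refs) <- unlist(lapply(res$homeologs, function(hs)
      names(homeologMembers(hs))))
    expr <- res$simulate$expression
    samples <- colnames(expr$expected)
    counts <- matrix(0L, length(refs), length(samples),
                     dimnames = list(names(refs), samples))
    truth_rows <- intersect(rownames(expr$expected), names(refs))
    qcfg <- config
    qcfg$ambiguous_base_rate <- 0
    qcfg$low_quality_tail <- 0
    for (j in seq_along(samples)) {
      mu <- expr$expected[truth_rows, j] * quant_scale
      src <- res$simulate$genes
      truth_seqs <- unlist(lapply(src, function(gg) gg$homeologs))
      names(truth_seqs) <- unlist(lapply(src, function(gg)
        names(gg$homeologs)))
      rd <- simulateReads(truth_seqs[truth_rows], mu, qcfg,
                          seed = deriveSeed(config$seed, 8000L + j),
                          long = FALSE)
      hits <- strictMap(pairs = rd$pairs, homeologs = refs)
      cf <- countFragments(hits, nchar(refs),
                           seed = deriveSeed(config$seed, 8500L + j))
      counts[names(cf$counts), j] <- cf$counts
    }
    hc <- homeologCounts(counts)
    hc <- normalizeCounts(hc)
    hc <- vstCounts(hc)
    res$counts <- hc
    res$ordination <- ordinateSamples(vstValues(hc))
    record("quant", list(quant_scale = quant_scale))
  }

  if (isTRUE(stages[["correlate"]])) {
    need("counts", "correlate")
    res$correlation <- correlateWithTocols(normalizedCounts(res$counts),
                                           sampleStages(res$counts),
                                           res$simulate$tocols)
    record("correlate")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- writePipelineOutputs(res, out_dir)
    manifest$outputs <- files
    manifest$checksums <- as.list(tools::md5sum(unlist(files)))
  }
  res$manifest <- manifest
  res
}

writePipelineOutputs <- function(res, out_dir) {
  files <- list()
  if (!is.null(res$homeologs)) {
    hom <- unlist(lapply(res$homeologs, function(hs)
      as.character(homeologMembers(hs))))
    names(hom) <- unlist(lapply(res$homeologs, function(hs)
      names(homeologMembers(hs))))
    files$homeologs <- writeFasta(hom, file.path(out_dir, "homeologs.fasta"))
  }
  if (!is.null(res$ks)) {
    km <- as.matrix(res$ks$averaged[, c("ks", "mya")])
    rownames(km) <- res$ks$averaged$pair
    files$ks <- writeTable(km, file.path(out_dir, "ks_dating.tsv"))
  }
  if (!is.null(res$tree))
    files$tree <- writeNewick(res$tree, file.path(out_dir, "subgenomes.nwk"))
  if (!is.null(res$counts)) {
    files$raw <- writeTable(rawCounts(res$counts),
                            file.path(out_dir, "counts_raw.tsv"))
    files$norm <- writeTable(normalizedCounts(res$counts),
                             file.path(out_dir, "counts_normalized.tsv"))
    files$vst <- writeTable(vstValues(res$counts),
                            file.path(out_dir, "counts_vst.tsv"))
  }
  if (!is.null(res$correlation))
    files$correlation <- writeTable(res$correlation$r,
                                    file.path(out_dir, "tocol_correlation.tsv"))
  files
}

#' Summary report for a pipeline run
#'
#' @param run result of \code{\link{runPipeline}}.
#' @return list of summary tables: \code{recovery} (vs simulation truth, or
#'   marked unavailable), \code{ks_dating}, \code{snp_summary},
#'   \code{bias_ratios}, \code{correlation}.
#' @export
pipelineReport <- function(run) {
  rep <- list()
  if (!is.null(run$simulate) && !is.null(run$homeologs)) {
    rec <- lapply(names(run$homeologs), function(g)
      cbind(gene = g, homeologRecovery(run$homeologs[[g]],
                                       run$simulate$genes[[g]]$homeologs)$table))
    rep$recovery <- do.call(rbind, rec)
  } else rep$recovery <- "unavailable (no simulation truth)"
  rep$ks_dating <- if (!is.null(run$ks)) run$ks$averaged else NULL
  rep$snp_summary <- run$snp_summary
  rep$bias_ratios <- if (!is.null(run$counts) &&
                         all(c("VTE2_1", "HGGT_1") %in%
                               rownames(rawCounts(run$counts))))
    biasRatios(rawCounts(run$counts)) else NULL
  rep$correlation <- if (!is.null(run$correlation)) run$correlation$r else NULL
  rep
}
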