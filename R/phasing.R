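#' Call homeolog-discriminating variant columns
#'
#' A column is variant when its depth reaches \code{min_depth} and at least
#' two alleles each reach both the frequency and absolute-count thresholds.
#' The frequency threshold (default 0.15, below 1/3) keeps a homeolog
#' present as one of three equal copies detectable while ~1\% sequencing
#' error stays below it; the count threshold guards low-depth columns.
#'
#' @param pileup a converged \linkS4class{Pileup}.
#' @param maf_threshold minimum allele frequency (default 0.15).
#' @param min_allele_count minimum allele read count (default 4).
#' @param min_depth minimum column depth (default 10).
#' @return data.frame: position (0-based), A, C, G, T, depth,
#'   n_alleles_passing, class (biallelic / triallelic / ambiguous); one row
#'   per variant column.
#' @export
callVariantColumns <- function(pileup, maf_threshold = 0.15,
                               min_allele_count = 4L, min_depth = 10L) {
  m <- pileup@counts
  depth <- colSums(m)
  freq <- sweep(m, 2L, pmax(depth, 1L), "/")
  passing <- m >= min_allele_count & freq >= maf_threshold
  n_pass <- colSums(passing)
  variant <- depth >= min_depth & n_pass >= 2L
  idx <- which(variant)
  if (!length(idx))
    return(data.frame(position = integer(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), depth = integer(0),
                      n_alleles_passing = integer(0), class = character(0)))
  cls <- c("biallelic", "triallelic", "ambiguous")[pmin(n_pass[idx] - 1L, 3L)]
  data.frame(position = idx - 1L,
             A = m[1L, idx], C = m[2L, idx], G = m[3L, idx], T = m[4L, idx],
             depth = depth[idx], n_alleles_passing = n_pass[idx],
             class = cls, row.names = NULL)
}

fragmentOf <- function(read_id) sub("/[12]$", "", read_id)

## allele signatures: per fragment, the observed base at each covered
## variant column (mate reads of one fragment contribute jointly; a
## within-fragment conflict blanks that column)
fragmentSignatures <- function(pileup, variants) {
  pl <- pileup@placements
  if (!nrow(pl) || !nrow(variants)) return(list())
  vpos <- variants$position + 1L  # 1-based
  sig <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(pl))) {
    s <- pl$start[r] + 1L; e <- pl$end[r]
    cover <- vpos[vpos >= s & vpos <= e]
    if (!length(cover)) next
    alleles <- substring(pl$bases[r], cover - s + 1L, cover - s + 1L)
    ok <- alleles %in% DNA_BASES_
    if (!any(ok)) next
    frag <- fragmentOf(pl$read_id[r])
    cur <- if (!is.null(sig[[frag]])) sig[[frag]] else character(0)
    for (k in which(ok)) {
      key <- as.character(cover[k])
      if (key %in% names(cur)) {
        if (!is.na(cur[[key]]) && cur[[key]] != alleles[k])
          cur[[key]] <- NA_character_  # mate conflict: drop the column
      } else cur[[key]] <- alleles[k]
    }
    sig[[frag]] <- cur
  }
  out <- as.list(sig)
  out <- lapply(out, function(v) v[!is.na(v)])
  out[lengths(out) > 0L]
}

clusterConsensusAllele <- function(counts_list) {
  lapply(counts_list, function(ct) DNA_BASES_[which.max(ct)])
}

compatibleWith <- function(sig, profile) {
  shared <- intersect(names(sig), names(profile))
  if (!length(shared)) return(NA)  # vacuously compatible (no joint columns)
  all(unlist(sig[shared]) == unlist(profile[shared]))
}

#' Phase variant-spanning reads into haplotype clusters
#'
#' Each fragment (read pair or singleton) spanning at least one variant
#' column receives an allele signature; signatures are clustered by greedy
#' agglomeration: a fragment joins the largest existing cluster whose
#' consensus signature agrees with it at every jointly covered variant,
#' else founds a new cluster; afterwards clusters that agree at all jointly
#' covered variants are merged, larger clusters first, until no compatible
#' merge remains. Fragments spanning no variant stay unassigned.
#'
#' @param pileup a converged \linkS4class{Pileup}.
#' @param variants variant table from \code{\link{callVariantColumns}}.
#' @return list: \code{clusters} (list with \code{fragments}, \code{size},
#'   \code{profile} = consensus allele per variant position),
#'   \code{assignment} (named cluster index per fragment),
#'   \code{unassigned} (fragment ids spanning no variant).
#' @export
phaseReads <- function(pileup, variants) {
  if (nrow(variants) == 0L)
    stop("phaseReads requires at least one variant column", call. = FALSE)
  sigs <- fragmentSignatures(pileup, variants)
  all_frags <- unique(fragmentOf(pileup@placements$read_id))
  unassigned <- setdiff(all_frags, names(sigs))
  ord <- order(-lengths(sigs), names(sigs))
  sigs <- sigs[ord]
  clusters <- list()  # each: counts (list pos -> int[4]), members, size
  assign_to <- integer(0)
  for (f in names(sigs)) {
    sig <- sigs[[f]]
    comp <- which(vapply(clusters, function(cl) {
      ok <- compatibleWith(sig, cl$profile)
      isTRUE(ok) || is.na(ok)
    }, TRUE))
    # prefer clusters sharing columns (informative agreement) over vacuous
    if (length(comp) > 1L) {
      informative <- comp[vapply(comp, function(ci)
        isTRUE(compatibleWith(sig, clusters[[ci]]$profile)), TRUE)]
      if (length(informative)) comp <- informative
    }
    if (length(comp)) {
      sizes <- vapply(clusters[comp], function(cl) cl$size, 0L)
      ci <- comp[order(-sizes, comp)][1L]
      clusters[[ci]] <- addToCluster(clusters[[ci]], f, sig)
    } else {
      ci <- length(clusters) + 1L
      clusters[[ci]] <- addToCluster(NULL, f, sig)
    }
    assign_to[f] <- ci
  }
  merged <- mergeCompatibleClusters(clusters, assign_to)
  list(clusters = lapply(merged$clusters, exportCluster),
       assignment = merged$assignment, unassigned = unassigned)
}

addToCluster <- function(cl, frag, sig) {
  if (is.null(cl)) cl <- list(counts = list(), members = character(0),
                              size = 0L)
  for (p in names(sig)) {
    if (is.null(cl$counts[[p]])) cl$counts[[p]] <- setNames(integer(4L),
                                                            DNA_BASES_)
    cl$counts[[p]][sig[[p]]] <- cl$counts[[p]][sig[[p]]] + 1L
  }
  cl$members <- c(cl$members, frag)
  cl$size <- cl$size + 1L
  cl$profile <- clusterConsensusAllele(cl$counts)
  cl
}

mergeCompatibleClusters <- function(clusters, assign_to) {
  repeat {
    n <- length(clusters)
    if (n < 2L) break
    sizes <- vapply(clusters, function(cl) cl$size, 0L)
    ord <- order(-sizes)
    pair <- NULL; vacuous_pair <- NULL
    for (a in seq_len(n - 1L)) {
      for (b in seq(a + 1L, n)) {
        ci <- ord[a]; cj <- ord[b]
        shared <- length(intersect(names(clusters[[ci]]$profile),
                                   names(clusters[[cj]]$profile))) > 0L
        if (!clustersCompatible(clusters[[ci]], clusters[[cj]])) next
        if (shared) { pair <- c(ci, cj); break }
        if (is.null(vacuous_pair)) vacuous_pair <- c(ci, cj)
      }
      if (!is.null(pair)) break
    }
    # informative merges (agreement at shared columns) take precedence over
    # vacuous ones (no jointly covered column)
    if (is.null(pair)) pair <- vacuous_pair
    if (is.null(pair)) break
    ci <- pair[1]; cj <- pair[2]
    tgt <- clusters[[ci]]
    src <- clusters[[cj]]
    for (p in names(src$counts)) {
      if (is.null(tgt$counts[[p]])) tgt$counts[[p]] <- src$counts[[p]]
      else tgt$counts[[p]] <- tgt$counts[[p]] + src$counts[[p]]
    }
    tgt$members <- c(tgt$members, src$members)
    tgt$size <- tgt$size + src$size
    tgt$profile <- clusterConsensusAllele(tgt$counts)
    clusters[[ci]] <- tgt
    clusters[[cj]] <- NULL
    assign_to[assign_to == cj] <- ci
    assign_to[assign_to > cj] <- assign_to[assign_to > cj] - 1L
  }
  list(clusters = clusters, assignment = assign_to)
}

clustersCompatible <- function(a, b) {
  shared <- intersect(names(a$profile), names(b$profile))
  if (!length(shared)) return(TRUE)
  all(unlist(a$profile[shared]) == unlist(b$profile[shared]))
}

exportCluster <- function(cl) {
  list(fragments = cl$members, size = cl$size,
       profile = unlist(cl$profile))
}

pDistance <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(va != vb)
}

#' Reconstruct homeolog consensus sequences from phased clusters
#'
#' Per cluster, a consensus over the columns its fragments cover, with
#' uncovered columns filled from the global (pooled) consensus. Clusters
#' covering less than \code{min_completeness} of the template, or beyond
#' the three largest, are demoted to \code{extra_members} (partial
#' assemblies / putative paralogs or pseudogenes). Of the labelled members,
#' \code{_1} goes to the copy with the greatest mean pairwise distance to
#' the others -- the most divergent subgenome.
#'
#' @param phase result of \code{\link{phaseReads}}.
#' @param pileup the converged \linkS4class{Pileup}.
#' @param gene gene name used for member labels.
#' @param min_completeness minimum covered fraction for a labelled member.
#' @return a \linkS4class{HomeologSet}.
#' @export
reconstructHomeologs <- function(phase, pileup, gene = pileup@refname,
                                 min_completeness = 0.5) {
  clusters <- phase$clusters
  if (!length(clusters)) stop("no clusters to reconstruct", call. = FALSE)
  global_cons <- strsplit(unname(callConsensus(pileup)), "")[[1]]
  L <- length(global_cons)
  pl <- pileup@placements
  pl$fragment <- fragmentOf(pl$read_id)
  seqs <- character(length(clusters))
  completeness <- numeric(length(clusters))
  for (k in seq_along(clusters)) {
    rows <- which(pl$fragment %in% clusters[[k]]$fragments)
    counts <- matrix(0L, 4L, L)
    for (r in rows) {
      b_int <- baseToInt(pl$bases[r])
      pos <- (pl$start[r] + 1L):pl$end[r]
      ok <- b_int != 0L
      if (!any(ok)) next
      flat <- (pos[ok] - 1L) * 4L + b_int[ok]
      counts <- counts + matrix(tabulate(flat, nbins = 4L * L), 4L, L)
    }
    depth <- colSums(counts)
    cons <- DNA_BASES_[max.col(t(counts), ties.method = "first")]
    cons[depth == 0L] <- global_cons[depth == 0L]
    seqs[k] <- paste(cons, collapse = "")
    completeness[k] <- mean(depth > 0L)
  }
  sizes <- vapply(clusters, function(cl) cl$size, 0L)
  eligible <- which(completeness >= min_completeness)
  labelled <- eligible[order(-sizes[eligible])]
  if (length(labelled) > 3L) {
    warning("more than 3 clusters pass completeness; labelling the 3 ",
            "largest, demoting the rest")
    labelled <- labelled[1:3]
  }
  demoted <- setdiff(seq_along(clusters), labelled)
  # divergence rule: _1 = greatest mean pairwise distance to the others
  lab_names <- character(length(labelled))
  if (length(labelled) >= 2L) {
    dm <- outer(labelled, labelled, Vectorize(function(i, j)
      if (i == j) 0 else pDistance(seqs[i], seqs[j])))
    mean_d <- rowSums(dm) / (length(labelled) - 1L)
    ord <- order(-mean_d, -sizes[labelled])
    most_div <- ord[1L]
    rest <- setdiff(seq_along(labelled), most_div)
    rest <- rest[order(-sizes[labelled][rest])]
    lab_names[most_div] <- paste0(gene, "_1")
    lab_names[rest] <- paste0(gene, "_", seq_along(rest) + 1L)
  } else lab_names <- paste0(gene, "_1")
  members <- Biostrings::DNAStringSet(setNames(seqs[labelled], lab_names))
  ord2 <- order(names(members))
  extras <- if (length(demoted))
    Biostrings::DNAStringSet(setNames(
      seqs[demoted], paste0(gene, "_extra", seq_along(demoted))))
  else Biostrings::DNAStringSet()
  new("HomeologSet", gene = gene, members = members[ord2],
      extra_members = extras,
      completeness = completeness[labelled][ord2],
      cluster_sizes = as.integer(sizes[labelled][ord2]))
}

#' Summarize variant classes across genes
#'
#' @param variant_lists named list (per gene) of variant tables from
#'   \code{\link{callVariantColumns}}.
#' @return data.frame with per-gene biallelic/triallelic/ambiguous/total
#'   counts and a TOTAL row.
#' @export
summarizeSnps <- function(variant_lists) {
  rows <- lapply(names(variant_lists), function(g) {
    v <- variant_lists[[g]]
    data.frame(gene = g,
               biallelic = sum(v$class == "biallelic"),
               triallelic = sum(v$class == "triallelic"),
               ambiguous = sum(v$class == "ambiguous"),
               total = nrow(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), biallelic = integer(0),
                      triallelic = integer(0), ambiguous = integer(0),
                      total = integer(0))
  rbind(out, data.frame(gene = "TOTAL", biallelic = sum(out$biallelic),
                        triallelic = sum(out$triallelic),
                        ambiguous = sum(out$ambiguous),
                        total = sum(out$total)))
}
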