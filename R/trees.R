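#' Pairwise synonymous-rate distance matrix
#'
#' NG86 dS between every pair of equal-length, gap-free coding sequences.
#' Saturated pairs (dS undefined) fall back to the uncorrected synonymous
#' proportion ps, so distance-based clustering still has a finite entry.
#'
#' @param sequences named character vector of aligned CDS.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
ksDistanceMatrix <- function(sequences) {
  n <- length(sequences)
  if (is.null(names(sequences)) || n < 2L)
    stop("need >= 2 named sequences", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    r <- ng86Distance(sequences[[i]], sequences[[j]])
    v <- if (is.na(r$dS)) r$ps else r$dS
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering under a constant-rate assumption;
#' the result is ultrametric. Rows are ordered lexically by label before
#' clustering so ties merge in lexical label order.
#'
#' @param d symmetric non-negative matrix with zero diagonal (labelled), or
#'   a \code{dist}.
#' @return an \code{ape} \code{phylo} tree with branch lengths (leaf depth =
#'   half the cophenetic distance).
#' @export
upgmaTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have zero diagonal", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  hc <- hclust(as.dist(d), method = "average")
  ape::as.phylo(hc)
}

cladePartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  parts <- lapply(pp, function(idx) sort(labs[idx]))
  # drop the trivial root partition (all leaves)
  keep <- lengths(parts) < length(labs) & lengths(parts) > 1L
  parts[keep]
}

#' Bootstrap support for a distance tree
#'
#' Resamples codon columns of the concatenated multi-gene alignment with
#' replacement, rebuilds the tree per replicate, and reports for each
#' internal clade of the original tree the percentage of replicates that
#' contain it.
#'
#' @param alignments list of named character vectors: per gene, gap-free
#'   aligned CDS over the same taxa.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param tree_builder function(distance matrix) -> phylo
#'   (default \code{\link{upgmaTree}}).
#' @param seed RNG seed for the resampling.
#' @return list: \code{tree} (original tree, \code{node.label} set to
#'   supports), \code{support} (named numeric, clade members pasted with
#'   \code{,}), \code{n_replicates}.
#' @export
bootstrapSupport <- function(alignments, n_replicates = 1000L,
                             tree_builder = upgmaTree, seed = 1L) {
  if (!length(alignments)) stop("empty alignment set", call. = FALSE)
  taxa <- sort(names(alignments[[1]]))
  for (al in alignments)
    if (!setequal(names(al), taxa))
      stop("all alignments must cover the same taxa", call. = FALSE)
  concat <- vapply(taxa, function(tx)
    paste(vapply(alignments, function(al) unname(al[[tx]]), ""), collapse = ""),
    "")
  n_codons <- nchar(concat[[1]]) %/% 3L
  codon_mat <- vapply(concat, function(s)
    substring(s, seq(1L, 3L * n_codons, 3L), seq(3L, 3L * n_codons, 3L)),
    character(n_codons))

  buildFromCodons <- function(idx) {
    seqs <- apply(codon_mat[idx, , drop = FALSE], 2L, paste, collapse = "")
    tree_builder(ksDistanceMatrix(seqs))
  }
  orig <- buildFromCodons(seq_len(n_codons))
  orig_parts <- cladePartitions(orig)
  keys <- vapply(orig_parts, paste, "", collapse = ",")
  hits <- setNames(numeric(length(keys)), keys)

  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(n_codons, n_codons, replace = TRUE)
    rep_parts <- cladePartitions(buildFromCodons(idx))
    rep_keys <- vapply(rep_parts, paste, "", collapse = ",")
    hits[keys %in% rep_keys] <- hits[keys %in% rep_keys] + 1
  }
  support <- 100 * hits / n_replicates
  # attach supports to the original tree's internal nodes
  node_lab <- rep(NA_character_, orig$Nnode)
  all_parts <- ape::prop.part(orig)
  labs <- attr(all_parts, "labels")
  for (i in seq_along(all_parts)) {
    key <- paste(sort(labs[all_parts[[i]]]), collapse = ",")
    if (key %in% keys) node_lab[i] <- as.character(support[[key]])
  }
  orig$node.label <- node_lab
  list(tree = orig, support = support, n_replicates = n_replicates)
}

#' Write a tree in Newick format
#'
#' @param tree an ape \code{phylo}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
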