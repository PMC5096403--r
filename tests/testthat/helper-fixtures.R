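# Shared fixture builders (all generated in code; nothing read from disk).

make_reads <- function(seqs, quals = 40L, ids = NULL, mate = NULL,
                       platform = "short_paired") {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  if (is.null(mate)) mate <- rep(NA_character_, length(seqs))
  ReadSet(id = ids, sequence = seqs, quality = quals, mate = mate,
          platform = platform)
}

# a mate-linked pair set from parallel R1/R2 sequence vectors
make_pairs <- function(r1, r2, q1 = 40L, q2 = 40L, prefix = "p") {
  n <- length(r1)
  id1 <- paste0(prefix, seq_len(n), "/1")
  id2 <- paste0(prefix, seq_len(n), "/2")
  ReadSet(id = c(id1, id2), sequence = c(r1, r2),
          quality = c(rep(list(NULL), 0),
                      lapply(nchar(c(r1, r2)), function(l)
                        rep(as.integer(q1), l))),
          mate = c(id2, id1), platform = "short_paired")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

revcomp <- function(s) chartr("ACGT", "TGCA",
                              vapply(s, function(x)
                                paste(rev(strsplit(x, "")[[1]]),
                                      collapse = ""), "",
                                USE.NAMES = FALSE))

# substitute n random bases without creating stop codons
mutateCodonsForTest <- function(seq, n) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  done <- 0
  while (done < n) {
    p <- sample(length(ch), 1)
    old <- ch[p]
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    cstart <- 3 * ((p - 1) %/% 3) + 1
    codon <- paste(ch[cstart:(cstart + 2)], collapse = "")
    if (oracle_is_stop(codon)) ch[p] <- old else done <- done + 1
  }
  paste(ch, collapse = "")
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 1L, cds_length_codons = 200L, coverage = 40,
                   error_rate = 0, ambiguous_base_rate = 0,
                   low_quality_tail = 0, long_coverage = 0, seed = 1L)
  do.call(simulationConfig, utils::modifyList(defaults, args))
}
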