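# Independent brute-force NG86 oracle.
#
# Deliberately shares no code with the package implementation: the genetic
# code comes from seqinr::translate, sites are enumerated mutation by
# mutation, and differences are averaged over explicitly generated
# pathway permutations by recursion.

oracle_bases <- c("A", "C", "G", "T")

oracle_aa <- function(codon) {
  seqinr::translate(strsplit(codon, "", fixed = TRUE)[[1]])
}

oracle_is_stop <- function(codon) oracle_aa(codon) == "*"

oracle_sites_codon <- function(codon) {
  aa0 <- oracle_aa(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in oracle_bases) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (oracle_is_stop(alt)) next
      valid <- valid + 1
      if (oracle_aa(alt) == aa0) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

oracle_sites <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  S <- sum(vapply(codons, oracle_sites_codon, 0))
  c(S = S, N = 3 * length(codons) - S)
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

oracle_diffs_codon <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  tot_s <- 0; tot_n <- 0; n_ok <- 0
  for (ord in oracle_permutations(pos)) {
    cur <- ca
    s <- 0; n <- 0; ok <- TRUE
    for (k in seq_along(ord)) {
      nxt <- cur
      substr(nxt, ord[k], ord[k]) <- substr(cb, ord[k], ord[k])
      if (k < length(ord) && oracle_is_stop(nxt)) { ok <- FALSE; break }
      if (oracle_aa(nxt) == oracle_aa(cur)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_ok <- n_ok + 1 }
  }
  if (n_ok == 0) c(0, 0) else c(tot_s / n_ok, tot_n / n_ok)
}

oracle_diffs <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  d <- mapply(function(x, y) oracle_diffs_codon(x, y), ca, cb)
  c(Sd = sum(d[1, ]), Nd = sum(d[2, ]))
}

oracle_distance <- function(a, b) {
  Sa <- oracle_sites(a); Sb <- oracle_sites(b)
  S <- (Sa["S"] + Sb["S"]) / 2
  N <- (Sa["N"] + Sb["N"]) / 2
  d <- oracle_diffs(a, b)
  ps <- d["Sd"] / S; pn <- d["Nd"] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  c(dS = unname(jc(ps)), dN = unname(jc(pn)))
}

# random stop-free CDS for property tests
random_cds <- function(n_codons) {
  repeat {
    s <- paste(sample(oracle_bases, 3 * n_codons, replace = TRUE),
               collapse = "")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (!any(vapply(codons, oracle_is_stop, TRUE))) return(s)
  }
}

sense_codons <- function() {
  all64 <- as.vector(outer(outer(oracle_bases, oracle_bases, paste0),
                           oracle_bases, paste0))
  all64[!vapply(all64, oracle_is_stop, TRUE)]
}
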