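# Shared test helpers: everything is generated in code, nothing on disk.

randomSeq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

randomRecords <- function(n, minLen = 20, maxLen = 200) {
  lens <- sample(minLen:maxLen, n, replace = TRUE)
  seqs <- vapply(lens, randomSeq, character(1))
  setNames(seqs, paste0("rec", seq_len(n)))
}

writeTempFasta <- function(records, env = parent.frame()) {
  tf <- withr::local_tempfile(fileext = ".fa", .local_envir = env)
  writeFasta(records, tf)
  tf
}

# Brute-force N50: try every observed length as the candidate L.
bruteN50 <- function(lengths) {
  cands <- sort(unique(lengths))
  ok <- vapply(cands, function(L)
    sum(lengths[lengths >= L]) >= sum(lengths) / 2, logical(1))
  max(cands[ok])
}

# Brute-force OVL/n-OVL by explicit base-set union over query positions
# (0-based half-open blocks).
bruteOvl <- function(qs, qe) {
  covered <- unique(unlist(mapply(function(s, e) seq(s, e - 1L), qs, qe,
                                  SIMPLIFY = FALSE)))
  ovl <- length(covered)
  extent <- max(qe) - min(qs)
  list(ovl = ovl, novl = extent - ovl)
}

pafLine <- function(q, qlen, qs, qe, strand, t, tlen, ts, te, nm, alen,
                    mapq = 60) {
  paste(q, qlen, qs, qe, strand, t, tlen, ts, te, nm, alen, mapq,
        sep = "\t")
}
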