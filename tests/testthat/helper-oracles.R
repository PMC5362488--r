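# Independent brute-force oracles shared by the unit and acceptance suites.

# cleavage-site scanner: cut after K/R unless followed by P
brute_digest <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  peps <- character(0)
  cur <- ""
  for (i in seq_along(res)) {
    cur <- paste0(cur, res[i])
    nxt <- if (i < length(res)) res[i + 1] else ""
    if (res[i] %in% c("K", "R") && nxt != "P" && nzchar(nxt)) {
      peps <- c(peps, cur)
      cur <- ""
    }
  }
  c(peps, cur)
}

rand_seq <- function(len)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
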