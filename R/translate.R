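# Standard-code translation tolerant of pad symbols: any codon containing a
# character outside {A,C,G,T} (e.g. the lowercase "n" used to pad restored
# deletions) translates to "X", never to a stop.
translate_dna <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  cods <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(GENETIC_CODE_TABLE[cods])
  aa[is.na(aa)] <- "X"
  collapse(aa)
}

GENETIC_CODE_TABLE <- local({
  b <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  cods <- sort(cods)
  setNames(vapply(cods, function(cd) {
    # defer to Biostrings' genetic code so the mapping is never hand-typed
    as.character(Biostrings::GENETIC_CODE[[cd]])
  }, character(1)), cods)
})
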