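# Package-level codon bookkeeping, built once at load time.
#
# .ng86$syn_sites[codon] is the NG86 synonymous-site fraction of a codon:
# the number of single-base changes that preserve the amino acid, divided
# by 3 (changes to stop codons count as nonsynonymous, as in the original
# Nei & Gojobori 1986 scheme). Stop codons get NA: they are rejected as
# input upstream.
.ng86 <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  bases <- c("A", "C", "G", "T")
  syn <- numeric(length(codons))
  for (i in seq_along(codons)) {
    if (code[[i]] == "*") {
      syn[i] <- NA_real_
      next
    }
    cod <- strsplit(codons[i], "", fixed = TRUE)[[1L]]
    s <- 0L
    for (p in 1:3) {
      for (b in bases[bases != cod[p]]) {
        alt <- cod
        alt[p] <- b
        if (code[[paste(alt, collapse = "")]] == code[[i]]) s <- s + 1L
      }
    }
    syn[i] <- s / 3
  }
  .ng86$code <- code
  .ng86$syn_sites <- stats::setNames(syn, codons)
  .ng86$pair_cache <- new.env(parent = emptyenv())
  invisible()
}
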