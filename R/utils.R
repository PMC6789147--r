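`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Split a coding sequence into codons
#'
#' @param x A single character string whose length is a multiple of 3.
#' @return Character vector of codons (upper case).
#' @export
split_codons <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  n <- nchar(x)
  if (n %% 3L != 0L) .stopf("sequence length %d is not a multiple of 3", n)
  if (n == 0L) return(character(0))
  substring(toupper(x), seq(1L, n, 3L), seq(3L, n, 3L))
}

# Accept either a codon vector or a single CDS string.
.as_codons <- function(x, what = "sequence") {
  if (is.character(x) && length(x) == 1L && nchar(x) != 3L) {
    return(split_codons(x))
  }
  x <- toupper(x)
  if (any(nchar(x) != 3L)) {
    .stopf("%s contains elements that are not codons (3 bases each)", what)
  }
  x
}

# simple permutations for n <= 3 (path enumeration in NG86 counting)
.perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
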