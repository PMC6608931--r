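#' @keywords internal
"_PACKAGE"

# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# round half up, so 0.645 -> 0.65 at digits = 2 (matches how the field
# prints percentages; R's round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# reverse complement of a nucleotide string, via Biostrings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# translate a vector of codon strings with the standard genetic code
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

site_id <- function(supercontig, position) paste0(supercontig, ":", position)

is_one_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
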