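DNA_BASES <- c("A", "C", "G", "T")

# round half away from zero (Table-1 style reporting), unlike base round()
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

collapse <- function(v) paste0(v, collapse = "")

is_dna <- function(s, allow_n = FALSE) {
  alphabet <- if (allow_n) c(DNA_BASES, "N") else DNA_BASES
  all(chars(toupper(s)) %in% alphabet)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# one deterministic sub-seed per named stream, so adding a generator never
# perturbs the draws of another (kept below 2^31 - 1)
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629)
}

random_dna <- function(n) collapse(sample(DNA_BASES, n, replace = TRUE))

AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

aa3 <- function(one_letter) unname(AA_THREE[one_letter])

# vertebrate mitochondrial genetic code (translation table 2)
mito_code <- function() Biostrings::getGeneticCode("SGC1")

translate_codon <- function(codon, code = mito_code()) {
  unname(code[[toupper(codon)]])
}
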