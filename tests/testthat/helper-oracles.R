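# Independent brute-force oracles used to cross-check the package's
# vectorized/regex implementations.

# character-by-character window oracle for the consensus scanners:
# checks each fixed-width window position-wise, no regex involved.
oracle_scan_sites <- function(sequence, rule = c("revised", "legacy")) {
  rule <- match.arg(rule)
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  w <- if (rule == "legacy") 12L else 10L
  if (n < w) return(integer())
  s <- seq_len(n - w + 1L)
  ok <- ch[s] == "C" & ch[s + 9L] == "C" &
    ch[s + 2L] %in% c("D", "N") & ch[s + 7L] %in% c("F", "Y")
  if (rule == "legacy") ok <- ok & ch[s + 11L] == "C"
  s[ok]
}

# linear scan oracle for cysteine indexing
oracle_cysteines <- function(sequence, start, end) {
  ch <- strsplit(sequence, "")[[1]]
  out <- integer()
  for (i in start:end) if (ch[i] == "C") out <- c(out, i)
  out
}

# explicit per-fragment summation oracle (no cumulative sums): b_i from
# residues 1..i, y_i from residues (n-i+1)..n, modification deltas added
# for spanned positions only.
oracle_by_mz <- function(sequence, mod_position = NULL, mod_delta = 0,
                         series, index, charge = 1L) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  span <- if (series == "b") seq_len(index) else (n - index + 1L):n
  m <- sum(asphkit::RESIDUE_MASSES[ch[span]])
  if (!is.null(mod_position) && mod_position %in% span) m <- m + mod_delta
  if (series == "y") m <- m + asphkit::WATER_MASS
  (m + charge * asphkit::PROTON_MASS) / charge
}

random_aa_sequence <- function(n) {
  paste(sample(asphkit::AMINO_ACIDS, n, replace = TRUE), collapse = "")
}
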