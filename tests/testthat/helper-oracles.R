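# Brute-force co-occurrence oracle: enumerate every unordered pair within
# every patient's endorsement set. Independent of the matrix-product path.
bruteForceCooccurrence <- function(strings) {
  codes <- canonicalCodes()
  m <- matrix(0L, 74, 74, dimnames = list(codes, codes))
  for (s in strings) {
    endorsed <- parseEndorsement(s)
    if (length(endorsed) < 2) next
    for (pair in utils::combn(endorsed, 2, simplify = FALSE)) {
      m[pair[1], pair[2]] <- m[pair[1], pair[2]] + 1L
      m[pair[2], pair[1]] <- m[pair[2], pair[1]] + 1L
    }
  }
  m
}

# Random cohort of delimited endorsement strings (possibly empty per patient)
randomStrings <- function(nPatients, maxAreas = 12) {
  vapply(seq_len(nPatients), function(i) {
    k <- sample(0:maxAreas, 1)
    paste(sample(canonicalCodes(), k), collapse = ", ")
  }, character(1))
}

sampleSkewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / (mean(z^2)^1.5)
}
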