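# In-code fixtures: build small genotype tables without touching disk, and a
# file-backed variant for the reader.

make_table <- function(ids, classes, tokens) {
  gen <- matrix(tokens, nrow = length(ids), byrow = TRUE)
  dimnames(gen) <- list(ids, sprintf("L%04d", seq_len(ncol(gen))))
  snparent:::new_raw_genotype_table(ids, classes, gen)
}

write_lines_table <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# random 0/1/2/NA state matrix for property tests
random_states <- function(n, L, miss = 0.1) {
  s <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  s[matrix(runif(n * L) < miss, n, L)] <- NA_real_
  s
}

# per-locus brute-force Gower oracle, straight from the definition
gower_oracle <- function(x, y) {
  stopifnot(length(x) == length(y))
  num <- 0; den <- 0
  for (l in seq_along(x)) {
    if (is.na(x[l]) || is.na(y[l])) next
    s <- if (x[l] == y[l]) 1 else if (abs(x[l] - y[l]) == 1) 0.5 else 0
    num <- num + s
    den <- den + 1
  }
  if (den == 0) return(list(gd = NA_real_, usable_loci = 0L))
  list(gd = 1 - num / den, usable_loci = den)
}

# expected-progeny oracle from the defining rules
ep_oracle <- function(sm, sf) {
  ep <- rep(NA_real_, length(sm))
  for (l in seq_along(sm)) {
    if (is.na(sm[l]) || is.na(sf[l])) next
    if (sm[l] == 1 || sf[l] == 1) next
    ep[l] <- (sm[l] + sf[l]) / 2
  }
  ep
}

# tokens for a state vector under alleles (A, B)
tok <- function(states, a = "A", b = "C") {
  vapply(states, function(s) {
    if (is.na(s)) "-/-"
    else if (s == 0) paste0(a, "/", a)
    else if (s == 1) paste0(a, "/", b)
    else paste0(b, "/", b)
  }, character(1))
}
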