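# Independent oracles used across the suite.

# Brute-force NLL: per-record loop, no aggregation, plain log of the
# clamped probability. Deliberately naive and independent of the package's
# vectorized likelihood path.
brute_force_nll <- function(responses, psi_fun, f_fun, sigma) {
  total <- 0
  for (i in seq_len(nrow(responses))) {
    s <- psi_fun(responses$standard[i])
    t1 <- psi_fun(responses$test1[i])
    t2 <- psi_fun(responses$test2[i])
    p <- pnorm((f_fun(abs(s - t1)) - f_fun(abs(t2 - s))) / sigma)
    p <- min(max(p, 1e-9), 1 - 1e-9)
    r <- responses$response[i]
    total <- total - (r * log(p) + (1 - r) * log(1 - p))
  }
  total
}

# Exhaustive factorial-design enumeration by triple loop.
brute_force_design_count <- function(standards, differences, deltas, gamut) {
  count <- 0
  seen <- character(0)
  for (s in standards) for (d1 in differences) for (d2 in differences) {
    if (any(abs((d1 - d2) - deltas) < 1e-9)) {
      t1 <- s - d1
      t2 <- s + d2
      if (t1 >= gamut[1] && t2 <= gamut[2]) {
        key <- paste(s, t1, t2)
        if (!key %in% seen) {
          seen <- c(seen, key)
          count <- count + 1
        }
      }
    }
  }
  count
}

# Small simulated dataset shared by several estimation tests.
small_design <- function() {
  triad_design(standards = c(40, 50, 60),
               differences = seq(0, 20, by = 5),
               deltas = c(-10, -5, 5, 10),
               gamut = c(0, 100))
}
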