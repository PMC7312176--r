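# Independent oracle: a literal nested-loop transcription of the positional
# distribution, mean, covariance and variance definitions. Deliberately slow
# and free of any shared code with the package implementation.

oracle_positions <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  out <- list(A = integer(0), C = integer(0), G = integer(0), T = integer(0))
  for (i in seq_along(chars)) {
    b <- chars[i]
    if (b %in% names(out)) out[[b]] <- c(out[[b]], i)
  }
  out
}

# U(i) per the step-function definition, scanning every position i and
# searching for its block; p0 = 0.
oracle_U <- function(positions, N) {
  u <- numeric(N)
  n <- length(positions)
  if (n == 0) return(u)
  p <- c(0, positions)              # p[j + 1] holds p_j
  for (i in 1:N) {
    found <- FALSE
    if (n >= 1) {
      for (j in 0:(n - 1)) {
        if (p[j + 1] <= i && i < p[j + 2]) {
          u[i] <- p[j + 1] / (p[j + 2] - p[j + 1])
          found <- TRUE
          break
        }
      }
    }
    if (!found) u[i] <- p[n + 1] / (N - (p[n + 1] - 1))
  }
  u
}

oracle_cov <- function(ua, ub, na, nb) {
  if (na == 0 || nb == 0) return(0)
  N <- length(ua)
  ubar_a <- 0; ubar_b <- 0
  for (i in 1:N) { ubar_a <- ubar_a + ua[i] / N; ubar_b <- ubar_b + ub[i] / N }
  s <- 0
  for (i in 1:N) s <- s + (ua[i] - ubar_a) * (ub[i] - ubar_b)
  s / (na * nb)
}

oracle_pcnv <- function(seq) {
  pos <- oracle_positions(seq)
  N <- nchar(seq)
  bases <- c("A", "C", "G", "T")
  ns <- sapply(pos, length)
  us <- lapply(bases, function(b) oracle_U(pos[[b]], N))
  names(us) <- bases
  kappa <- numeric(4)
  for (k in 1:4) {
    if (ns[k] > 0) {
      s <- 0
      for (i in 1:N) s <- s + us[[k]][i]
      kappa[k] <- s / ns[k]
    }
  }
  d2 <- numeric(4)
  for (k in 1:4) d2[k] <- oracle_cov(us[[k]], us[[k]], ns[k], ns[k])
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  cv <- numeric(6)
  for (k in 1:6) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    cv[k] <- oracle_cov(us[[a]], us[[b]], ns[a], ns[b])
  }
  unname(c(ns, kappa, d2, cv))
}

# Random test sequence over ACGT (occasionally with ambiguity codes).
random_test_seq <- function(len, ambiguous = FALSE) {
  alphabet <- c("A", "C", "G", "T")
  if (ambiguous) alphabet <- c(alphabet, "N", "R", "Y")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Robinson-Foulds distance between two trees, as a bare number.
rf_dist <- function(a, b) as.numeric(ape::dist.topo(a, b))

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
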