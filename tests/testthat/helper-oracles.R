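# Independent oracles used across the suite. These stay deliberately naive:
# plain enumeration and exact integer arithmetic, no shared code with the
# implementation under test.

# all integer partitions of n (each partition a descending integer vector)
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq(min(n, max_part), 1)) {
    for (tail in integer_partitions(n - k, k)) {
      out[[length(out) + 1L]] <- c(k, tail)
    }
  }
  out
}

# exact unsigned Stirling numbers of the first kind, s(n, a) for a = 1..n,
# by the integer recurrence (exact in doubles for the small n used here)
stirling1_exact <- function(n) {
  row <- 1
  if (n == 1) return(row)
  for (k in 1:(n - 1)) {
    nxt <- numeric(k + 1)
    for (a in 1:(k + 1)) {
      left <- if (a >= 2) row[a - 1] else 0
      same <- if (a <= k) k * row[a] else 0
      nxt[a] <- left + same
    }
    row <- nxt
  }
  row
}

# brute-force K(D, A) by summation over every ancestry allocation
# (a_1, ..., a_S) with 1 <= a_i <= n_i
K_bruteforce <- function(abund) {
  S <- length(abund)
  J <- sum(abund)
  grids <- lapply(abund, function(n) seq_len(n))
  alloc <- expand.grid(grids)
  K <- numeric(J - S + 1)
  srows <- lapply(abund, stirling1_exact)
  for (r in seq_len(nrow(alloc))) {
    a <- as.numeric(alloc[r, ])
    term <- 1
    for (i in seq_len(S)) {
      term <- term * srows[[i]][a[i]] * factorial(a[i] - 1) /
        factorial(abund[i] - 1)
    }
    A <- sum(a)
    K[A - S + 1] <- K[A - S + 1] + term
  }
  K
}

# a small panel of hand-shaped abundance configurations reused by several
# property tests
panel_configs <- function() {
  list(
    c(5, 3, 1),
    c(2, 2, 1),
    c(10, 1, 1, 1),
    c(7, 7, 7),
    c(20, 5, 3, 2, 1, 1, 1),
    c(50, 25, 10, 5, 5, 2, 1, 1, 1, 1),
    c(4, 4, 4, 4, 4),
    c(100, 1),
    c(12, 9, 6, 3, 1),
    c(30, 20, 10, 8, 6, 5, 4, 3, 2, 1)
  )
}
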