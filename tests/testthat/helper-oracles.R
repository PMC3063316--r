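# Independent oracles used across the suite. These deliberately re-derive
# each quantity from first principles (closed forms, exhaustive enumeration,
# direct evaluation of definitions) and never call the package's own code
# paths.

# Exhaustive hypergeometric enumeration for a 2x2 table with fixed margins,
# using log-binomial coefficients directly.
oracle_fisher_p <- function(a, b, c, d, alternative = "two.sided") {
  n <- a + b + c + d
  m1 <- a + c          # edited margin
  k <- a + b           # tissue margin
  xs <- max(0, k - (b + d)):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(n - m1, k - xs) - lchoose(n, k)
  probs <- exp(logp)
  pobs <- probs[xs == a]
  if (alternative == "greater") sum(probs[xs >= a])
  else sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Direct evaluation of the step-up definition: scan ranked p-values from the
# largest down, stop at the first that satisfies p(i) <= (i/m) q, reject it
# and everything smaller; adjusted value = min over j >= rank of m p(j)/j.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in rev(seq_len(m))) {
    if (ps[i] <= i / m * q) { k <- i; break }
  }
  rejected <- rep(FALSE, m)
  if (k > 0L) rejected[o[seq_len(k)]] <- TRUE
  adjusted <- numeric(m)
  for (i in seq_len(m))
    adjusted[o[i]] <- min(1, min(m * ps[i:m] / (i:m)))
  list(k = k, rejected = rejected, adjusted = adjusted)
}

# Brute-force ESS diff: rescan before/after in full, then restrict the set
# difference to windows covering the edited position.
oracle_diff_ess <- function(sequence, position, hexamers) {
  scan_all <- function(s) {
    n <- nchar(s)
    if (n < 6L) return(character(0))
    starts <- seq_len(n - 5L)
    w <- substring(s, starts, starts + 5L)
    paste(starts[w %in% hexamers], w[w %in% hexamers])
  }
  edited <- paste0(substring(sequence, 1, position - 1), "G",
                   substring(sequence, position + 1, nchar(sequence)))
  before <- scan_all(sequence)
  after <- scan_all(edited)
  covers <- function(keys) {
    st <- as.integer(sub(" .*", "", keys))
    keys[st <= position & position <= st + 5L]
  }
  list(lost = sort(covers(setdiff(before, after))),
       gained = sort(covers(setdiff(after, before))))
}

random_dna <- function(n, p = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}
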