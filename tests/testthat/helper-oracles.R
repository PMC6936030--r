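# Independent oracles, written directly from the published definitions
# with plain loops, used to cross-check the vectorized encoders.

oracle_cksnap <- function(s, k_max) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  nts <- c("A", "C", "G", "U")
  out <- numeric(0)
  for (g in 0:k_max) {
    for (x in nts) for (y in nts) {
      cnt <- 0
      for (i in seq_len(n - g - 1)) {
        if (chars[i] == x && chars[i + g + 1] == y) cnt <- cnt + 1
      }
      out <- c(out, cnt / (n - g - 1))
    }
  }
  out
}

# Direct evaluation of the Type-I pseudo composition: k-tuple
# frequencies damped by w-weighted tier correlation factors computed
# from the standardized dinucleotide property table.
oracle_pseknc <- function(s, k, lambda, w, tab) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  nts <- c("A", "C", "G", "U")
  tuples <- nts
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      tuples <- as.vector(vapply(tuples, function(t) paste0(t, nts), character(4)))
    }
  }
  tuples <- sort(tuples)
  f <- numeric(length(tuples)); names(f) <- tuples
  for (i in seq_len(n - k + 1)) {
    t <- paste(chars[i:(i + k - 1)], collapse = "")
    f[t] <- f[t] + 1
  }
  f <- f / sum(f)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0; m <- 0
    for (i in seq_len(n - 1 - j)) {
      d1 <- paste0(chars[i], chars[i + 1])
      d2 <- paste0(chars[i + j], chars[i + j + 1])
      acc <- acc + mean((tab[d1, ] - tab[d2, ])^2)
      m <- m + 1
    }
    theta[j] <- acc / m
  }
  denom <- 1 + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}
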