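# Independent oracles: deliberately naive re-implementations used only to
# check the package's optimized code paths.

# All length-k windows of a set of sequences, one protein at a time,
# keeping only windows made of standard letters.
oracle_windows <- function(seqs, k) {
  std <- stallscan::AA_STANDARD
  out <- character(0)
  for (s in seqs) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- chars[i:(i + k - 1L)]
      if (all(w %in% std)) out <- c(out, paste0(w, collapse = ""))
    }
  }
  out
}

# Naive frequency bias: enumerate windows, tally composition by hand.
oracle_bias <- function(seqs, pattern) {
  std <- stallscan::AA_STANDARD
  k <- nchar(pattern)
  wins <- oracle_windows(seqs, k)
  chars <- unlist(strsplit(seqs, "", fixed = TRUE))
  chars <- chars[chars %in% std]
  comp <- table(factor(chars, levels = std)) / length(chars)
  ef <- prod(comp[strsplit(pattern, "", fixed = TRUE)[[1L]]])
  tw <- length(wins)
  obs <- sum(wins == pattern)
  if (tw == 0L || ef == 0) return(list(bias = NA_real_, obs = obs, tw = tw,
                                       ef = ef))
  list(bias = (obs / tw) / ef, obs = obs, tw = tw, ef = ef)
}

# Fisher two-sided p by full enumeration with choose(), no dhyper.
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), 0)
  pobs <- probs[match(a, lo:hi)]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Direct step-up BH formula.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Naive localization heuristic: literal loops over the stated rules.
oracle_localize <- function(seq, window = 19L, threshold = 1.6,
                            n_region = 35L) {
  kd <- stallscan::KYTE_DOOLITTLE
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < window) return("CP")
  half <- window %/% 2L
  h <- kd[chars]; h[is.na(h)] <- 0
  centers <- (half + 1L):(n - half)
  hot <- logical(length(centers))
  for (j in seq_along(centers)) {
    i <- centers[j]
    hot[j] <- mean(h[(i - half):(i + half)]) >= threshold
  }
  segs <- list()
  j <- 1L
  while (j <= length(hot)) {
    if (hot[j]) {
      j2 <- j
      while (j2 < length(hot) && hot[j2 + 1L]) j2 <- j2 + 1L
      segs[[length(segs) + 1L]] <- c(centers[j], centers[j2])
      j <- j2 + 1L
    } else j <- j + 1L
  }
  kinds <- vapply(segs, function(se) {
    if (se[2L] <= n_region && se[1L] > 1L &&
        any(chars[1:(se[1L] - 1L)] %in% c("K", "R"))) "signal" else "tm"
  }, "")
  tm_after <- any(kinds == "tm" &
                  vapply(segs, `[[`, 0, 2L) > n_region)
  if (any(kinds == "signal") && !tm_after) "SP"
  else if (tm_after) "TM"
  else "CP"
}

# Random test proteome built independently of the package's generator.
random_seqs <- function(n_proteins, len_range = c(4L, 60L),
                        alphabet = stallscan::AA_STANDARD) {
  vapply(seq_len(n_proteins), function(i) {
    n <- sample(len_range[1L]:len_range[2L], 1L)
    paste0(sample(alphabet, n, replace = TRUE), collapse = "")
  }, "")
}
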