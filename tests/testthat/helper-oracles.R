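# Independent brute-force oracles, deliberately implemented with
# different code paths (explicit loops, probability sums, pair
# counting) than the package functions they check.

plugin_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# MI from explicit joint/marginal probability tables, pairwise
# complete over the amino-acid alphabet.
oracle_mi <- function(m) {
  L <- m$length
  out <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      a <- m$seqs[, i]; b <- m$seqs[, j]
      ok <- a %in% AA_ALPHABET & b %in% AA_ALPHABET
      a <- a[ok]; b <- b[ok]
      n <- length(a)
      pj <- as.numeric(table(paste(a, b))) / n
      pa <- as.numeric(table(a)) / n
      pb <- as.numeric(table(b)) / n
      out[i, j] <- max(plugin_entropy(pa) + plugin_entropy(pb) -
                         plugin_entropy(pj), 0)
    }
  }
  out
}

oracle_mip <- function(mi) {
  L <- nrow(mi)
  m <- mi; diag(m) <- NA
  mbar <- vapply(seq_len(L), function(k) mean(m[k, -k]), numeric(1))
  grand <- mean(m[upper.tri(m)])
  out <- matrix(NA_real_, L, L)
  if (!is.finite(grand) || grand <= 0) return(m)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i != j) out[i, j] <- m[i, j] - mbar[i] * mbar[j] / grand
    }
  }
  out
}

# Two-pass standardization: column stats first, then per-entry
# z-product and signed square root.
oracle_zpx <- function(mip) {
  L <- nrow(mip)
  mu <- numeric(L); s <- numeric(L)
  for (k in seq_len(L)) {
    v <- mip[k, -k]
    mu[k] <- mean(v); s[k] <- sd(v)
  }
  out <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      z <- (mip[i, j] - mu[i]) / s[i] * (mip[i, j] - mu[j]) / s[j]
      out[i, j] <- sign(z) * sqrt(abs(z))
    }
  }
  out
}

# Exhaustive positive-negative pair counting AUC (ties count 1/2).
oracle_auc <- function(labels, scores) {
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Independent three-way classifier used to cross-check
# classify_stability / fraction_correct.
oracle_class <- function(v, hw = 1) {
  if (abs(v) <= hw) "neutral" else if (v > hw) "destabilizing" else "stabilizing"
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid transform to a structure_coords object.
transform_structure <- function(s, R, t) {
  df <- as.data.frame(s)
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% R
  df$x <- xyz[, 1] + t[1]; df$y <- xyz[, 2] + t[2]; df$z <- xyz[, 3] + t[3]
  structure_coords(df)
}
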