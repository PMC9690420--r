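# Independent brute-force reference implementations used to cross-check
# the package's closed-form scoring functions. These deliberately follow
# the definitions term by term rather than reusing package code.

# Mutual information of a T x C dropout stack, written directly as
# -sum_c pbar log pbar + (1/T) sum_{c,t} p log p.
bruteBald <- function(stack) {
  Tn <- nrow(stack)
  pbar <- apply(stack, 2, sum) / Tn
  term1 <- -sum(ifelse(pbar > 0, pbar * log(pbar), 0))
  term2 <- sum(ifelse(stack > 0, stack * log(stack), 0)) / Tn
  term1 + term2
}

# Diversity score computed step by step: sort, truncate, z-score with the
# population sd, softmax, Shannon entropy.
bruteDiversity <- function(distances, k) {
  d <- sort(distances)[1:k]
  if (k == 1) return(0)
  mu <- sum(d) / k
  sdPop <- sqrt(sum((d - mu)^2) / k)
  z <- if (sdPop == 0) rep(0, k) else (d - mu) / sdPop
  e <- exp(z - max(z))
  p <- e / sum(e)
  -sum(p * log(p))
}

# O(n^2) pairwise AUC with the half-tie convention.
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  tot / (length(pos) * length(neg))
}

bruteMinmax <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) rep(0, length(v)) else (v - lo) / (hi - lo)
}

# Top-n selection by full sort, ties by id.
bruteTopN <- function(ids, scores, n) {
  df <- data.frame(ids, scores, stringsAsFactors = FALSE)
  df <- df[order(-df$scores, df$ids), ]
  df$ids[1:n]
}

# Monte Carlo estimate of KL(q || N(0, I)) for a diagonal Gaussian q:
# mean over draws z ~ q of log q(z) - log p(z).
mcKL <- function(mu, logVar, nDraws = 50000, seed = 1) {
  set.seed(seed)
  d <- length(mu)
  sd <- exp(0.5 * logVar)
  z <- matrix(rnorm(nDraws * d), nDraws, d)
  z <- sweep(sweep(z, 2, sd, "*"), 2, mu, "+")
  logq <- -0.5 * rowSums(sweep(sweep(z, 2, mu)^2, 2, exp(logVar), "/") +
                           matrix(logVar, nDraws, d, byrow = TRUE) + log(2 * pi))
  logp <- -0.5 * rowSums(z^2 + log(2 * pi))
  mean(logq - logp)
}

randomStack <- function(Tn, C) {
  m <- matrix(rexp(Tn * C), Tn, C)
  m / rowSums(m)
}
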