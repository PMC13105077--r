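# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain normal equations, brute-force BH, direct
# gamma-function evaluation of the DM pmf.

# OLS by explicit normal equations.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  fitted <- X %*% beta
  rss <- sum((y - fitted)^2)
  list(beta = as.numeric(beta), rss = rss)
}

# Partial F statistic from two explicit RSS computations.
partial_f_oracle <- function(Xfull, Xred, y) {
  rf <- ols_oracle(Xfull, y)$rss
  rr <- ols_oracle(Xred, y)$rss
  df1 <- ncol(Xfull) - ncol(Xred)
  df2 <- length(y) - ncol(Xfull)
  Fstat <- ((rr - rf) / df1) / (rf / df2)
  list(F = Fstat, p = pf(Fstat, df1, df2, lower.tail = FALSE))
}

# Simple-regression slope/p/adjusted-R2 oracle via explicit sums.
trend_oracle <- function(y, x) {
  n <- length(y)
  xc <- x - mean(x); yc <- y - mean(y)
  beta <- sum(xc * yc) / sum(xc^2)
  rss <- sum((yc - beta * xc)^2)
  tss <- sum(yc^2)
  se <- sqrt(rss / (n - 2) / sum(xc^2))
  t <- beta / se
  list(beta = beta,
       p = 2 * pt(abs(t), n - 2, lower.tail = FALSE),
       r2_adj = 1 - (rss / (n - 2)) / (tss / (n - 1)))
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Direct Dirichlet-multinomial pmf from the gamma-function formula.
dm_pmf_oracle <- function(x, p, gamma) {
  n <- sum(x)
  coef <- factorial(n) / prod(factorial(x))
  coef * gamma(gamma) / gamma(n + gamma) *
    prod(gamma(x + gamma * p) / gamma(gamma * p))
}

# Enumerate all count vectors of length K summing to n.
enumerate_counts <- function(n, K) {
  if (K == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (i in 0:n) {
    rest <- enumerate_counts(n - i, K - 1)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

# Small fixed cohort used by many tests: one age, 2 batches, n_per_cell
# samples per (genotype, sex) cell.
tiny_cohort <- function(n_per_cell = 5, ages = "12mo", n_batches = 2) {
  simulate_cohort(cohort_design(n_per_cell = n_per_cell, ages = ages,
                                n_batches = n_batches, seed = 1))
}

# Collections whose pathway-by-domain intersections are exactly n_blocks
# disjoint gene blocks: each pathway is one block, each domain the union of
# its blocks. Gives controlled, non-overlapping intersection truth.
block_collections <- function(universe, n_blocks = 60, block_size = 15,
                              n_domains = 6) {
  stopifnot(n_blocks * block_size <= length(universe))
  blocks <- split(universe[seq_len(n_blocks * block_size)],
                  rep(seq_len(n_blocks), each = block_size))
  dom_of <- rep_len(seq_len(n_domains), n_blocks)
  domains <- lapply(seq_len(n_domains), function(d)
    sort(unname(unlist(blocks[dom_of == d]))))
  names(domains) <- sprintf("Domain%02d", seq_len(n_domains))
  paths <- lapply(blocks, sort)
  names(paths) <- sprintf("map%05d", seq_len(n_blocks))
  list(kegg = gene_set_collection(paths, source = "synthetic-blocks"),
       biodomains = gene_set_collection(domains, source = "synthetic-blocks"))
}
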