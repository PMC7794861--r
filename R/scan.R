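# Vectorized per-SNP marginal association scans.
#
# Each SNP is fit as its own two-parameter model (intercept + additive allele
# count). The linear scan is the closed-form simple-regression solution; the
# logistic scan runs a per-SNP Newton-Raphson in compiled code, which is what
# makes the replicate simulation studies tractable. Both are validated
# against lm()/glm() in the test suite.

# columns of G with zero variance are returned as NA (monomorphic)
linear_scan <- function(G, y) {
  n <- nrow(G)
  stopifnot(length(y) == n, n >= 3)
  if (!is.double(G)) storage.mode(G) <- "double"
  gbar <- colMeans(G)
  Sxx <- colSums(G^2) - n * gbar^2
  Sxy <- colSums(G * y) - n * gbar * mean(y)
  mono <- Sxx <= .Machine$double.eps * n
  Sxx[mono] <- NA_real_
  beta <- Sxy / Sxx
  Syy <- sum((y - mean(y))^2)
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- sqrt(rss / (n - 2) / Sxx)
  beta <- unname(beta)
  se <- unname(se)
  mono <- unname(mono)
  tibble::tibble(
    beta = beta, se = se,
    pvalue = 2 * stats::pt(-abs(beta / se), df = n - 2),
    monomorphic = mono
  )
}

# per-SNP univariable logistic regression, log-odds per allele
logistic_scan <- function(G, y, tol = 1e-8, max_iter = 30L) {
  n <- nrow(G)
  stopifnot(length(y) == n, all(y %in% c(0, 1)), n >= 3)
  if (!is.double(G)) storage.mode(G) <- "double"
  res <- .logistic_scan_cpp(G, as.double(y), tol, as.integer(max_iter))
  beta <- res[, 1]
  se <- res[, 2]
  mono <- is.na(beta) & res[, 3] == 0
  tibble::tibble(
    beta = beta, se = se,
    pvalue = two_sided_p(beta, se),
    monomorphic = mono
  )
}
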