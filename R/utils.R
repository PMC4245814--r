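# internal numerical helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log N(x; mu_i, Sigma) for each row mu_i of `means`, common covariance
dmvnorm_log_rows <- function(x, means, sigma) {
  d <- length(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    sigma <- sigma + diag(1e-6 * mean(diag(sigma)) + 1e-12, d)
    ch <- chol(sigma)
  }
  dev <- sweep(means, 2, x) # means - x, rowwise
  z <- backsolve(ch, t(dev), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# robust per-column scale: MAD, falling back to SD then 1 for constants
robust_scale <- function(x) {
  s <- apply(x, 2, mad)
  zero <- !is.finite(s) | s <= 0
  if (any(zero)) s[zero] <- apply(x[, zero, drop = FALSE], 2, sd)
  s[!is.finite(s) | s <= 0] <- 1
  s
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)

# add-one permutation p-value
perm_pvalue <- function(null_stats, observed) {
  (sum(null_stats >= observed) + 1) / (length(null_stats) + 1)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE), f)
  unname(tools::md5sum(f))
}
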