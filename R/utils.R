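# Internal helpers shared across modules.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Percentages to `digits` decimals whose rounded values sum exactly to 100
# (largest-remainder method; Table-style accounting).
largest_remainder_percent <- function(counts, total, digits = 1) {
  stopifnot(total > 0, all(counts >= 0))
  scale <- 10^digits
  p <- 100 * counts / total
  base <- floor(p * scale)
  deficit <- round(100 * scale - sum(base))
  if (deficit > 0) {
    order_rem <- order(p * scale - base, decreasing = TRUE)
    base[order_rem[seq_len(deficit)]] <- base[order_rem[seq_len(deficit)]] + 1
  }
  base / scale
}

round1 <- function(x) round(x, 1)

abort_domain <- function(msg) abort(msg, class = "quadtrace_domain_error")
abort_config <- function(msg) abort(msg, class = "quadtrace_config_error")
abort_data <- function(msg) abort(msg, class = "quadtrace_data_error")

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_domain(sprintf("`%s` must be numeric and non-missing.", name))
  }
  if (positive && any(x <= 0)) {
    abort_domain(sprintf("`%s` must be strictly positive.", name))
  }
  if (non_negative && any(x < 0)) {
    abort_domain(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

# Draw from Normal(mean, sd) truncated to (0, Inf) by rejection.
rnorm_pos <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean[pmin(bad, length(mean))], sd[pmin(bad, length(sd))])
    bad <- bad[out[bad] <= 0]
  }
  out
}

# Categorical draw per row of a probability matrix (rows sum to 1).
sample_categorical <- function(prob) {
  cp <- t(apply(prob, 1, cumsum))
  u <- runif(nrow(prob))
  1L + rowSums(u > cp[, -ncol(cp), drop = FALSE])
}
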