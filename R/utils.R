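# Largest-remainder (Hamilton) apportionment of `total` integer units to
# shares `ideal` (non-negative reals), each result capped at `cap`.
# Ties in remainder break toward the lower index. Errors if the caps make
# the total infeasible.
largest_remainder <- function(ideal, total, cap = rep(Inf, length(ideal))) {
  stopifnot(all(ideal >= 0), total >= 0, length(cap) == length(ideal))
  if (sum(cap) < total) stop("caps sum below the requested total")
  base <- pmin(floor(ideal), cap)
  rem <- ideal - floor(ideal)
  left <- total - sum(base)
  while (left > 0) {
    elig <- which(base < cap)
    ord <- elig[order(-rem[elig], elig)]
    take <- ord[seq_len(min(left, length(ord)))]
    base[take] <- base[take] + 1
    left <- total - sum(base)
  }
  while (left < 0) {  # only reachable when total < sum(floor(ideal)) after caps
    elig <- which(base > 0)
    ord <- elig[order(rem[elig], elig)]
    take <- ord[seq_len(min(-left, length(ord)))]
    base[take] <- base[take] - 1
    left <- total - sum(base)
  }
  as.integer(base)
}

# log-density of rows of x under N(mu, sigma), via one Cholesky factor
.dmvnorm_log <- function(x, mu, chol_sigma) {
  d <- ncol(x)
  z <- backsolve(chol_sigma, t(x) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_sigma))) - 0.5 * d * log(2 * pi)
}

# column z-score that tolerates zero-variance columns (left centered only)
.safe_scale <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd[is.na(sd) | sd == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sd, "/")
}
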