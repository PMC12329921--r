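# Independent oracles: deliberately naive implementations used to check the
# package's statistics. They must stay independent of the code paths they
# verify (no calls into drivertx internals).

# F1 from raw confusion counts
oracle_f1 <- function(tp, fp, fn) {
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  2 * precision * recall / (precision + recall)
}

# standard normal quantile via root-finding on pnorm (independent of qnorm)
oracle_z_quantile <- function(p) {
  stats::uniroot(function(z) stats::pnorm(z) - p, c(-10, 10),
                 tol = 1e-12)$root
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free data, n1 + n2 small)
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
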