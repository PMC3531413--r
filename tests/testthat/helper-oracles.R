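# Independent oracles used across the suite.  These deliberately take the
# dumbest correct route (closed forms, exhaustive enumeration, plain loops)
# so they share no code with the implementation paths they check.

# Closed-form mean and sd of a Normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  m <- mu + sigma * (dnorm(al) - dnorm(be)) / Z
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z -
                    ((dnorm(al) - dnorm(be)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# Two-sided Fisher p by exhaustive enumeration of every table with the
# observed margins, using binomial coefficients directly.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- r1 + r2
  a_all <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, a_all) * choose(r2, c1 - a_all) / choose(N, c1)
  p_obs <- pr[a_all == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo p-value of the Pearson statistic under the fixed-margins
# (permutation) null, sampled with r2dtable.
perm_chisq_p <- function(tab, B = 1e5) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  obs <- sum((tab - E)^2 / E)
  sims <- r2dtable(B, rowSums(tab), colSums(tab))
  stats <- vapply(sims, function(m) sum((m - E)^2 / E), numeric(1))
  mean(stats >= obs - 1e-9)
}

# Monte-Carlo goodness-of-fit p for counts against a uniform multinomial.
uniform_gof_p <- function(counts, B = 2000) {
  n <- sum(counts)
  k <- length(counts)
  E <- n / k
  obs <- sum((counts - E)^2 / E)
  sims <- rmultinom(B, n, rep(1 / k, k))
  stats <- colSums((sims - E)^2 / E)
  (1 + sum(stats >= obs - 1e-9)) / (B + 1)
}

# Acute angular distance (degrees) of orientations to a reference axis.
fold_deg <- function(theta, ref = 0) {
  d <- abs((theta - ref) %% pi)
  pmin(d, pi - d) * 180 / pi
}

# A small cell with hand-chosen orientations and uniform pre-stretch,
# for arithmetic checks of the stretch rule.
manual_cell <- function(theta, params) {
  params$n_sectors <- length(theta)
  params$sigma_pre <- 0
  cell <- init_cell("circular", params)
  cell$theta <- theta
  cell
}

# Fibrosity linearity fixture: congruent horizontal fibers at mirrored rows
# near the image centre, so every added pair carries near-equal Hann-window
# weight.  Returns y-coordinates (um) for k fibers.
linearity_rows <- function(k) {
  cs <- c(2, 4, 6, 8, 10)[seq_len(k / 2)]
  c(32 - cs, 32 + cs)
}
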