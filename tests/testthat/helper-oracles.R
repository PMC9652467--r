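# Independent brute-force oracles.  Everything here is deliberately written
# from first principles (sums of squares, rank formulas, exhaustive
# enumeration) and never calls the package's own code paths, so agreement
# is evidence, not tautology.

oracle_oneway_F <- function(values, groups) {
  g <- split(values, groups)
  grand <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  df1 <- length(g) - 1
  df2 <- length(values) - length(g)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

oracle_lsd_p <- function(values, groups, a, b) {
  g <- split(values, groups)
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  df <- length(values) - length(g)
  mse <- ssw / df
  t <- (mean(g[[a]]) - mean(g[[b]])) /
    sqrt(mse * (1 / length(g[[a]]) + 1 / length(g[[b]])))
  2 * pt(-abs(t), df)
}

oracle_kruskal_H <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  rs <- tapply(r, groups, function(x) length(x) * (mean(x) - (n + 1) / 2)^2)
  h <- 12 / (n * (n + 1)) * sum(rs)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

oracle_dunn_z <- function(values, groups, a, b) {
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  s2 <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  ra <- mean(r[groups == a]); rb <- mean(r[groups == b])
  na <- sum(groups == a); nb <- sum(groups == b)
  (ra - rb) / sqrt(s2 * (1 / na + 1 / nb))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mwu_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, `>`)) + 0.5 * sum(outer(xs, ys, `==`))
  }
  u_obs <- u_of(seq_len(n1))
  us <- combn(n, n1, u_of)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# all r x c tables with the observed margins, by recursive fill
enumerate_tables <- function(rs, cs) {
  nr <- length(rs); nc <- length(cs)
  out <- list()
  fill <- function(tab, i, rem_cols) {
    if (i == nr) {
      tab[nr, ] <- rem_cols
      if (all(rem_cols >= 0)) out[[length(out) + 1L]] <<- tab
      return(invisible())
    }
    cells <- function(row, j, rem_row) {
      if (j == nc) {
        row[nc] <- rem_row
        if (rem_row >= 0 && rem_row <= rem_cols[nc]) {
          tab[i, ] <- row
          fill(tab, i + 1L, rem_cols - row)
        }
        return(invisible())
      }
      for (v in 0:min(rem_row, rem_cols[j])) {
        row[j] <- v
        cells(row, j + 1L, rem_row - v)
      }
    }
    cells(integer(nc), 1L, rs[i])
    invisible()
  }
  fill(matrix(0L, nr, nc), 1L, cs)
  out
}

table_prob <- function(tab) {
  # conditional probability of a table given its margins
  exp(sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
        lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
}

oracle_fisher_p <- function(tab) {
  tabs <- enumerate_tables(rowSums(tab), colSums(tab))
  probs <- vapply(tabs, table_prob, 0)
  p_obs <- table_prob(tab)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_hypergeom_p <- function(N, A, B, k) {
  ks <- k:min(A, B)
  sum(choose(A, ks) * choose(N - A, B - ks)) / choose(N, B)
}

# step-by-step ART oracle: explicit effect estimates, ranking, and a
# cell-means F computed from scratch on the ranks (balanced designs only)
oracle_art <- function(values, age, arm, term) {
  cm <- tapply(values, list(age, arm), mean)
  grand <- mean(cm)
  ra <- rowMeans(cm) - grand
  cb <- colMeans(cm) - grand
  ab <- sweep(sweep(cm, 1, rowMeans(cm)), 2, colMeans(cm)) + grand
  resid <- values - cm[cbind(age, arm)]
  eff <- switch(term,
                age = ra[age],
                intervention = cb[arm],
                interaction = ab[cbind(age, arm)])
  r <- rank(resid + eff)
  # balanced two-way ANOVA on ranks from cell means
  n <- table(age, arm)[1, 1]
  cmr <- tapply(r, list(age, arm), mean)
  grand_r <- mean(cmr)
  ss_a <- 2 * n * sum((rowMeans(cmr) - grand_r)^2)
  ss_b <- 2 * n * sum((colMeans(cmr) - grand_r)^2)
  ss_ab <- n * sum((sweep(sweep(cmr, 1, rowMeans(cmr)), 2, colMeans(cmr)) +
                      grand_r)^2)
  ss_e <- sum((r - cmr[cbind(age, arm)])^2)
  df2 <- length(values) - 4
  ss_t <- switch(term, age = ss_a, intervention = ss_b, interaction = ss_ab)
  F <- ss_t / (ss_e / df2)
  list(F = F, p = pf(F, 1, df2, lower.tail = FALSE))
}

# (X'X)^-1 X'y by hand for the standardized 2x2 model
oracle_std_coefs <- function(values, age, arm) {
  z <- (values - mean(values)) / sd(values)
  o <- as.numeric(age == "old"); t <- as.numeric(arm == "treated")
  X <- cbind(1, o, t, o * t)
  drop(solve(t(X) %*% X) %*% t(X) %*% z)[2:4]
}

# ICC(A,1) from variance components estimated via explicit mean squares
oracle_icc_a1 <- function(x, y) {
  m <- cbind(x, y); n <- nrow(m); k <- 2
  aovtab <- summary(aov(val ~ Error(row) + col,
                        data = data.frame(val = c(x, y),
                                          row = factor(rep(seq_len(n), 2)),
                                          col = factor(rep(1:2, each = n)))))
  msr <- aovtab[["Error: row"]][[1]]["Residuals", "Mean Sq"]
  msc <- aovtab[["Error: Within"]][[1]]["col", "Mean Sq"]
  mse <- aovtab[["Error: Within"]][[1]]["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# literal reading of the onset rule, coded as explicit pattern predicates
# over the 2^5 significance patterns rather than a scan
oracle_onset <- function(sig, omnibus_sig) {
  ages <- c(5, 8, 14, 20, 26)
  if (!omnibus_sig) return("none")
  for (i in seq_along(ages)) {
    before_all_ns <- !any(sig[seq_len(i - 1)])
    here_sig <- sig[i]
    after <- sig[-seq_len(i)]
    after_ok <- sum(!after) <= 1
    if (before_all_ns && here_sig && after_ok) return(paste0("m", ages[i]))
  }
  "other"
}
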