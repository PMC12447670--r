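# Independent brute-force re-derivation of the three-criteria shift
# definition, written from first principles: explicit window index sets and
# stats::t.test() for the pooled t statistic. Used only as an oracle against
# the package's detector.
oracle_detect <- function(x, direction, cutoff, scale_max,
                          pregain_fraction = 0.25, kind = "gain") {
  if (kind == "loss") {
    direction <- setdiff(c("lower_better", "higher_better"), direction)
  }
  crit_tab <- list("3_3" = 2.776, "3_2" = 3.182, "2_3" = 3.182,
                   "2_2" = 4.303)
  found <- integer(0)
  t_len <- length(x)
  for (n in seq_len(max(0L, t_len - 1L))) {
    a <- x[n]; b <- x[n + 1]
    if (is.na(a) || is.na(b)) next
    imp <- if (direction == "lower_better") a - b else b - a
    if (imp < cutoff) next
    base <- if (direction == "lower_better") a else scale_max - a
    if (base > 0 && imp < pregain_fraction * base) next
    pre <- x[max(1, n - 2):n]
    post <- x[(n + 1):min(t_len, n + 3)]
    pre <- pre[!is.na(pre)]
    post <- post[!is.na(post)]
    if (length(pre) < 2 || length(post) < 2) next
    crit <- crit_tab[[paste0(length(pre), "_", length(post))]]
    d <- if (direction == "lower_better") {
      mean(pre) - mean(post)
    } else {
      mean(post) - mean(pre)
    }
    pooled_zero <- all(pre == pre[1]) && all(post == post[1])
    ok <- if (pooled_zero) {
      d > 0
    } else {
      tt <- stats::t.test(pre, post, var.equal = TRUE)
      t_abs <- abs(unname(tt$statistic))
      d > 0 && t_abs > crit
    }
    if (ok) found <- c(found, n)
  }
  found
}

# random gappy short series over a small score alphabet
random_series <- function(len, scale_max = 10, na_prob = 0.15) {
  x <- sample(0:scale_max, len, replace = TRUE)
  x[runif(len) < na_prob] <- NA
  x
}
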