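# Vectorized two-sample Student (pooled-variance) t-test p-values.
#
# Degenerate groups follow the documented conventions: zero pooled variance
# with equal means gives p = 1 (no evidence of change), zero pooled variance
# with unequal means gives p = 0 (infinite t). `tail` selects the two-sided
# test or a one-sided alternative (mean1 > mean2 for "greater").
pooled_t_pvalue <- function(m1, m2, v1, v2, n1, n2,
                            tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- (m1 - m2) / se
  p <- switch(tail,
    two = 2 * pt(-abs(t_stat), df),
    greater = pt(t_stat, df, lower.tail = FALSE),
    less = pt(t_stat, df, lower.tail = TRUE)
  )
  zero_var <- !is.na(se) & se == 0
  if (any(zero_var)) {
    eq <- zero_var & (m1 == m2)
    p[eq] <- if (tail == "two") 1 else 1
    ne <- zero_var & (m1 != m2)
    up <- m1 > m2
    p[ne] <- switch(tail,
      two = 0,
      greater = ifelse(up[ne], 0, 1),
      less = ifelse(up[ne], 1, 0)
    )
    p[eq] <- 1
  }
  pmin(pmax(p, 0), 1)
}
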