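# Independent oracles used across the suite. These are deliberately naive
# (per-region lm(), brute-force subset enumeration, direct binomial
# arithmetic) and never share code with the implementation they check.

# Closed-form PLS1 weight direction: normalized cross-covariance of the
# centered blocks.
oracle_pls1_weights <- function(x, y) {
  xc <- sweep(x, 2L, colMeans(x), "-")
  yc <- y - mean(y)
  w <- as.numeric(crossprod(xc, yc))
  w / sqrt(sum(w^2))
}

abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Per-region OLS via lm(), the slow reference for the w-score model.
oracle_wscore_fit <- function(controls, region) {
  fit <- stats::lm(controls[[region]] ~ age + sex, data = controls)
  list(coef = stats::coef(fit), sigma = summary(fit)$sigma,
       se = summary(fit)$coefficients[, "Std. Error"])
}

# Pooled two-sample t-statistic (equal-variance), target minus reference.
oracle_two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Brute-force dominance analysis built on lm(): every subset fit with the
# formula interface, increments averaged within then across subset sizes.
oracle_dominance <- function(y, X) {
  m <- ncol(X)
  df <- data.frame(y = y, X)
  preds <- colnames(X)
  r2_of <- function(s) {
    if (!length(s)) return(0)
    summary(stats::lm(stats::reformulate(preds[s], "y"), data = df))$r.squared
  }
  subsets <- unlist(lapply(0:(m - 1L), function(k) {
    utils::combn(m, k, simplify = FALSE)
  }), recursive = FALSE)
  total <- numeric(m)
  for (i in seq_len(m)) {
    others <- subsets[vapply(subsets, function(s) !(i %in% s), logical(1L))]
    szs <- vapply(others, length, integer(1L))
    inc <- vapply(others, function(s) r2_of(c(s, i)) - r2_of(s), numeric(1L))
    total[i] <- mean(tapply(inc, szs, mean))
  }
  list(total = total, r2_full = r2_of(seq_len(m)))
}

# Exact hypergeometric upper tail by direct summation of binomial
# coefficients (no phyper).
oracle_hyper_tail <- function(overlap, query, target, background) {
  ks <- overlap:min(query, target)
  sum(choose(target, ks) * choose(background - target, query - ks)) /
    choose(background, query)
}

# Small planted-signal dataset shared by several tests: expression with a
# planted component and a contrast vector aligned to that component.
planted_instance <- function(n_regions = 50L, n_genes = 300L,
                             n_planted = 30L, seed = 7L, noise = 0.3) {
  gen <- make_expression(n_regions, n_genes, n_latent = 2L, noise_sd = noise,
                         n_planted = n_planted, seed = seed)
  y <- stats::setNames(gen$truth$factors[, 1L], rownames(gen$expression))
  list(x = gen$expression, y = y, truth = gen$truth)
}
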