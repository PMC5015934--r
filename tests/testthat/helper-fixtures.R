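# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (explicit loops, enumeration) so they stay
# independent of the vectorized implementation paths they check.

make_meth <- function(chrom, pos, strand = "+", context3 = "CGA",
                      mc = 0L, total = 0L, call = NULL) {
  n <- max(length(chrom), length(pos), length(mc), length(total))
  if (is.null(call)) {
    call <- ifelse(total > 0 & mc / pmax(total, 1) > 0.05, 1L, 0L)
  }
  methylome(data.frame(
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    strand = rep_len(strand, n), context3 = rep_len(context3, n),
    mc_count = as.integer(rep_len(mc, n)),
    total_count = as.integer(rep_len(total, n)),
    site_call = as.integer(rep_len(call, n))))
}

random_meth <- function(n, chrom = "chr1", max_pos = 100000L,
                        contexts = c("CGA", "CAG", "CTT")) {
  pos <- sort(sample.int(max_pos, n))
  total <- rpois(n, 12)
  mc <- rbinom(n, total, runif(n))
  make_meth(chrom, pos, strand = sample(c("+", "-"), n, replace = TRUE),
            context3 = sample(contexts, n, replace = TRUE),
            mc = mc, total = total,
            call = ifelse(total > 0 & mc > 0, 1L, 0L))
}

# loop-based weighted methylation (two-pass accumulation)
oracle_weighted <- function(meth, context = "ALL") {
  sm <- 0; st <- 0
  for (i in seq_len(nrow(meth))) {
    if (meth$total_count[i] == 0) next
    if (!identical(context, "ALL") &&
        !(meth$context_class[i] %in% context)) next
    sm <- sm + meth$mc_count[i]
    st <- st + meth$total_count[i]
  }
  if (st == 0) NA_real_ else sm / st
}

# per-window recomputation by filtering, one window at a time
oracle_window_levels <- function(meth, chrom_len, window_bp, context) {
  starts <- seq(0L, chrom_len - 1L, by = window_bp)
  sapply(starts, function(s) {
    e <- min(s + window_bp, chrom_len)
    sub <- meth[meth$pos - 1L >= s & meth$pos - 1L < e &
                  meth$context_class == context & meth$total_count > 0, ]
    if (nrow(sub) == 0 || sum(sub$total_count) == 0) NA_real_
    else sum(sub$mc_count) / sum(sub$total_count)
  })
}

# literal step-up BH: q_(i) = min_{j >= i} p_(j) * n / j, capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    cands <- vapply(i:n, function(j) ps[j] * n / j, numeric(1))
    q[o[i]] <- min(1, min(cands))
  }
  q
}

# two-sided Fisher p by enumerating all tables with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; kk <- a + c
  lo <- max(0L, kk - n2); hi <- min(kk, m)
  support <- lo:hi
  probs <- vapply(support, function(x) dhyper(x, m, n2, kk), numeric(1))
  p_obs <- dhyper(a, m, n2, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force metagene: per feature, per bin, filter sites in genomic
# coordinates (explicit bin edges) and pool reads; then average features
oracle_metagene <- function(meth, features, flank_bp, body_bins, flank_bins,
                            context) {
  flank_w <- if (flank_bins > 0) flank_bp / flank_bins else 1
  n_bins <- 2 * flank_bins + body_bins
  acc <- matrix(NA_real_, nrow = nrow(features), ncol = n_bins)
  for (fi in seq_len(nrow(features))) {
    f <- features[fi, ]
    L <- f$end - f$start
    for (b in seq_len(n_bins)) {
      # bin membership in strand-corrected offset coordinates (0 = 5' gene
      # start); the rational bin edges are compared by cross-multiplication
      # so membership is exact for integer offsets
      in_bin <- function(off) {
        if (b <= flank_bins) {
          off * flank_bins >= (b - 1 - flank_bins) * flank_bp &&
            off * flank_bins < (b - flank_bins) * flank_bp
        } else if (b <= flank_bins + body_bins) {
          k <- b - flank_bins
          off >= 0 && off * body_bins >= (k - 1) * L &&
            off * body_bins < k * L
        } else {
          k <- b - flank_bins - body_bins
          (off - L) * flank_bins >= (k - 1) * flank_bp &&
            (off - L) * flank_bins < k * flank_bp
        }
      }
      sm <- 0; st <- 0
      for (si in seq_len(nrow(meth))) {
        if (meth$total_count[si] == 0) next
        if (meth$chrom[si] != f$chrom) next
        if (meth$context_class[si] != context) next
        pos0 <- meth$pos[si] - 1
        off <- if (f$strand == "-") (f$end - 1 - pos0) else (pos0 - f$start)
        if (in_bin(off)) {
          sm <- sm + meth$mc_count[si]
          st <- st + meth$total_count[si]
        }
      }
      if (st > 0) acc[fi, b] <- sm / st
    }
  }
  apply(acc, 2, function(v) if (all(is.na(v))) NA_real_ else
    mean(v, na.rm = TRUE))
}

# closed-form OLS via normal equations
oracle_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  list(slope = slope, intercept = my - slope * mx,
       r_squared = if (syy == 0) 0 else sxy^2 / (sxx * syy))
}

tiny_spec <- function(len = 50000L, seed = 1L, peri = NULL, ...) {
  genome_spec(c(chr1 = len), pericentromere = peri, seed = seed, ...)
}
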