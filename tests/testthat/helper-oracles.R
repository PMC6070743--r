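# Independent brute-force oracles for the texture engines. These scan
# pixels with explicit loops and evaluate the textbook formulas literally;
# they share no code with the package implementation.

oracle_step <- function(angle) {
  switch(as.character(angle),
         "0" = c(0, 1), "45" = c(-1, 1), "90" = c(1, 0), "135" = c(1, 1))
}

# Symmetrised, normalised co-occurrence matrix by explicit pair loops.
oracle_glcm <- function(slices, L, angle, d) {
  st <- oracle_step(angle) * d
  counts <- matrix(0, L, L)
  for (Q in slices) {
    for (r in seq_len(nrow(Q))) for (c in seq_len(ncol(Q))) {
      r2 <- r + st[1]; c2 <- c + st[2]
      if (r2 < 1 || r2 > nrow(Q) || c2 < 1 || c2 > ncol(Q)) next
      a <- Q[r, c]; b <- Q[r2, c2]
      if (a > 0 && b > 0) {
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

# The eight co-occurrence features, literal double sums.
oracle_glcm_features <- function(p) {
  L <- nrow(p)
  if (sum(p) == 0)
    return(c(Energy = 0, Entropy = 0, Inertia = 0, Correlation = 0,
             InverseDifferenceMoment = 0, ClusterShade = 0,
             ClusterProminence = 0, HaralickCorrelation = 0))
  px <- sapply(seq_len(L), function(i) sum(p[i, ]))
  mu <- sum((1:L) * px)
  sig2 <- sum(((1:L) - mu)^2 * px)
  en <- ent <- ine <- corr <- idm <- cs <- cp <- ac <- 0
  for (i in 1:L) for (j in 1:L) {
    q <- p[i, j]
    en <- en + q^2
    if (q > 0) ent <- ent - q * log(q)
    ine <- ine + (i - j)^2 * q
    if (sig2 > 0) corr <- corr + (i - mu) * (j - mu) * q / sig2
    idm <- idm + q / (1 + (i - j)^2)
    cs <- cs + (i + j - 2 * mu)^3 * q
    cp <- cp + (i + j - 2 * mu)^4 * q
    ac <- ac + i * j * q
  }
  mm <- mean(px)
  mv <- sum((px - mm)^2) / L
  hc <- if (mv > 0) (ac - mm^2) / mv else 0
  c(Energy = en, Entropy = ent, Inertia = ine, Correlation = corr,
    InverseDifferenceMoment = idm, ClusterShade = cs,
    ClusterProminence = cp, HaralickCorrelation = hc)
}

# Maximal-run scanner: a pixel starts a run iff its predecessor along the
# direction is off-grid or differently valued; run length follows the
# chain forward. Sentinel-0 runs are discarded.
oracle_rlm <- function(slices, L, angle, d, maxlen = 64) {
  st <- oracle_step(angle) * d
  counts <- matrix(0, L, maxlen)
  n_r <- 0
  for (Q in slices) {
    nr <- nrow(Q); nc <- ncol(Q)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      v <- Q[r, c]
      pr <- r - st[1]; pc <- c - st[2]
      starts <- pr < 1 || pr > nr || pc < 1 || pc > nc || Q[pr, pc] != v
      if (!starts) next
      len <- 1
      r2 <- r + st[1]; c2 <- c + st[2]
      while (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
             Q[r2, c2] == v) {
        len <- len + 1
        r2 <- r2 + st[1]; c2 <- c2 + st[2]
      }
      if (v > 0) {
        counts[v, len] <- counts[v, len] + 1
        n_r <- n_r + 1
      }
    }
  }
  list(r = counts, n_r = n_r)
}

# The ten run-length features, literal double sums.
oracle_rlm_features <- function(R) {
  r <- R$r; n_r <- R$n_r
  nm <- c("ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
          "RunLengthNonuniformity", "LowGreyLevelRunEmphasis",
          "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
          "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis",
          "LongRunHighGreyLevelEmphasis")
  if (n_r == 0) return(setNames(numeric(10), nm))
  sre <- lre <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- 0
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
    q <- r[i, j]
    if (q == 0) next
    sre <- sre + q / j^2;         lre <- lre + q * j^2
    lgl <- lgl + q / i^2;         hgl <- hgl + q * i^2
    srl <- srl + q / (i^2 * j^2); srh <- srh + q * i^2 / j^2
    lrl <- lrl + q * j^2 / i^2;   lrh <- lrh + q * i^2 * j^2
  }
  gln <- sum(sapply(seq_len(nrow(r)), function(i) sum(r[i, ]))^2)
  rln <- sum(sapply(seq_len(ncol(r)), function(j) sum(r[, j]))^2)
  setNames(c(sre, lre, gln, rln, lgl, hgl, srl, srh, lrl, lrh) / n_r, nm)
}

# Angle-aggregated feature blocks via the oracles (mean + population SD
# over the four angles), mirroring the catalogue naming.
oracle_block <- function(qslab, offsets, family = c("glcm", "rlm")) {
  family <- match.arg(family)
  angles <- c(0, 45, 90, 135)
  L <- qslab$n_levels
  out <- numeric(0)
  for (d in offsets) {
    per <- sapply(angles, function(a) {
      if (family == "glcm")
        oracle_glcm_features(oracle_glcm(qslab$slices, L, a, d))
      else
        oracle_rlm_features(oracle_rlm(qslab$slices, L, a, d))
    })
    for (f in rownames(per)) {
      v <- per[f, ]
      m <- mean(v)
      s <- sqrt(mean((v - m)^2))
      vals <- c(v, m, s)
      names(vals) <- c(paste0(f, "_angle", angles, "_offset", d),
                       paste0(f, "_AllDirection_offset", d),
                       paste0(f, "_AllDirection_offset", d, "_SD"))
      out <- c(out, vals)
    }
  }
  out
}

# Literal secondary Haralick formulas on an angle-averaged matrix.
oracle_haralick <- function(p) {
  L <- nrow(p)
  ps <- sapply(2:(2 * L), function(k) {
    s <- 0
    for (i in 1:L) for (j in 1:L) if (i + j == k) s <- s + p[i, j]
    s
  })
  pd <- sapply(0:(L - 1), function(k) {
    s <- 0
    for (i in 1:L) for (j in 1:L) if (abs(i - j) == k) s <- s + p[i, j]
    s
  })
  ks <- 2:(2 * L); kd <- 0:(L - 1)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  sa <- sum(ks * ps)
  mu_d <- sum(kd * pd)
  px <- rowSums(p)
  hx <- ent(px)
  hxy <- ent(p)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    pij <- px[i] * px[j]
    if (p[i, j] > 0 && pij > 0) hxy1 <- hxy1 - p[i, j] * log(pij)
    if (pij > 0) hxy2 <- hxy2 - pij * log(pij)
  }
  ac <- diss <- 0
  for (i in 1:L) for (j in 1:L) {
    ac <- ac + i * j * p[i, j]
    diss <- diss + abs(i - j) * p[i, j]
  }
  c(SumAverage = sa,
    SumVariance = sum((ks - sa)^2 * ps),
    SumEntropy = ent(ps),
    DifferenceVariance = sum((kd - mu_d)^2 * pd),
    DifferenceEntropy = ent(pd),
    InformationMeasureCorrelation1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    InformationMeasureCorrelation2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    MaximumProbability = max(p),
    Autocorrelation = ac,
    Dissimilarity = diss)
}
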