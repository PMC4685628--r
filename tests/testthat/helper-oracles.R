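# Independent reference implementations used to validate the package's
# computational cores. These deliberately take the most direct route
# (full enumeration, explicit loops) and share no code with R/.

# Exact Hardy-Weinberg test by full enumeration: direct multinomial
# weights for every heterozygote count compatible with the allele
# counts, p = total probability of tables no more probable than observed.
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(1)
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  r <- min(nA, na)
  if (r == 0) return(1)
  hs <- seq(r %% 2, r, by = 2)
  logw <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) + hs * log(2)
  w <- exp(logw - max(logw))
  probs <- w / sum(w)
  pobs <- probs[match(nAa, hs)]
  min(1, sum(probs[probs <= pobs * (1 + 1e-12)]))
}

# Naive cross-validated MDR for one pair: explicit loops over folds,
# cells and samples; division-based ratio rule.
oracle_mdr_cvv <- function(G, s01, folds, v1, v2,
                           policy = "low_risk", T_fix = NULL) {
  n_folds <- max(folds)
  bas <- numeric(0)
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (!length(te)) next
    trc <- sum(s01[tr] == 1)
    trn <- sum(s01[tr] == 0)
    Tval <- if (is.null(T_fix)) trc / trn else T_fix
    lab <- matrix("", 3, 3)
    for (a in 0:2) for (b in 0:2) {
      ca <- co <- 0
      for (i in tr) {
        if (is.na(G[i, v1]) || is.na(G[i, v2])) next
        if (G[i, v1] == a && G[i, v2] == b) {
          if (s01[i] == 1) ca <- ca + 1 else co <- co + 1
        }
      }
      lab[a + 1, b + 1] <-
        if (ca == 0 && co == 0) "empty"
        else if (co == 0) "high"
        else if (ca / co >= Tval) "high" else "low"
    }
    tp <- tn <- 0
    nca <- sum(s01[te] == 1)
    nco <- sum(s01[te] == 0)
    for (i in te) {
      cell <- if (is.na(G[i, v1]) || is.na(G[i, v2])) "empty"
      else lab[G[i, v1] + 1, G[i, v2] + 1]
      pred <- if (cell == "high") 1
      else if (cell == "low") 0
      else if (policy == "low_risk") 0
      else 1 - s01[i]
      if (s01[i] == 1 && pred == 1) tp <- tp + 1
      if (s01[i] == 0 && pred == 0) tn <- tn + 1
    }
    ba <- if (nca > 0 && nco > 0) (tp / nca + tn / nco) / 2
    else if (nca > 0) tp / nca
    else tn / nco
    bas <- c(bas, ba)
  }
  sum(bas) / length(bas)
}

# Exact minimum set cover by exhaustive subset search (m <= ~15).
# covers[i, j] == TRUE means candidate j covers element i.
oracle_min_cover_size <- function(covers) {
  m <- ncol(covers)
  for (k in seq_len(m)) {
    for (idx in utils::combn(m, k, simplify = FALSE)) {
      if (all(rowSums(covers[, idx, drop = FALSE]) > 0)) return(k)
    }
  }
  m
}
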