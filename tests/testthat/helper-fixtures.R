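# Programmatic fixtures shared across test files.

# Wrap a raw genotype matrix into a dataset with minimal metadata.
make_ds <- function(g, status, pos = NULL, gene = NULL, sex = "unknown",
                    age = 50) {
  g <- as.matrix(g)
  n <- nrow(g); m <- ncol(g)
  genotype_dataset(
    g,
    data.frame(id = sprintf("v%03d", seq_len(m)), chrom = "1",
               pos = if (is.null(pos)) 1000L * seq_len(m) else pos,
               allele_a = "A", allele_b = "B",
               gene = if (is.null(gene)) NA_character_ else gene,
               stringsAsFactors = FALSE),
    data.frame(id = sprintf("s%03d", seq_len(n)), sex = sex, age = age,
               status = status, stringsAsFactors = FALSE))
}

# Deterministic QC stress fixture: 120 samples x 30 variants where
# exactly one sample violates each sample filter and one variant each
# variant filter, and nothing else is touchable:
#   s001 -> 10% missing; s002 -> heterozygosity outlier (all het);
#   s004 -> exact duplicate of s003;
#   v01 -> >5% missing; v02 -> MAF ~0.009; v03 -> all-het (HWE fail in
#   controls). Filler variants give every clean sample exactly 13
#   heterozygous and ~7 homozygous-minor calls, so heterozygosity is
#   constant across clean samples and fillers sit near HWE at MAF ~0.5.
make_qc_fixture <- function() {
  n <- 120L; m <- 30L
  set.seed(424242)
  g <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    het <- sample(27L, 13L)
    hom2 <- sample(setdiff(seq_len(27L), het), 7L)
    g[i, 3L + het] <- 1L
    g[i, 3L + hom2] <- 2L
  }
  g[, 3] <- 1L
  g[, 1] <- ifelse(seq_len(n) %% 2 == 0, 2L, 0L)
  g[1, c(10, 15, 20)] <- NA_integer_
  g[2, ] <- 1L
  g[4, ] <- g[3, ]
  g[, 2] <- 0L
  g[6, 2] <- 2L
  miss_rows <- setdiff(seq_len(n), c(1L, 2L, 4L, 6L))[10:21]
  g[miss_rows, 1] <- NA_integer_
  make_ds(g, status = rep(c("case", "control"), each = 60))
}

# A small cohort with one strongly separating pair, for MDR sanity tests:
# SNP v001 equals 2*status, v002..v00m are noise.
make_separating_ds <- function(n_case = 20L, n_ctrl = 20L, m_noise = 3L,
                               seed = 99L) {
  set.seed(seed)
  n <- n_case + n_ctrl
  status <- rep(c("case", "control"), c(n_case, n_ctrl))
  g <- cbind(ifelse(status == "case", 2L, 0L),
             matrix(rbinom(n * m_noise, 2L, 0.3), n, m_noise))
  make_ds(g, status)
}
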