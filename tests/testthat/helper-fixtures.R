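# shared generators for the test suite; everything built in code

random_beta_matrix <- function(n_probes, n_samples, seed = 1,
                               probe_prefix = "cg", sample_prefix = "S") {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("%s%06d", probe_prefix, seq_len(n_probes)),
                              sprintf("%s%02d", sample_prefix, seq_len(n_samples))))
  m
}

# paired two-group sheet: subjects C01.. / N01.., samples <subject>_<tp>
paired_sheet <- function(n_conv, n_nonc) {
  subjects <- c(sprintf("C%02d", seq_len(n_conv)),
                sprintf("N%02d", seq_len(n_nonc)))
  groups <- c(rep("converter", n_conv), rep("nonconverter", n_nonc))
  data.frame(sample_id = c(paste0(subjects, "_M0"), paste0(subjects, "_MF")),
             subject_id = rep(subjects, 2),
             group = rep(groups, 2),
             timepoint = rep(c("M0", "MF"), each = length(subjects)),
             stringsAsFactors = FALSE)
}

# betas for both timepoints of a paired sheet in one matrix
paired_betas <- function(n_probes, sheet, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_probes * nrow(sheet)), n_probes, nrow(sheet),
              dimnames = list(sprintf("cg%06d", seq_len(n_probes)),
                              sheet$sample_id))
  m
}

# independent step-up BH oracle, written from the definition:
# q_(i) = min_{j >= i} min(1, p_(j) * n / j)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * n / seq_len(n))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# loop-based median oracle (sort-and-pick, even n = mean of middle two)
median_oracle <- function(x) {
  x <- unname(sort(x[!is.na(x)]))
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}
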