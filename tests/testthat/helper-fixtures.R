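# Small deterministic plot tables built in code.

make_plots <- function(n_sites = 2, n_reps = 3,
                       treatments = ofs_treatments()) {
  grid <- expand.grid(
    replicate = seq_len(n_reps), treatment = treatments,
    site = paste0("S", seq_len(n_sites)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  # deterministic, strictly positive, non-constant values
  tibble::tibble(
    site = grid$site, treatment = grid$treatment,
    replicate = grid$replicate,
    yield = 8 + 0.1 * seq_len(n) %% 7,
    grain_fe = 35 + seq_len(n) %% 11,
    grain_mn = 30 + seq_len(n) %% 5,
    grain_cu = 4 + 0.1 * (seq_len(n) %% 4),
    grain_zn = 24 + 0.5 * (seq_len(n) %% 6),
    phytic_acid = 8 + 0.05 * (seq_len(n) %% 9)
  )
}

# Independent pooled-variance LSD decision matrix, written from scratch for
# use as an oracle against fisher_lsd()'s letters.
oracle_lsd_matrix <- function(values, groups, alpha) {
  gs <- split(values, groups)
  k <- length(gs)
  n <- lengths(gs)
  means <- vapply(gs, mean, numeric(1))
  df_w <- sum(n) - k
  msw <- sum(vapply(gs, function(g) sum((g - mean(g))^2), numeric(1))) / df_w
  tcrit <- qt(1 - alpha / 2, df_w)
  out <- matrix(FALSE, k, k, dimnames = list(names(gs), names(gs)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      lsd <- tcrit * sqrt(msw * (1 / n[i] + 1 / n[j]))
      out[i, j] <- out[j, i] <- abs(means[i] - means[j]) > lsd
    }
  }
  out
}

# TRUE iff two letter strings share at least one character.
shares_letter <- function(a, b) {
  length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
}
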