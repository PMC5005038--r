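# Shared fixtures: one layout and one reference design, built in code.

fix_layout <- build_city_layout()
fix_combos <- enumerate_combinations(fix_layout)
fix_combos48 <- apply_exclusions(fix_combos, seed = 101)
fix_trials <- generate_design(fix_combos48, seed = 202)
fix_labels <- label_pairs(fix_trials, fix_layout)

# Brute-force pairwise Pearson correlation oracle (independent of the
# vectorized implementation path).
oracle_pairwise_cor <- function(x) {
  n <- nrow(x)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out <- rbind(out, c(i = i, j = j, r = cor(x[i, ], x[j, ])))
    }
  }
  out <- as.data.frame(out)
  out[order(out$j, out$i), ] # match the column-major pair enumeration
}
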