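# Shared fixtures: random tables and their expansion to 0/1 vectors for
# correlation oracles.

random_table <- function(max_count = 10) {
  contingency_table(sample(0:max_count, 1L), sample(0:max_count, 1L),
                    sample(0:max_count, 1L), sample(0:max_count, 1L))
}

# One row per observed food, coded 0/1, for use with cor()
expand_binary <- function(tab) {
  cells <- as.integer(tab)
  list(h = rep(c(1, 1, 0, 0), cells), t = rep(c(1, 0, 1, 0), cells))
}
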