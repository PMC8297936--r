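# independent oracles used across test files

# all permutations of a vector (n <= 8)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  unlist(lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))),
    recursive = FALSE)
}

# Kendall S between x and y by direct pair enumeration
kendall_s <- function(x, y) {
  up <- upper.tri(diag(length(x)))
  sum(sign(outer(x, x, "-"))[up] * sign(outer(y, y, "-"))[up])
}

# brute-force null pmf of S for tie-free data against template y
brute_s_null <- function(y) {
  n <- length(y)
  s <- vapply(all_perms(seq_len(n)), function(p) kendall_s(p, y), 0)
  tab <- table(s)
  list(S = as.numeric(names(tab)), prob = as.numeric(tab) / length(s))
}

# standard 6x6 design shared by many tests
design66 <- sampling_design()

# cosine series on the 6x6 design peaking at `phase`
cosine_series <- function(phase, amplitude = 1, baseline = 100,
                          design = design66) {
  baseline + amplitude * cos(2 * pi * (design$samples$CT - phase) / 24)
}
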