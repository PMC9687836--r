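# Independent oracles used to check the package's implementations.

# exact two-sided Mann-Whitney p by exhaustive enumeration of group splits
exact_mw_p <- function(x, y) {
  n <- length(x)
  N <- n + length(y)
  r <- rank(c(x, y))
  obs <- abs(sum(r[seq_len(n)]) - n * (N + 1) / 2)
  combs <- utils::combn(N, n)
  devs <- abs(colSums(matrix(r[combs], nrow = n)) - n * (N + 1) / 2)
  mean(devs >= obs - 1e-9)
}

# exact two-sided Fisher p by the point-probability criterion
exact_fisher_p <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  support <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  probs <- dhyper(support, cs[1], cs[2], rs[1])
  obs <- dhyper(tab[1, 1], cs[1], cs[2], rs[1])
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Benjamini-Yekutieli step-up written directly from the definition
by_stepup <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  raw <- pmin(1, m * cm * p[o] / seq_len(m))
  adj <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force UniFrac by summation over every edge of a rooted tree
unifrac_brute <- function(a, b, tree, weighted = FALSE, normalized = FALSE) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc[[e]]]
    bl <- tree$edge.length[e]
    pa <- sum(a[tips]) / sum(a)
    pb <- sum(b[tips]) / sum(b)
    if (weighted) {
      num <- num + bl * abs(pa - pb)
      den <- den + bl * (pa + pb)
    } else {
      ina <- any(a[tips] > 0)
      inb <- any(b[tips] > 0)
      num <- num + bl * xor(ina, inb)
      den <- den + bl * (ina || inb)
    }
  }
  if (weighted && !normalized) num else num / den
}

# small metadata builder for matching tests
toy_metadata <- function(ages_d, ages_c, bmi_d = NULL, bmi_c = NULL) {
  if (is.null(bmi_d)) bmi_d <- rep(25, length(ages_d))
  if (is.null(bmi_c)) bmi_c <- rep(25, length(ages_c))
  rbind(
    data.frame(sample_id = sprintf("D%02d", seq_along(ages_d)),
               group = "Disease", age = ages_d, bmi = bmi_d,
               sex = "M", extraction_method = "FS",
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("C%02d", seq_along(ages_c)),
               group = "Control", age = ages_c, bmi = bmi_c,
               sex = "F", extraction_method = "FS",
               stringsAsFactors = FALSE))
}
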