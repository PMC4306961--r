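# Shared fixtures and independent oracles.

# Brute-force oracle for the allele-recovery probability: enumerate every
# multinomial outcome over (allele_1..allele_m, error) and sum the
# probability of those where all allele counts reach k. Independent of the
# package's inclusion-exclusion path (only uses stats::dmultinom).
enum_recovery <- function(n, q, k) {
  m <- length(q)
  probs <- c(q, 1 - sum(q))
  grid <- as.matrix(expand.grid(rep(list(0:n), m)))
  grid <- grid[rowSums(grid) <= n & rowSums(grid >= k) == m, , drop = FALSE]
  total <- 0
  for (r in seq_len(nrow(grid))) {
    cnt <- grid[r, ]
    total <- total + stats::dmultinom(c(cnt, n - sum(cnt)), prob = probs)
  }
  total
}

# deterministic concrete realisation of a degenerate primer (first base of
# each IUPAC set), guaranteed to satisfy the IUPAC-aware primer match
concretize_primer <- function(p) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "A", Y = "C", S = "C",
           W = "A", K = "G", M = "A", B = "C", D = "A", H = "A", V = "A",
           N = "A")
  paste(map[strsplit(toupper(p), "")[[1]]], collapse = "")
}

# assemble a structurally complete tailed-amplicon read
make_read <- function(design, mid, insert,
                      fwd_primer = concretize_primer(design$forward_primer),
                      rev_primer = concretize_primer(design$reverse_primer)) {
  paste0(design$adaptor_forward, mid, design$forward_tail, fwd_primer,
         insert, reverse_complement(rev_primer),
         reverse_complement(design$reverse_tail), reverse_complement(mid),
         reverse_complement(design$adaptor_reverse))
}

random_insert <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# one-MID sample sheet for the simple marker system
simple_sheet <- function(mid = strrep("ACGTT", 2), enzyme = "Phusion",
                         individual = "ind1", condition = "standard") {
  sample_sheet(data.frame(
    mid = mid, locus = "mito_cr", system = "simple", enzyme = enzyme,
    pcr_condition = condition, individual = individual,
    stringsAsFactors = FALSE
  ))
}
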