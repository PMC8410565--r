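# Shared fixtures: small synthetic inputs built in code.

# compact field spec for fast pipeline tests
smallFieldSpec <- function(n_wbc = 25, n_ctc = 2, n_debris = 0, seed = 1,
                           ...) {
  fieldSpec(width = 256, height = 256, n_wbc = n_wbc, n_ctc = n_ctc,
            n_debris = n_debris, seed = seed, ...)
}

# a field holding explicit disks of value `v` on background `bg`
diskField <- function(centers, radius = 10, v = 5000, bg = 0, dim = 96,
                      pixelSize = 1) {
  m <- matrix(bg, dim, dim)
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(dim) - centers[k, 2])^2,
                (seq_len(dim) - centers[k, 1])^2, "+")
    m[d2 <= radius^2] <- v
  }
  FluorescentField(DAPI = m, CK = m, CD45 = matrix(bg, dim, dim),
                   pixelSize = pixelSize)
}

# exhaustive-search Otsu oracle over a discrete histogram
otsuOracle <- function(counts, values) {
  p <- counts / sum(counts)
  n <- length(counts)
  best <- -Inf; bestK <- 1L
  for (k in seq_len(n - 1L)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:k] * values[1:k]) / w0
    m1 <- sum(p[(k + 1):n] * values[(k + 1):n]) / w1
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best + 1e-12) { best <- sb; bestK <- k }
  }
  values[bestK]
}

# brute-force pairwise AUC (ties count 1/2)
aucOracle <- function(pos_scores, neg_scores) {
  tot <- 0
  for (a in pos_scores) for (b in neg_scores)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos_scores) * length(neg_scores))
}

# cohort counts reconstructing printed per-group detection tallies:
# n subjects, of which k have count >= 1
countsFromTally <- function(k, n) c(rep(1L, k), rep(0L, n - k))
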