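# Independent oracles, kept deliberately naive: literal double-sum
# implementations of the coupling algebra and an O(n^3) agglomerative
# clusterer. They never share code with the package internals they check.

oracle_coupling <- function(coords, sigma) {
  n <- nrow(coords)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((coords[i, ] - coords[j, ])^2)
    J[i, j] <- exp(-r2 / (4 * sigma^2))
  }
  J
}

# E(I) / <phi_I, phi_K> as explicit loops over residue pairs.
oracle_inner <- function(res_i, res_k, residues, coords, sigma) {
  J <- oracle_coupling(coords, sigma)
  acc <- 0
  for (a in res_i) for (b in res_k) {
    ia <- which(residues == a)
    ib <- which(residues == b)
    acc <- acc + J[ia, ib]
  }
  acc
}

oracle_sine <- function(res_i, res_k, residues, coords, sigma) {
  ee_i <- oracle_inner(res_i, res_i, residues, coords, sigma)
  ee_k <- oracle_inner(res_k, res_k, residues, coords, sigma)
  sp <- oracle_inner(res_i, res_k, residues, coords, sigma)
  cth <- min(max(sp / sqrt(ee_i * ee_k), 0), 1)
  sqrt(1 - cth^2)
}

# Naive average/single/complete-linkage agglomeration with a distance-
# criterion stop: merge the closest pair of clusters while the linkage
# distance is <= threshold. Returns an integer partition vector.
oracle_agglomerate <- function(d, threshold, linkage = "average") {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL
    best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      vals <- d[clusters[[a]], clusters[[b]], drop = FALSE]
      ld <- switch(linkage, average = mean(vals), single = min(vals),
                   complete = max(vals))
      if (ld < best_d - 1e-12) {
        best_d <- ld
        best <- c(a, b)
      }
    }
    if (best_d > threshold) break
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  out <- integer(nrow(d))
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

# Partition equality up to label permutation.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
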