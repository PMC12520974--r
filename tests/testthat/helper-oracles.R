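# Independent brute-force oracles, deliberately written on a different code
# path (full dist() matrices + stable sorts) from the package implementation.

oracle_knn <- function(spatial, reference, k) {
  d <- as.matrix(stats::dist(rbind(cbind(spatial$e1, spatial$e2),
                                   cbind(reference$e1, reference$e2))))
  d <- d[seq_len(nrow(spatial)), nrow(spatial) + seq_len(nrow(reference)),
         drop = FALSE]
  out <- lapply(seq_len(nrow(spatial)), function(i) {
    ord <- sort.list(d[i, ], method = "radix")[seq_len(k)]
    data.frame(cell_id = spatial$cell_id[i], neighbor_rank = seq_len(k),
               ref_cell_id = reference$cell_id[ord], distance = d[i, ord])
  })
  do.call(rbind, out)
}

oracle_nearest_target <- function(qx, qy, tx, ty) {
  vapply(seq_along(qx), function(i) {
    which.min(sqrt((tx - qx[i])^2 + (ty - qy[i])^2))
  }, integer(1))
}

# Exact binomial upper tail by direct summation of the pmf.
oracle_binom_upper <- function(obs, n, p) {
  if (obs == 0) return(1)
  ks <- obs:n
  sum(choose(n, ks) * p^ks * (1 - p)^(n - ks))
}
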