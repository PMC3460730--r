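# Independent dense reference MCL used only as a cross-check oracle.
# Plain base-R matrices and loops; cluster read-out via connected components
# of the converged matrix's non-zero pattern (a different route from the
# package's sparse attractor-based implementation).

mcl_oracle <- function(graph, inflation, expansion = 2, prune = 1e-5,
                       tol = 1e-6, max_iter = 200) {
  nodes <- graph$nodes
  n <- length(nodes)
  A <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    ui <- match(graph$edges$u, nodes)
    vi <- match(graph$edges$v, nodes)
    for (k in seq_along(ui)) {
      A[ui[k], vi[k]] <- A[ui[k], vi[k]] + graph$edges$w[k]
      A[vi[k], ui[k]] <- A[vi[k], ui[k]] + graph$edges$w[k]
    }
  }
  for (j in seq_len(n)) {
    mx <- max(A[, j])
    A[j, j] <- if (mx > 0) mx else 1
  }
  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  for (it in seq_len(max_iter)) {
    Mp <- M
    E <- M
    for (e in seq_len(expansion - 1)) E <- E %*% M
    M <- E^inflation
    for (j in seq_len(n)) {
      col <- M[, j]
      drop <- col < prune
      drop[which.max(col)] <- FALSE
      col[drop] <- 0
      M[, j] <- col
    }
    M <- normalize(M)
    if (max(abs(M - Mp)) < tol) break
  }
  # clusters = connected components of the symmetrized non-zero pattern
  adj <- (M + t(M)) > 0
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- which(adj[cur, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}
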