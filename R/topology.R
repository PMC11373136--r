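# Classical 2D topological indices computed from the heavy-atom connectivity
# matrix. These form the extended descriptor block; all are pure graph
# quantities (no conformers), defined for connected molecular graphs and
# returned as NA where degenerate (single atoms, no bonds) so that
# clean_features() can drop them uniformly.

# all-pairs shortest paths by BFS; molecules are small so this is cheap
.graph_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

.topological_indices <- function(sdf) {
  con <- tryCatch(ChemmineR::conMA(sdf, exclude = "H")[[1]], error = function(e) NULL)
  na_out <- c(Wiener = NA_real_, Harary = NA_real_, ZagrebM1 = NA_real_,
              ZagrebM2 = NA_real_, Randic = NA_real_, Platt = NA_real_,
              BalabanJ = NA_real_, Diameter = NA_real_, Radius = NA_real_,
              EccConn = NA_real_, MeanDist = NA_real_, Kappa1 = NA_real_,
              Kappa2 = NA_real_, LeadEig = NA_real_, Connectivity1 = NA_real_)
  if (is.null(con) || nrow(con) < 2) return(na_out)
  adj <- (con > 0) * 1
  diag(adj) <- 0
  n <- nrow(adj)
  deg <- rowSums(adj)
  if (any(deg == 0)) return(na_out)
  d <- .graph_distances(adj)
  if (any(!is.finite(d))) return(na_out)   # disconnected (should not occur post-curation)
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  m <- nrow(edges)
  dsum <- rowSums(d)
  ecc <- apply(d, 1, max)
  wiener <- sum(d[upper.tri(d)])
  harary <- sum(1 / d[upper.tri(d)])
  zm1 <- sum(deg^2)
  zm2 <- sum(deg[edges[, 1]] * deg[edges[, 2]])
  randic <- sum(1 / sqrt(deg[edges[, 1]] * deg[edges[, 2]]))
  platt <- sum(deg[edges[, 1]] + deg[edges[, 2]] - 2)
  mu <- m - n + 1                                   # cyclomatic number
  balaban <- if (mu + 1 > 0)
    m / (mu + 1) * sum(1 / sqrt(dsum[edges[, 1]] * dsum[edges[, 2]])) else NA_real_
  p2 <- sum(choose(deg, 2))                         # paths of length 2
  kappa1 <- if (m > 0) n * (n - 1)^2 / m^2 else NA_real_
  kappa2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else NA_real_
  leig <- max(eigen(adj, symmetric = TRUE, only.values = TRUE)$values)
  c(Wiener = wiener, Harary = harary, ZagrebM1 = zm1, ZagrebM2 = zm2,
    Randic = randic, Platt = platt, BalabanJ = balaban,
    Diameter = max(ecc), Radius = min(ecc), EccConn = sum(deg * ecc),
    MeanDist = wiener / (n * (n - 1) / 2), Kappa1 = kappa1, Kappa2 = kappa2,
    LeadEig = leig)
}
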