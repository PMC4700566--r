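# fixtures shared across test files; all generated in code

# per-linkage-group map characteristics as published for the SY-PM cross
sypm_lg_table <- function() {
  utils::read.delim(system.file("extdata", "sypm_linkage_groups.tsv",
                                package = "brassicomp"))
}

# per-chromosome rearrangement event counts among the three A subgenomes
sypm_event_table <- function() {
  utils::read.delim(system.file("extdata", "a_subgenome_rearrangements.tsv",
                                package = "brassicomp"), check.names = FALSE)
}

# random genotype matrix with bins planted by duplicating rows
random_calls <- function(m, n, missing_rate = 0.1, seed = 1) {
  set.seed(seed)
  base <- matrix(sample(c("A", "H", "B"), m * n, replace = TRUE,
                        prob = c(0.25, 0.5, 0.25)), m, n)
  drop <- matrix(runif(m * n) < missing_rate, m, n)
  base[drop] <- NA_character_
  rownames(base) <- sprintf("M%03d", seq_len(m))
  base
}

# independent O(m^2 n) oracle: connected components of the pairwise
# zero-mismatch compatibility graph, via repeated BFS
brute_force_bins <- function(calls) {
  m <- nrow(calls)
  compat <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    compat[i, j] <- !any(calls[i, ok] != calls[j, ok])
  }
  comp <- rep(NA_integer_, m)
  cid <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(compat[v, ] & is.na(comp)))
    }
  }
  ids <- rownames(calls)
  unname(vapply(seq_len(m),
                function(i) min(ids[comp == comp[i]]), character(1)))
}

# UPGMA cophenetic matrix recomputed by brute force over the merge sequence
brute_force_upgma_cophenetic <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  sizes <- rep(1, length(labels))
  coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      if (d[i, j] < best[1] - 1e-12) best <- c(d[i, j], i, j)
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]])
      coph[a, b] <- coph[b, a] <- best[1]
    keep <- setdiff(1:m, c(i, j))
    newd <- (sizes[i] * d[i, keep] + sizes[j] * d[j, keep]) /
      (sizes[i] + sizes[j])
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd), c(newd, 0))
    clusters <- c(clusters[keep], list(c(clusters[[i]], clusters[[j]])))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  coph
}

# random symmetric distance matrix with distinct off-diagonal entries
random_dist <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- sample(seq_len(n * (n - 1) / 2)) + runif(n * (n - 1) / 2)
  d <- d + t(d)
  dimnames(d) <- list(letters[seq_len(n)], letters[seq_len(n)])
  d
}
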