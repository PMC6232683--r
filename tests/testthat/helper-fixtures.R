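# Fixtures and independent brute-force oracles used across the suite.

# write a two-column association TSV and return its path
write_assoc_file <- function(pairs, comments = character(0)) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(comments, vapply(pairs, paste, character(1), collapse = "\t")),
             path)
  path
}

# similarity_matrix from a plain matrix with default labels
sim_from <- function(m, names = paste0("D", seq_len(nrow(m)))) {
  similarity_matrix(m, names)
}

# the 3-edge fixture: lncRNAs l1, l2 and disease d1 with association edges
# l1-d1 and l2-d1 (weight 1) and an LL edge l1-l2 of weight 0.5
fixture_net_3edge <- function(cfg = network_config(T = 0.2, tau = 2)) {
  data <- association_dataset(c("l1", "l2"), "d1", matrix(1, 2, 1))
  LS <- sim_from(matrix(c(1, 0.5, 0.5, 1), 2), c("l1", "l2"))
  DS <- sim_from(matrix(1, 1, 1), "d1")
  list(data = data, net = build_network(data, DS, LS, cfg), cfg = cfg)
}

# random small association dataset + similarities + network, for property
# tests over the real construction path
random_hetero_instance <- function(nl = sample(2:5, 1), nd = sample(2:5, 1),
                                   T = runif(1, 0, 0.5)) {
  LD <- matrix(rbinom(nl * nd, 1, 0.4), nl, nd)
  if (sum(LD) == 0) LD[sample(nl, 1), sample(nd, 1)] <- 1
  data <- association_dataset(paste0("l", seq_len(nl)),
                              paste0("d", seq_len(nd)), LD)
  rand_sim <- function(n, names) {
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    m[m < 0.3] <- 0                      # some sparsity
    diag(m) <- 1
    similarity_matrix(m, names)
  }
  LS <- rand_sim(nl, data$lncrna_names)
  DS <- rand_sim(nd, data$disease_names)
  cfg <- network_config(T = T, tau = sample(1:4, 1))
  list(data = data, LS = LS, DS = DS, cfg = cfg,
       net = build_network(data, DS, LS, cfg))
}

# ---- brute-force oracles -------------------------------------------------

# all ordered k-permutations of v
perms_of <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  if (length(v) == 0L) return(list())
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i], k - 1L))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# simple paths s..t with <= tau edges by testing every node sequence:
# returns a sorted character vector of "s-i1-...-t" keys
brute_force_path_keys <- function(W, s, t, tau) {
  n <- nrow(W)
  interior <- setdiff(seq_len(n), c(s, t))
  keys <- character(0)
  for (len in seq_len(tau)) {            # len = edge count
    for (mid in perms_of(interior, len - 1L)) {
      seqn <- c(s, mid, t)
      ok <- all(W[cbind(seqn[-length(seqn)], seqn[-1])] > 0)
      if (ok) keys <- c(keys, paste(seqn, collapse = "-"))
    }
  }
  sort(keys)
}

# decay-weighted score by explicit summation over brute-force paths
brute_force_score <- function(W, s, t, tau, alpha) {
  n <- nrow(W)
  interior <- setdiff(seq_len(n), c(s, t))
  total <- 0
  for (len in seq_len(tau)) {
    for (mid in perms_of(interior, len - 1L)) {
      seqn <- c(s, mid, t)
      w <- W[cbind(seqn[-length(seqn)], seqn[-1])]
      if (all(w > 0)) total <- total + prod(w) * alpha^(-len)
    }
  }
  total
}

# Mann-Whitney AUC by explicit pairwise counting
brute_force_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# lncRNA functional similarity by nested loops and explicit max scan
brute_force_fs <- function(LD, SSv) {
  nl <- nrow(LD)
  FS <- diag(1, nl)
  sim_to_group <- function(d, D) {
    best <- 0
    for (dp in D) if (SSv[d, dp] > best) best <- SSv[d, dp]
    best
  }
  for (i in seq_len(nl)) for (j in seq_len(nl)) {
    if (i == j) next
    Di <- which(LD[i, ] == 1); Dj <- which(LD[j, ] == 1)
    if (length(Di) + length(Dj) == 0) { FS[i, j] <- 0; next }
    acc <- 0
    for (d in Di) acc <- acc + sim_to_group(d, Dj)
    for (d in Dj) acc <- acc + sim_to_group(d, Di)
    FS[i, j] <- acc / (length(Di) + length(Dj))
  }
  FS
}
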