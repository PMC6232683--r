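#' Enumerate simple paths of bounded length between an lncRNA and a disease
#'
#' Depth-first enumeration of every simple (non-cyclic) path with between 1
#' and `tau` edges connecting the two endpoints in the heterogeneous network.
#' Each path is reported once; ordering is unspecified. This R-level
#' enumeration materializes the paths; [score_pair()] uses an equivalent
#' compiled traversal that accumulates the score without storing paths.
#'
#' @param net a `hetero_network` from [build_network()].
#' @param l lncRNA name.
#' @param d disease name.
#' @param tau maximum path length in edges (`>= 1`); defaults to the
#'   network's configuration.
#' @return A list of class `path_set`; each element is a list with `nodes`
#'   (class-prefixed node ids from `l` to `d`), `length` (edge count) and
#'   `weight_product`.
#' @export
enumerate_paths <- function(net, l, d, tau = net$config$tau) {
  stopifnot(inherits(net, "hetero_network"))
  if (tau < 1) stop("tau must be >= 1")
  s <- resolve_node(net, l, "lncrna")
  t <- resolve_node(net, d, "disease")
  W <- net$W
  ids <- rownames(W)
  n <- nrow(W)
  nbrs <- lapply(seq_len(n), function(i) which(W[i, ] > 0))

  paths <- list()
  visited <- logical(n)
  walk <- function(u, depth, prod, trail) {
    visited[u] <<- TRUE
    for (v in nbrs[[u]]) {
      p2 <- prod * W[u, v]
      if (v == t) {
        paths[[length(paths) + 1L]] <<- list(
          nodes = ids[c(trail, u, v)], length = depth + 1L,
          weight_product = p2
        )
      } else if (!visited[v] && depth + 1L < tau) {
        walk(v, depth + 1L, p2, c(trail, u))
      }
    }
    visited[u] <<- FALSE
  }
  walk(s, 0L, 1, integer(0))
  structure(paths, class = "path_set",
            lncrna = net$nodes$name[s], disease = net$nodes$name[t])
}

decay_code <- function(decay_form) {
  switch(decay_form, exp_decay = 1L, product_power = 2L,
         stop("unknown decay form: ", decay_form))
}

#' Decay-weighted score of a path set
#'
#' Sums each path's edge-weight product, down-weighted by path length: under
#' `exp_decay` a path of length `len` and product `p` contributes
#' `p * alpha^-len`; under `product_power` it contributes `p^(alpha*len)`.
#' An empty path set scores 0.
#'
#' @param paths a `path_set` from [enumerate_paths()].
#' @param cfg a [network_config()] supplying `alpha` and `decay_form`.
#' @return A list of class `pair_score` with `lncrna`, `disease`, `score`,
#'   `n_paths`.
#' @export
path_score <- function(paths, cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  terms <- vapply(paths, function(p) {
    if (cfg$decay_form == "exp_decay")
      p$weight_product * cfg$alpha^(-p$length)
    else
      p$weight_product^(cfg$alpha * p$length)
  }, numeric(1))
  structure(list(
    lncrna = attr(paths, "lncrna"), disease = attr(paths, "disease"),
    score = sum(terms), n_paths = length(paths)
  ), class = "pair_score")
}

#' Score one lncRNA-disease pair
#'
#' Composition of bounded simple-path enumeration and decay-weighted
#' summation, executed by the compiled depth-first traversal. The score is 0
#' exactly when no path of length `<= tau` connects the pair.
#'
#' @inheritParams enumerate_paths
#' @param cfg a [network_config()]; `tau`, `alpha` and `decay_form` are taken
#'   from it.
#' @return A `pair_score` list: `lncrna`, `disease`, `score`, `n_paths`.
#' @export
score_pair <- function(net, l, d, cfg = net$config) {
  stopifnot(inherits(net, "hetero_network"), inherits(cfg, "network_config"))
  s <- resolve_node(net, l, "lncrna")
  t <- resolve_node(net, d, "disease")
  res <- cpp_path_scores(net$W, s - 1L, t - 1L, cfg$tau, cfg$alpha,
                         decay_code(cfg$decay_form))
  structure(list(
    lncrna = net$nodes$name[s], disease = net$nodes$name[t],
    score = res$score[1], n_paths = res$n_paths[1]
  ), class = "pair_score")
}

#' Score every lncRNA-disease pair
#'
#' @param net a `hetero_network`.
#' @param data the [association_dataset()] the network was built from (fixes
#'   the row/column order of the result).
#' @param cfg a [network_config()].
#' @return Numeric matrix (lncRNAs x diseases) of non-negative scores.
#' @export
score_all <- function(net, data, cfg = net$config) {
  stopifnot(inherits(net, "hetero_network"),
            inherits(data, "association_dataset"))
  nl <- length(data$lncrna_names)
  nd <- length(data$disease_names)
  if (nl != net$n_lncrna || nd != net$n_disease)
    stop("dataset and network dimensions differ")
  pairs <- expand.grid(i = seq_len(nl), j = seq_len(nd))
  res <- cpp_path_scores(net$W, pairs$i - 1L, net$n_lncrna + pairs$j - 1L,
                         cfg$tau, cfg$alpha, decay_code(cfg$decay_form))
  matrix(res$score, nl, nd,
         dimnames = list(data$lncrna_names, data$disease_names))
}

# batch scorer over explicit (lncRNA index, disease index) pairs; internal
score_pairs_idx <- function(net, li, dj, cfg = net$config) {
  res <- cpp_path_scores(net$W, li - 1L, net$n_lncrna + dj - 1L,
                         cfg$tau, cfg$alpha, decay_code(cfg$decay_form))
  res$score
}
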