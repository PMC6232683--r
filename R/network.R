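#' Network and scoring configuration
#'
#' Holds the operating point of the predictor: the similarity edge threshold
#' `T`, the maximum path length `tau` (in edges), the decay factor `alpha`,
#' and the decay form. The defaults (`T = 0.2`, `tau = 3`, `alpha = 2.26`)
#' are the operating point at which the method performs best in
#' leave-one-out cross-validation.
#'
#' @param T similarity-edge weight threshold in `[0, 1]`; similarity entries
#'   below `T` produce no edge (association edges are never thresholded).
#' @param tau maximum number of edges in a scored path, `>= 1`.
#' @param alpha path-length decay factor, `> 1`.
#' @param decay_form `"exp_decay"` (default): each path contributes
#'   `prod(weights) * alpha^-length`; `"product_power"`: it contributes
#'   `prod(weights)^(alpha * length)`.
#' @return A list of class `network_config`.
#' @export
network_config <- function(T = 0.2, tau = 3, alpha = 2.26,
                           decay_form = c("exp_decay", "product_power")) {
  decay_form <- match.arg(decay_form)
  if (!is.numeric(T) || length(T) != 1 || T < 0 || T > 1)
    stop("threshold T must lie in [0, 1]")
  if (!is.numeric(tau) || length(tau) != 1 || tau < 1 || tau != round(tau))
    stop("tau must be an integer >= 1")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 1)
    stop("alpha must be > 1")
  structure(list(T = T, tau = as.integer(tau), alpha = alpha,
                 decay_form = decay_form), class = "network_config")
}

# internal node id: class-prefixed so an lncRNA and a disease sharing a name
# stay distinct nodes
node_ids <- function(data) {
  c(paste0("l:", data$lncrna_names), paste0("d:", data$disease_names))
}

#' Assemble the thresholded heterogeneous network
#'
#' Builds one undirected weighted graph over all lncRNA and disease nodes
#' with three edge classes: lncRNA-lncRNA edges weighted by `LS` (kept when
#' `LS >= T`), disease-disease edges weighted by `DS` (kept when `DS >= T`),
#' and lncRNA-disease association edges of weight exactly 1 wherever
#' `LD = 1`. Isolated nodes are retained, so novel entities are scoreable
#' (score 0 when no path exists). No self-loops are created.
#'
#' @param data an [association_dataset()].
#' @param DS integrated disease similarity over `data$disease_names`.
#' @param LS integrated lncRNA similarity over `data$lncrna_names`.
#' @param cfg a [network_config()].
#' @return An object of class `hetero_network`: `nodes` (data.frame with
#'   `name`, `type`), `W` (full symmetric weight matrix, 0 = no edge),
#'   `n_lncrna`, `n_disease`, `config`.
#' @export
build_network <- function(data, DS, LS, cfg = network_config()) {
  stopifnot(inherits(data, "association_dataset"),
            inherits(cfg, "network_config"))
  LS <- align_similarity(LS, data$lncrna_names, what = "lncRNA")
  DS <- align_similarity(DS, data$disease_names, what = "disease")
  nl <- length(data$lncrna_names)
  nd <- length(data$disease_names)

  WL <- LS$values; WL[WL < cfg$T] <- 0; diag(WL) <- 0
  WD <- DS$values; WD[WD < cfg$T] <- 0; diag(WD) <- 0

  W <- matrix(0, nl + nd, nl + nd)
  W[seq_len(nl), seq_len(nl)] <- WL
  W[nl + seq_len(nd), nl + seq_len(nd)] <- WD
  W[seq_len(nl), nl + seq_len(nd)] <- data$LD
  W[nl + seq_len(nd), seq_len(nl)] <- t(data$LD)
  ids <- node_ids(data)
  dimnames(W) <- list(ids, ids)

  structure(list(
    nodes = data.frame(
      name = c(data$lncrna_names, data$disease_names),
      type = rep(c("lncrna", "disease"), c(nl, nd)),
      stringsAsFactors = FALSE
    ),
    W = W, n_lncrna = nl, n_disease = nd, config = cfg
  ), class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  e <- network_edges(x)
  cat(sprintf(
    "<hetero_network> %d lncRNAs + %d diseases; %d edges (%d LL, %d DD, %d assoc)\n",
    x$n_lncrna, x$n_disease, nrow(e),
    sum(e$class == "LL"), sum(e$class == "DD"), sum(e$class == "LDassoc")
  ))
  invisible(x)
}

#' Edge list of a heterogeneous network
#'
#' @param net a `hetero_network`.
#' @return data.frame with columns `node1`, `node2`, `weight`, `class`
#'   (one row per undirected edge).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  idx <- which(upper.tri(net$W) & net$W > 0, arr.ind = TRUE)
  nl <- net$n_lncrna
  cls <- ifelse(idx[, 1] <= nl & idx[, 2] <= nl, "LL",
         ifelse(idx[, 1] > nl & idx[, 2] > nl, "DD", "LDassoc"))
  data.frame(
    node1 = net$nodes$name[idx[, 1]],
    node2 = net$nodes$name[idx[, 2]],
    weight = net$W[idx],
    class = cls,
    stringsAsFactors = FALSE
  )
}

# resolve entity names to node indices in net$W
resolve_node <- function(net, name, type) {
  pool <- which(net$nodes$type == type)
  hit <- pool[normalize_name(net$nodes$name[pool]) == normalize_name(name)]
  if (length(hit) != 1L)
    stop(sprintf("unknown %s node '%s'", type, name))
  hit
}

#' Remove one association edge from a network
#'
#' Used to construct cross-validation folds: returns a copy of the network
#' with the lncRNA-disease association edge removed; the input network is
#' unmodified. Errors if the pair has no association edge.
#'
#' @param net a `hetero_network`.
#' @param l lncRNA name.
#' @param d disease name.
#' @return A `hetero_network` with one edge fewer.
#' @export
remove_association <- function(net, l, d) {
  i <- resolve_node(net, l, "lncrna")
  j <- resolve_node(net, d, "disease")
  if (net$W[i, j] == 0)
    stop(sprintf("no association edge between '%s' and '%s'", l, d))
  net$W[i, j] <- 0
  net$W[j, i] <- 0
  net
}
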