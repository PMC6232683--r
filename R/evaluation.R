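#' ROC curve and AUC from positive and negative score lists
#'
#' AUC is the Mann-Whitney statistic: the probability that a random positive
#' outranks a random negative, ties counted half —
#' `AUC = (#(pos > neg) + 0.5 * #(pos = neg)) / (|pos| * |neg|)`, computed
#' via midranks. ROC points are obtained by sweeping the decision threshold
#' over every distinct score, from (0, 0) to (1, 1).
#'
#' @param positive_scores,negative_scores non-empty numeric vectors.
#' @return List with `auc` and `roc_points` (data.frame `fpr`, `tpr`).
#' @export
roc_auc <- function(positive_scores, negative_scores) {
  np <- length(positive_scores); nn <- length(negative_scores)
  if (np == 0L || nn == 0L)
    stop("both score lists must be non-empty")
  r <- rank(c(positive_scores, negative_scores))   # midranks handle ties
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  thr <- sort(unique(c(positive_scores, negative_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(positive_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(negative_scores >= t), numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  list(auc = auc, roc_points = roc)
}

loocv_result <- function(mode, positive_scores, negative_scores, per_fold) {
  ra <- roc_auc(positive_scores, negative_scores)
  structure(list(
    mode = mode,
    positive_scores = positive_scores,
    negative_scores = negative_scores,
    auc = ra$auc,
    roc_points = ra$roc_points,
    per_fold = per_fold
  ), class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> mode=%s folds=%d positives=%d negatives=%d AUC=%.5f\n",
              x$mode, nrow(x$per_fold), length(x$positive_scores),
              length(x$negative_scores), x$auc))
  invisible(x)
}

# shared fold machinery: given a training LD (with held-out entries zeroed),
# recompute (or reuse) similarities and return the fold network
fold_network <- function(data, SS, cfg, LD_train, full_sims,
                         reuse_similarities, gamma_prime_l, gamma_prime_d,
                         use_gl, use_gd) {
  train <- association_dataset(data$lncrna_names, data$disease_names, LD_train)
  sims <- if (reuse_similarities) full_sims
          else compute_similarities(train, SS, gamma_prime_l, gamma_prime_d,
                                    use_gl, use_gd)
  build_network(train, sims$DS, sims$LS, cfg)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is held out once: its entry is zeroed in the
#' training matrix, every similarity (functional, both kernels, fallback
#' sets, integrations) is recomputed from the training matrix, the network
#' is rebuilt, and the held-out pair is scored on it. Scores of all
#' unassociated pairs, computed once on the full-data network, serve as the
#' negative set. AUC pools the held-out scores against the negatives.
#'
#' @param data an [association_dataset()] with at least 2 associations.
#' @param SS disease semantic similarity covering `data`'s diseases.
#' @param cfg a [network_config()].
#' @param reuse_similarities if `TRUE`, folds reuse the full-data
#'   similarities and only drop the association edge (faster, but lets the
#'   held-out association leak into the kernels).
#' @param gamma_prime_l,gamma_prime_d kernel bandwidth scales.
#' @param use_gl,use_gd kernel-fallback switches (see
#'   [compute_similarities()]).
#' @return A `loocv_result` (mode `"global"`); `per_fold` has one row per
#'   association with its held-out score.
#' @export
global_loocv <- function(data, SS, cfg = network_config(),
                         reuse_similarities = FALSE,
                         gamma_prime_l = 1, gamma_prime_d = 1,
                         use_gl = TRUE, use_gd = TRUE) {
  stopifnot(inherits(data, "association_dataset"))
  SS <- align_similarity(SS, data$disease_names, what = "disease")
  pos_idx <- which(data$LD == 1, arr.ind = TRUE)
  if (nrow(pos_idx) < 2L) stop("global LOOCV needs at least 2 associations")

  full_sims <- compute_similarities(data, SS, gamma_prime_l, gamma_prime_d,
                                    use_gl, use_gd)
  full_net <- build_network(data, full_sims$DS, full_sims$LS, cfg)
  neg_idx <- which(data$LD == 0, arr.ind = TRUE)
  negative_scores <- score_pairs_idx(full_net, neg_idx[, 1], neg_idx[, 2], cfg)

  positive_scores <- numeric(nrow(pos_idx))
  for (k in seq_len(nrow(pos_idx))) {
    i <- pos_idx[k, 1]; j <- pos_idx[k, 2]
    LD_train <- data$LD
    LD_train[i, j] <- 0
    net <- fold_network(data, SS, cfg, LD_train, full_sims,
                        reuse_similarities, gamma_prime_l, gamma_prime_d,
                        use_gl, use_gd)
    # the held-out pair's direct edge must be absent from the fold network
    stopifnot(net$W[i, net$n_lncrna + j] == 0)
    positive_scores[k] <- score_pairs_idx(net, i, j, cfg)
  }
  per_fold <- data.frame(
    lncrna = data$lncrna_names[pos_idx[, 1]],
    disease = data$disease_names[pos_idx[, 2]],
    score = positive_scores,
    stringsAsFactors = FALSE
  )
  loocv_result("global", positive_scores, negative_scores, per_fold)
}

#' Local leave-one-out cross-validation for novel entities
#'
#' For each lncRNA (mode `"novel_lncrna"`) or disease (mode
#' `"novel_disease"`) with at least one association, all of its associations
#' are held out at once — the whole row (or column) of the training matrix
#' is zeroed, similarities and network recomputed — and the entity is scored
#' against every entity of the other class. Its true associations are the
#' fold's positives, the rest its negatives; folds are pooled for the AUC.
#'
#' @inheritParams global_loocv
#' @param mode `"novel_lncrna"` or `"novel_disease"`.
#' @return A `loocv_result`; `per_fold` has one row per (entity, candidate)
#'   pair with the score and the true label.
#' @export
local_loocv <- function(data, SS, cfg = network_config(),
                        mode = c("novel_lncrna", "novel_disease"),
                        reuse_similarities = FALSE,
                        gamma_prime_l = 1, gamma_prime_d = 1,
                        use_gl = TRUE, use_gd = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "association_dataset"))
  SS <- align_similarity(SS, data$disease_names, what = "disease")
  full_sims <- compute_similarities(data, SS, gamma_prime_l, gamma_prime_d,
                                    use_gl, use_gd)
  nl <- length(data$lncrna_names)
  nd <- length(data$disease_names)
  by_lncrna <- mode == "novel_lncrna"
  entities <- if (by_lncrna) which(rowSums(data$LD) > 0)
              else which(colSums(data$LD) > 0)
  if (length(entities) == 0L) stop("no entity with an association to hold out")

  folds <- vector("list", length(entities))
  for (k in seq_along(entities)) {
    e <- entities[k]
    LD_train <- data$LD
    if (by_lncrna) LD_train[e, ] <- 0 else LD_train[, e] <- 0
    net <- fold_network(data, SS, cfg, LD_train, full_sims,
                        reuse_similarities, gamma_prime_l, gamma_prime_d,
                        use_gl, use_gd)
    if (by_lncrna) {
      stopifnot(all(net$W[e, net$n_lncrna + seq_len(nd)] == 0))
      sc <- score_pairs_idx(net, rep(e, nd), seq_len(nd), cfg)
      folds[[k]] <- data.frame(
        entity = data$lncrna_names[e], candidate = data$disease_names,
        score = sc, label = data$LD[e, ] == 1, stringsAsFactors = FALSE)
    } else {
      stopifnot(all(net$W[seq_len(nl), net$n_lncrna + e] == 0))
      sc <- score_pairs_idx(net, seq_len(nl), rep(e, nl), cfg)
      folds[[k]] <- data.frame(
        entity = data$disease_names[e], candidate = data$lncrna_names,
        score = sc, label = data$LD[, e] == 1, stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, folds)
  loocv_result(mode,
               per_fold$score[per_fold$label],
               per_fold$score[!per_fold$label],
               per_fold)
}

#' Precision within score intervals
#'
#' Pools the held-out positive and negative scores of a cross-validation
#' result, assigns each to the interval defined by consecutive `bin_edges`
#' (left-closed; the last interval also closed on the right), and reports
#' the fraction of true associations per interval. Empty intervals get
#' `NA` precision.
#'
#' @param result a `loocv_result`.
#' @param bin_edges strictly increasing numeric vector of interval edges.
#' @return data.frame with `score_lo`, `score_hi`, `n_predictions`,
#'   `n_true`, `precision`.
#' @export
precision_bins <- function(result, bin_edges) {
  stopifnot(inherits(result, "loocv_result"))
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing with length >= 2")
  scores <- c(result$positive_scores, result$negative_scores)
  labels <- rep(c(TRUE, FALSE), c(length(result$positive_scores),
                                  length(result$negative_scores)))
  nb <- length(bin_edges) - 1L
  out <- data.frame(score_lo = bin_edges[-length(bin_edges)],
                    score_hi = bin_edges[-1],
                    n_predictions = integer(nb), n_true = integer(nb),
                    precision = NA_real_)
  for (b in seq_len(nb)) {
    hi_ok <- if (b == nb) scores <= out$score_hi[b] else scores < out$score_hi[b]
    in_bin <- scores >= out$score_lo[b] & hi_ok
    out$n_predictions[b] <- sum(in_bin)
    out$n_true[b] <- sum(labels[in_bin])
    if (out$n_predictions[b] > 0)
      out$precision[b] <- out$n_true[b] / out$n_predictions[b]
  }
  out
}

#' Sweep the weight threshold and maximum path length
#'
#' Runs [global_loocv()] for every combination of threshold `T` and maximum
#' path length `L`, returning the AUC grid. Cells are skipped (AUC `NA`)
#' once a cheaper cell at the same threshold with a smaller `L` has already
#' exceeded `cell_time_budget` seconds, since runtime grows steeply with `L`.
#'
#' @inheritParams global_loocv
#' @param T_values numeric vector of thresholds.
#' @param L_values integer vector of maximum path lengths.
#' @param cell_time_budget per-cell wall-clock budget in seconds
#'   (default `Inf`).
#' @return data.frame with columns `T`, `L`, `auc`, `elapsed`, `skipped`.
#' @export
parameter_sweep <- function(data, SS, T_values, L_values,
                            cfg = network_config(),
                            reuse_similarities = FALSE,
                            cell_time_budget = Inf) {
  grid <- expand.grid(T = T_values, L = sort(L_values))
  grid$auc <- NA_real_; grid$elapsed <- NA_real_; grid$skipped <- FALSE
  for (r in seq_len(nrow(grid))) {
    over <- grid$T == grid[r, "T"] & grid$L < grid[r, "L"] &
      !is.na(grid$elapsed) & grid$elapsed > cell_time_budget
    if (any(over)) { grid$skipped[r] <- TRUE; next }
    cell_cfg <- network_config(T = grid[r, "T"], tau = grid[r, "L"],
                               alpha = cfg$alpha, decay_form = cfg$decay_form)
    t0 <- proc.time()[["elapsed"]]
    res <- global_loocv(data, SS, cell_cfg,
                        reuse_similarities = reuse_similarities)
    grid$elapsed[r] <- proc.time()[["elapsed"]] - t0
    grid$auc[r] <- res$auc
  }
  grid
}

#' Effect of the Gaussian-kernel fallbacks on cross-validation AUC
#'
#' Runs global LOOCV under four settings: no kernel fallback at all
#' (`DS = SS`, `LS = FS`), lncRNA kernel only, disease kernel only, and both
#' kernels (the full method). When no entity lacks semantic/functional
#' similarity, the four settings coincide.
#'
#' @inheritParams global_loocv
#' @return Named numeric vector of AUCs:
#'   `no_kernel`, `gl_only`, `gd_only`, `both`.
#' @export
kernel_ablation <- function(data, SS, cfg = network_config(),
                            reuse_similarities = FALSE) {
  run <- function(use_gl, use_gd)
    global_loocv(data, SS, cfg, reuse_similarities = reuse_similarities,
                 use_gl = use_gl, use_gd = use_gd)$auc
  c(no_kernel = run(FALSE, FALSE),
    gl_only = run(TRUE, FALSE),
    gd_only = run(FALSE, TRUE),
    both = run(TRUE, TRUE))
}
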