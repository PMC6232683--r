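#' Run the full prediction pipeline
#'
#' End-to-end orchestration: read (or accept) the association dataset and
#' disease semantic similarity, compute the integrated similarities, build
#' the thresholded heterogeneous network, score every lncRNA-disease pair,
#' and write the ranked predictions and score matrix; optionally run a
#' cross-validation and write its report. Known associations are flagged in
#' the ranked output rather than removed (`novel_only = TRUE` filters them).
#'
#' @param associations path to a two-column association TSV, or an
#'   [association_dataset()].
#' @param ss path to a labeled similarity TSV, or a [similarity_matrix()].
#' @param out_dir output directory (created if missing); `NULL` writes
#'   nothing and only returns results.
#' @param cfg a [network_config()].
#' @param loocv_mode `"none"`, `"global"`, `"novel_lncrna"` or
#'   `"novel_disease"`.
#' @param reuse_similarities passed to the cross-validation drivers.
#' @param novel_only drop known associations from the ranked predictions.
#' @param verbose print per-stage progress with entity/edge/fold counts.
#' @return List with `data`, `similarities`, `network`, `scores` (matrix),
#'   `predictions` (ranked data.frame), and `loocv` (a `loocv_result` or
#'   `NULL`), invisibly.
#' @export
run_pipeline <- function(associations, ss, out_dir = NULL,
                         cfg = network_config(),
                         loocv_mode = c("none", "global", "novel_lncrna",
                                        "novel_disease"),
                         reuse_similarities = FALSE, novel_only = FALSE,
                         verbose = TRUE) {
  loocv_mode <- match.arg(loocv_mode)
  say <- function(...) if (verbose) message(sprintf(...))

  data <- if (inherits(associations, "association_dataset")) associations
          else read_associations(associations)
  SS <- if (inherits(ss, "similarity_matrix")) ss else read_similarity(ss)
  say("loaded %d lncRNAs, %d diseases, %d associations",
      length(data$lncrna_names), length(data$disease_names), sum(data$LD))
  say("parameters: T=%g tau=%d alpha=%g decay=%s",
      cfg$T, cfg$tau, cfg$alpha, cfg$decay_form)

  sims <- compute_similarities(data, SS)
  say("similarities: |NS|=%d |NF|=%d", length(sims$NS), length(sims$NF))
  net <- build_network(data, sims$DS, sims$LS, cfg)
  say("network: %d edges", nrow(network_edges(net)))

  scores <- score_all(net, data, cfg)
  preds <- data.frame(
    lncrna = rep(data$lncrna_names, times = ncol(scores)),
    disease = rep(data$disease_names, each = nrow(scores)),
    score = as.vector(scores),
    known = as.vector(data$LD) == 1,
    stringsAsFactors = FALSE
  )
  preds <- preds[order(-preds$score, preds$lncrna, preds$disease), ]
  rownames(preds) <- NULL
  if (novel_only) preds <- preds[!preds$known, ]

  loocv <- NULL
  if (loocv_mode != "none") {
    loocv <- if (loocv_mode == "global")
      global_loocv(data, SS, cfg, reuse_similarities = reuse_similarities)
    else
      local_loocv(data, SS, cfg, mode = loocv_mode,
                  reuse_similarities = reuse_similarities)
    say("%s LOOCV over %d folds: AUC = %.5f", loocv_mode,
        if (loocv_mode == "global") nrow(loocv$per_fold)
        else length(unique(loocv$per_fold$entity)), loocv$auc)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out_preds <- preds
    out_preds$score <- signif(out_preds$score, 6)
    write.table(out_preds, file.path(out_dir, "predictions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(lncrna = rownames(scores), signif(scores, 6),
                           check.names = FALSE),
                file.path(out_dir, "score_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(loocv)) {
      write.table(loocv$per_fold, file.path(out_dir, "loocv_folds.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(loocv$roc_points, file.path(out_dir, "roc_points.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(sprintf("mode=%s\nauc=%.6f", loocv$mode, loocv$auc),
                 file.path(out_dir, "loocv_summary.txt"))
    }
    say("wrote outputs to %s", out_dir)
  }
  invisible(list(data = data, similarities = sims, network = net,
                 scores = scores, predictions = preds, loocv = loocv))
}
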