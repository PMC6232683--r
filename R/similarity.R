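#' Semantic similarity between a disease and a disease group
#'
#' The best-match rule used when lifting disease-disease semantic similarity
#' to lncRNA functional similarity: the similarity of disease `d` to a
#' non-empty group `D` is the maximum pairwise similarity over the group
#' (the `"mean"` aggregation averages instead; see [functional_similarity()]).
#'
#' @param d disease index (into `SS$names`).
#' @param D non-empty vector of disease indices.
#' @param SS disease semantic-similarity [similarity_matrix()].
#' @param agg `"max"` (default) or `"mean"`.
#' @return A number in `[0, 1]`.
#' @export
group_similarity <- function(d, D, SS, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  stopifnot(inherits(SS, "similarity_matrix"))
  if (length(D) == 0L) stop("disease group D must be non-empty")
  n <- length(SS$names)
  if (d < 1 || d > n || any(D < 1 | D > n)) stop("disease index out of range")
  v <- SS$values[d, D]
  if (agg == "max") max(v) else mean(v)
}

#' lncRNA functional similarity from associated-disease sets
#'
#' Two lncRNAs are functionally similar to the extent that their
#' associated-disease sets are semantically similar. With disease sets
#' `D_i` (size m) and `D_j` (size n),
#' `FS(i,j) = (sum_k SIM(d_ik, D_j) + sum_l SIM(d_jl, D_i)) / (m + n)`,
#' where `SIM` is the best-match [group_similarity()]. The diagonal is 1.
#' An lncRNA with no associated disease (possible inside a cross-validation
#' fold) gets an all-zero off-diagonal row, which later routes it to the
#' Gaussian-kernel fallback.
#'
#' @param data an [association_dataset()].
#' @param SS disease semantic similarity; must contain every disease of
#'   `data` (matched by normalized name).
#' @param agg group aggregation, `"max"` (default) or `"mean"`.
#' @return A [similarity_matrix()] over `data$lncrna_names` (role FS).
#' @export
functional_similarity <- function(data, SS, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  stopifnot(inherits(data, "association_dataset"))
  SS <- align_similarity(SS, data$disease_names, what = "disease")
  nl <- length(data$lncrna_names)
  nd <- length(data$disease_names)
  sets <- lapply(seq_len(nl), function(i) which(data$LD[i, ] == 1))

  # grp[j, d] = SIM(d, D_j): best-match (or mean) similarity of disease d to
  # lncRNA j's disease set; 0 for empty sets.
  grp <- matrix(0, nl, nd)
  for (j in seq_len(nl)) {
    Dj <- sets[[j]]
    if (length(Dj)) {
      sub <- SS$values[, Dj, drop = FALSE]
      grp[j, ] <- if (agg == "max") apply(sub, 1, max) else rowMeans(sub)
    }
  }

  FS <- diag(1, nl)
  if (nl >= 2) {
    for (i in seq_len(nl - 1L)) {
      Di <- sets[[i]]
      for (j in (i + 1L):nl) {
        Dj <- sets[[j]]
        mn <- length(Di) + length(Dj)
        FS[i, j] <- FS[j, i] <-
          if (mn == 0) 0 else (sum(grp[j, Di]) + sum(grp[i, Dj])) / mn
      }
    }
  }
  similarity_matrix(FS, data$lncrna_names)
}

#' Gaussian interaction-profile kernel similarity
#'
#' Similarity between binary interaction profiles (rows of the association
#' matrix for lncRNAs, columns for diseases):
#' `K(i,j) = exp(-gamma * ||IP_i - IP_j||^2)` with bandwidth
#' `gamma = gamma_prime / mean_i ||IP_i||^2`. The mean runs over all
#' profiles of the class, all-zero rows included, so the bandwidth reflects
#' the overall density of the association matrix.
#'
#' @param profiles numeric matrix, one profile per row.
#' @param gamma_prime bandwidth scale, conventionally 1.
#' @param names optional row labels for the result.
#' @return A [similarity_matrix()] with unit diagonal (role GL or GD).
#' @export
gaussian_kernel <- function(profiles, gamma_prime = 1,
                            names = rownames(profiles)) {
  profiles <- as.matrix(profiles)
  if (is.null(names)) names <- paste0("p", seq_len(nrow(profiles)))
  nrm2 <- rowSums(profiles^2)
  mean_nrm2 <- mean(nrm2)
  if (mean_nrm2 == 0) stop("bandwidth undefined: all interaction profiles are zero")
  gamma <- gamma_prime / mean_nrm2
  d2 <- outer(nrm2, nrm2, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0                       # numerical guard
  K <- exp(-gamma * d2)
  diag(K) <- 1
  similarity_matrix(K, names)
}

#' Kernel bandwidth parameters for a dataset
#'
#' Derived bandwidths for the lncRNA and disease interaction-profile kernels:
#' `gamma = gamma_prime / mean ||IP||^2`, with the mean over rows (lncRNAs)
#' or columns (diseases) of `LD`.
#'
#' @param data an [association_dataset()].
#' @param gamma_prime_l,gamma_prime_d bandwidth scales (default 1).
#' @return List with `gamma_prime_l`, `gamma_prime_d`, `gamma_l`, `gamma_d`.
#' @export
kernel_params <- function(data, gamma_prime_l = 1, gamma_prime_d = 1) {
  stopifnot(inherits(data, "association_dataset"))
  ml <- mean(rowSums(data$LD^2))
  md <- mean(colSums(data$LD^2))
  if (ml == 0 || md == 0) stop("bandwidth undefined: no associations")
  list(gamma_prime_l = gamma_prime_l, gamma_prime_d = gamma_prime_d,
       gamma_l = gamma_prime_l / ml, gamma_d = gamma_prime_d / md)
}

#' Entities lacking any similarity to the rest of their class
#'
#' `NS` is the set of diseases whose semantic-similarity row is zero
#' everywhere off the diagonal; `NF` the analogous set of lncRNAs under
#' functional similarity. These are the entities routed to the Gaussian
#' kernel by [integrate_similarity()].
#'
#' @param SS disease semantic similarity.
#' @param FS lncRNA functional similarity.
#' @return List with integer index vectors `NS` and `NF`.
#' @export
fallback_sets <- function(SS, FS) {
  iso <- function(sim) {
    v <- sim$values
    diag(v) <- 0
    which(rowSums(v > 0) == 0)
  }
  list(NS = unname(iso(SS)), NF = unname(iso(FS)))
}

#' Integrate a primary similarity with a kernel fallback
#'
#' Entry `(i, j)` is taken from `kernel` when either index belongs to the
#' fallback set, and from `primary` otherwise. With an empty fallback set the
#' result equals `primary`; with all indices in it, `kernel`.
#'
#' @param primary,kernel [similarity_matrix()] objects over the same names.
#' @param fallback integer indices of entities with no primary similarity.
#' @return A [similarity_matrix()] (role DS or LS).
#' @export
integrate_similarity <- function(primary, kernel, fallback) {
  stopifnot(inherits(primary, "similarity_matrix"),
            inherits(kernel, "similarity_matrix"))
  n <- length(primary$names)
  if (length(kernel$names) != n)
    stop("primary and kernel similarity dimensions differ")
  in_fb <- seq_len(n) %in% fallback
  mask <- outer(in_fb, in_fb, "|")
  v <- primary$values
  v[mask] <- kernel$values[mask]
  similarity_matrix(v, primary$names)
}

#' Compute every similarity the pipeline needs from one dataset
#'
#' Convenience wrapper running functional similarity, both Gaussian kernels,
#' the fallback-set scan and the integration in one go; this is what each
#' cross-validation fold recomputes from its training association matrix.
#' Setting `use_gl`/`use_gd` to `FALSE` skips the corresponding fallback so
#' `LS = FS` / `DS = SS` (used by [kernel_ablation()]).
#'
#' @param data an [association_dataset()].
#' @param SS disease semantic similarity covering `data`'s diseases.
#' @param gamma_prime_l,gamma_prime_d kernel bandwidth scales.
#' @param use_gl,use_gd whether to substitute the lncRNA/disease kernel for
#'   entities lacking functional/semantic similarity.
#' @param agg group aggregation for [functional_similarity()].
#' @return List with elements `SS`, `FS`, `GL`, `GD`, `DS`, `LS`, `NS`, `NF`,
#'   `params`.
#' @export
compute_similarities <- function(data, SS, gamma_prime_l = 1,
                                 gamma_prime_d = 1, use_gl = TRUE,
                                 use_gd = TRUE, agg = "max") {
  SS <- align_similarity(SS, data$disease_names, what = "disease")
  FS <- functional_similarity(data, SS, agg = agg)
  GL <- gaussian_kernel(data$LD, gamma_prime_l, names = data$lncrna_names)
  GD <- gaussian_kernel(t(data$LD), gamma_prime_d, names = data$disease_names)
  fb <- fallback_sets(SS, FS)
  DS <- if (use_gd) integrate_similarity(SS, GD, fb$NS) else SS
  LS <- if (use_gl) integrate_similarity(FS, GL, fb$NF) else FS
  list(SS = SS, FS = FS, GL = GL, GD = GD, DS = DS, LS = LS,
       NS = fb$NS, NF = fb$NF,
       params = kernel_params(data, gamma_prime_l, gamma_prime_d))
}
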