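#' Construct an association dataset
#'
#' Bundles ordered lncRNA and disease name lists with the binary association
#' matrix `LD` (rows = lncRNAs, columns = diseases). `LD[i, j] = 1` records an
#' experimentally confirmed association between lncRNA `i` and disease `j`.
#'
#' @param lncrna_names character vector of unique lncRNA names.
#' @param disease_names character vector of unique disease names.
#' @param LD binary matrix with `length(lncrna_names)` rows and
#'   `length(disease_names)` columns.
#' @return An object of class `association_dataset` with elements
#'   `lncrna_names`, `disease_names` and `LD` (dimnames set to the names).
#' @export
association_dataset <- function(lncrna_names, disease_names, LD) {
  lncrna_names <- as.character(lncrna_names)
  disease_names <- as.character(disease_names)
  if (anyDuplicated(normalize_name(lncrna_names)))
    stop("duplicate lncRNA names after normalization")
  if (anyDuplicated(normalize_name(disease_names)))
    stop("duplicate disease names after normalization")
  LD <- as.matrix(LD)
  if (!all(dim(LD) == c(length(lncrna_names), length(disease_names))))
    stop("LD dimensions do not match the name lists")
  if (!all(LD %in% c(0, 1)))
    stop("LD must be binary (0/1)")
  storage.mode(LD) <- "double"
  dimnames(LD) <- list(lncrna_names, disease_names)
  structure(
    list(lncrna_names = lncrna_names, disease_names = disease_names, LD = LD),
    class = "association_dataset"
  )
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf(
    "<association_dataset> %d lncRNAs x %d diseases, %d associations\n",
    length(x$lncrna_names), length(x$disease_names), sum(x$LD)
  ))
  invisible(x)
}

#' Read an lncRNA-disease association table
#'
#' Reads a two-column tab-separated file (lncRNA name, disease name), one
#' association per line. Lines starting with `#` and blank lines are ignored.
#' Duplicate pairs (after whitespace/case normalization) are collapsed to a
#' single association; name order follows first appearance in the file.
#'
#' @param path path to a UTF-8 TSV file.
#' @return An [association_dataset()].
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty association file: ", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(parts, function(p) sum(nzchar(trimws(p))) < 2L, logical(1)))
  if (length(bad))
    stop(sprintf("malformed association line %d: %s",
                 idx[bad[1]], lines[idx[bad[1]]]))
  lnc_raw <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  dis_raw <- vapply(parts, function(p) trimws(p[[2]]), character(1))
  lnc_key <- normalize_name(lnc_raw)
  dis_key <- normalize_name(dis_raw)

  # first-appearance order, first-seen spelling preserved
  lnc_names <- lnc_raw[!duplicated(lnc_key)]
  dis_names <- dis_raw[!duplicated(dis_key)]
  i <- match(lnc_key, normalize_name(lnc_names))
  j <- match(dis_key, normalize_name(dis_names))
  LD <- matrix(0, length(lnc_names), length(dis_names))
  LD[cbind(i, j)] <- 1
  association_dataset(lnc_names, dis_names, LD)
}

#' Write an association dataset back to a two-column TSV
#'
#' Pairs are written in row-major order of the dataset's name lists, so
#' reading the file back reproduces the same names and `LD` matrix.
#'
#' @param data an [association_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(data, path) {
  stopifnot(inherits(data, "association_dataset"))
  idx <- which(t(data$LD) == 1)          # row-major over LD
  j <- (idx - 1L) %% ncol(data$LD) + 1L
  i <- (idx - 1L) %/% ncol(data$LD) + 1L
  writeLines(paste(data$lncrna_names[i], data$disease_names[j], sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Construct a labeled symmetric similarity matrix
#'
#' Container for the similarity roles used throughout the pipeline: disease
#' semantic similarity (SS), lncRNA functional similarity (FS), the Gaussian
#' interaction-profile kernels (GL, GD) and the integrated similarities
#' (DS, LS). Entries must lie in `[0, 1]`; symmetry is enforced to within
#' `tol` and the matrix is exactly symmetrized by averaging mirrored entries.
#'
#' @param values square numeric matrix.
#' @param names character vector of row/column labels.
#' @param tol symmetry and range tolerance (default `1e-9`).
#' @return An object of class `similarity_matrix` with elements `names` and
#'   `values`.
#' @export
similarity_matrix <- function(values, names = rownames(values), tol = 1e-9) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (is.null(names)) stop("similarity matrix requires names")
  names <- as.character(names)
  if (length(names) != nrow(values)) stop("label length does not match matrix")
  if (anyDuplicated(normalize_name(names))) stop("duplicate labels")
  asym <- max(abs(values - t(values)), 0)
  if (asym > tol)
    stop(sprintf("matrix asymmetric beyond tolerance (max |v(i,j)-v(j,i)| = %g)", asym))
  values <- (values + t(values)) / 2
  lo <- min(values); hi <- max(values)
  if (lo < -tol || hi > 1 + tol)
    stop(sprintf("values outside [0, 1]: range [%g, %g]", lo, hi))
  values[values < 0] <- 0
  values[values > 1] <- 1
  dimnames(values) <- list(names, names)
  structure(list(names = names, values = values), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, zero fraction %.3f\n",
              length(x$names), length(x$names), zero_fraction(x)))
  invisible(x)
}

#' Read a labeled similarity matrix from TSV
#'
#' Expects a tab-separated table whose first row holds column labels and first
#' column holds row labels (identical up to order-preserving match). Used for
#' the externally computed disease semantic-similarity matrix.
#'
#' @inheritParams read_associations
#' @param tol symmetry/range tolerance passed to [similarity_matrix()].
#' @return A [similarity_matrix()].
#' @export
read_similarity <- function(path, tol = 1e-9) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, row.names = 1,
                   fileEncoding = "UTF-8")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("similarity matrix contains non-numeric values")
  if (!identical(normalize_name(rownames(m)), normalize_name(colnames(m))))
    stop("row and column labels do not match")
  similarity_matrix(m, rownames(m), tol = tol)
}

#' Write a labeled similarity matrix to TSV
#'
#' @param sim a [similarity_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  df <- data.frame(name = sim$names, sim$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary statistics of an association dataset
#'
#' Degree statistics of the bipartite association graph: entity counts,
#' association count, average and maximum degrees per side, and the minimum
#' degree over both sides. Average degrees are reported rounded to one
#' decimal, the convention used when characterizing curated association sets.
#'
#' @param data an [association_dataset()].
#' @return A list of class `dataset_stats` with fields `n_lncrnas`,
#'   `n_diseases`, `n_associations`, `avg_deg_lncrna`, `avg_deg_disease`,
#'   `max_deg_lncrna`, `max_deg_disease`, `min_deg`.
#' @export
dataset_stats <- function(data) {
  stopifnot(inherits(data, "association_dataset"))
  deg_l <- rowSums(data$LD)
  deg_d <- colSums(data$LD)
  n_assoc <- sum(data$LD)
  if (n_assoc == 0) {
    warning("dataset has no associations; statistics are all zero")
    return(structure(list(
      n_lncrnas = length(deg_l), n_diseases = length(deg_d),
      n_associations = 0L, avg_deg_lncrna = 0, avg_deg_disease = 0,
      max_deg_lncrna = 0L, max_deg_disease = 0L, min_deg = 0L
    ), class = "dataset_stats"))
  }
  structure(list(
    n_lncrnas = length(deg_l),
    n_diseases = length(deg_d),
    n_associations = as.integer(n_assoc),
    avg_deg_lncrna = round(n_assoc / length(deg_l), 1),
    avg_deg_disease = round(n_assoc / length(deg_d), 1),
    max_deg_lncrna = as.integer(max(deg_l)),
    max_deg_disease = as.integer(max(deg_d)),
    min_deg = as.integer(min(c(deg_l, deg_d)))
  ), class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  for (k in names(unclass(x))) cat(sprintf("%s=%s\n", k, format(x[[k]])))
  invisible(x)
}

#' Fraction of exactly-zero entries in a similarity matrix
#'
#' Counted over all `n^2` entries including the diagonal, the denominator
#' used when describing sparsity of semantic-similarity matrices.
#'
#' @param sim a [similarity_matrix()].
#' @return A number in `[0, 1]`.
#' @export
zero_fraction <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  mean(sim$values == 0)
}

# Reorder/subset a similarity matrix to a given name vector (normalized
# matching); errors naming the first label that is absent.
align_similarity <- function(sim, names, what = "entity") {
  stopifnot(inherits(sim, "similarity_matrix"))
  pos <- match(normalize_name(names), normalize_name(sim$names))
  if (anyNA(pos))
    stop(sprintf("%s '%s' not present in similarity matrix",
                 what, names[which(is.na(pos))[1]]))
  similarity_matrix(sim$values[pos, pos, drop = FALSE], names)
}
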