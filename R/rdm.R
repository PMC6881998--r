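#' Representational dissimilarity matrices
#'
#' An `rdm` is a labelled, square, symmetric dissimilarity matrix with a zero
#' diagonal: the central currency of the analysis. Neural RDMs hold
#' correlation distances (`1 - r`, range \[0, 2\]) between the multi-voxel
#' response patterns evoked by pairs of stimuli; model RDMs hold candidate
#' dissimilarity structures (binary category models, affect distances,
#' feature differences) that the regression stage weighs against each other.
#'
#' @param values square numeric matrix of dissimilarities
#' @param labels character vector of stimulus ids, one per row/column
#' @param kind `"neural"` or `"model"`
#' @param source free-text provenance (subject/ROI for neural RDMs, model
#'   name for model RDMs)
#'
#' @return an object of class `rdm`: a list with elements `values`
#'   (labelled matrix), `labels`, `kind` and `source`.
#' @export
rdm <- function(values, labels = rownames(values), kind = c("model", "neural"),
                source = "") {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("RDM values must be a square matrix")
  }
  if (is.null(labels)) {
    labels <- paste0("s", seq_len(nrow(values)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("labels length (", length(labels), ") does not match RDM dimension (",
         nrow(values), ")")
  }
  if (anyDuplicated(labels)) {
    stop("RDM labels must be unique")
  }
  if (any(!is.finite(values))) {
    stop("RDM contains non-finite entries")
  }
  if (max(abs(values - t(values))) > 1e-8) {
    stop("RDM is not symmetric within tolerance")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, kind = kind,
                 source = source),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("%s RDM (%d x %d)%s\n", x$kind, n, n,
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  ut <- upper_tri_vec(x$values)
  cat(sprintf("  dissimilarity range: %.4g .. %.4g (mean %.4g)\n",
              min(ut), max(ut), mean(ut)))
  invisible(x)
}

#' @export
dim.rdm <- function(x) dim(x$values)

#' Test for the rdm class
#' @param x object
#' @return logical scalar
#' @export
is_rdm <- function(x) inherits(x, "rdm")

#' Voxel-pattern container for one subject and ROI
#'
#' Wraps a stimulus-by-voxel response matrix extracted from one region of
#' interest of one subject, with the stimulus order aligned to a design
#' table. Rows are stimuli (named by stimulus id), columns are voxels.
#'
#' @param matrix numeric stimulus x voxel matrix with stimulus ids as
#'   rownames
#' @param subject_id,group,roi provenance strings; `group` is typically
#'   `"NT"` or `"ASD"`
#' @return object of class `pattern_set`
#' @export
pattern_set <- function(matrix, subject_id, group, roi) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) < 2) {
    stop("pattern matrix needs at least 2 voxels (pairwise correlation is ",
         "undefined otherwise)")
  }
  if (is.null(rownames(matrix))) {
    stop("pattern matrix must carry stimulus ids as rownames")
  }
  if (any(!is.finite(matrix))) {
    stop("pattern matrix contains non-finite entries")
  }
  structure(list(matrix = matrix, subject_id = as.character(subject_id),
                 group = as.character(group), roi = as.character(roi)),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: subject %s (%s), ROI %s, %d stimuli x %d voxels\n",
              x$subject_id, x$group, x$roi, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Neural RDM from a voxel-pattern matrix
#'
#' Computes the pairwise correlation distance between the voxel patterns of
#' every stimulus pair: entry (i, j) is `1 - r(pattern_i, pattern_j)` with
#' Pearson's r across voxels (or `-r` if `dissim = "neg_r"`). The diagonal
#' is zero by construction.
#'
#' @param patterns a [pattern_set()] (or a bare stimulus x voxel matrix with
#'   rownames)
#' @param dissim dissimilarity transform of the correlation coefficient:
#'   `"one_minus_r"` (default, range \[0, 2\]) or `"neg_r"`
#' @return a neural [rdm()]
#' @export
neural_rdm <- function(patterns, dissim = c("one_minus_r", "neg_r")) {
  dissim <- match.arg(dissim)
  if (inherits(patterns, "pattern_set")) {
    m <- patterns$matrix
    src <- paste0(patterns$subject_id, "/", patterns$roi)
  } else {
    m <- as.matrix(patterns)
    src <- "patterns"
  }
  if (ncol(m) < 2) stop("need at least 2 voxels")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(m)[sds == 0]
    stop("constant voxel pattern for stimulus: ", paste(bad, collapse = ", "),
         " (correlation undefined)")
  }
  r <- stats::cor(t(m))
  d <- if (dissim == "one_minus_r") 1 - r else -r
  diag(d) <- 0
  rdm(d, labels = rownames(m), kind = "neural", source = src)
}

#' Binary category model RDM
#'
#' Dissimilarity 0 for stimulus pairs in the same class, 1 for pairs in
#' different classes. The default partition is social versus non-social
#' touch.
#'
#' @param design a stimulus design table (see [make_design()])
#' @param partition either a logical/character/factor vector over stimuli,
#'   or a function mapping the design to one; defaults to the social vs.
#'   non-social split of the `category` column
#' @param name model name recorded in the RDM metadata
#' @return a model [rdm()]
#' @export
model_rdm_binary <- function(design, partition = NULL, name = "social") {
  if (is.null(partition)) {
    partition <- design$category %in% c("social_positive", "social_negative")
  } else if (is.function(partition)) {
    partition <- partition(design)
  }
  if (length(partition) != nrow(design)) {
    stop("partition must cover every stimulus in the design")
  }
  if (anyNA(partition)) stop("partition undefined for some stimuli")
  cls <- as.integer(factor(partition))
  d <- outer(cls, cls, FUN = function(a, b) as.numeric(a != b))
  rdm(d, labels = design$stimulus_id, kind = "model", source = name)
}

#' Feature-based model RDM
#'
#' Pairwise dissimilarity on one named design column. Numeric features use
#' the absolute difference (or Euclidean distance over several columns);
#' categorical features use the binary same/different metric.
#'
#' @param design stimulus design table
#' @param feature column name(s) in `design`
#' @param metric `"abs_diff"` (default; Euclidean when several numeric
#'   columns are given) or `"binary"` for categorical labels
#' @return a model [rdm()]
#' @export
model_rdm_features <- function(design, feature,
                               metric = c("abs_diff", "binary")) {
  metric <- match.arg(metric)
  missing_cols <- setdiff(feature, names(design))
  if (length(missing_cols)) {
    stop("unknown feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  vals <- design[, feature, drop = FALSE]
  if (metric == "binary" || !all(vapply(vals, is.numeric, logical(1)))) {
    if (length(feature) != 1) stop("binary metric takes a single column")
    cls <- as.integer(factor(vals[[1]]))
    d <- outer(cls, cls, FUN = function(a, b) as.numeric(a != b))
  } else {
    d <- as.matrix(stats::dist(as.matrix(vals), method = "euclidean"))
  }
  rdm(d, labels = design$stimulus_id, kind = "model",
      source = paste(feature, collapse = "+"))
}

#' Restrict an RDM to a subset of stimuli
#'
#' Drops rows and columns outside `keep`, preserving the original stimulus
#' order. Used to carve the social-touch RDM (39 stimuli by default) out of
#' the general-touch RDM (75 stimuli).
#'
#' @param x an [rdm()]
#' @param keep character vector of stimulus ids to retain
#' @return an [rdm()] over the retained stimuli
#' @export
subset_rdm <- function(x, keep) {
  stopifnot(is_rdm(x))
  keep <- as.character(keep)
  unknown <- setdiff(keep, x$labels)
  if (length(unknown)) {
    stop("unknown stimulus id(s): ", paste(unknown, collapse = ", "))
  }
  sel <- x$labels[x$labels %in% keep]   # preserve original order
  rdm(x$values[sel, sel, drop = FALSE], labels = sel, kind = x$kind,
      source = x$source)
}

#' Element-wise average of RDMs
#'
#' All RDMs must share the same labels in the same order. Averaging
#' individual-subject neural RDMs yields the group RDM that the
#' group-level regression models.
#'
#' @param rdms list of [rdm()] objects
#' @return an [rdm()] holding the element-wise mean
#' @export
average_rdms <- function(rdms) {
  if (!length(rdms)) stop("empty RDM list")
  stopifnot(all(vapply(rdms, is_rdm, logical(1))))
  ref <- rdms[[1]]$labels
  for (r in rdms) {
    if (!identical(r$labels, ref)) {
      stop("RDM label mismatch: all RDMs must share the same stimulus order")
    }
  }
  acc <- Reduce(`+`, lapply(rdms, `[[`, "values")) / length(rdms)
  rdm(acc, labels = ref, kind = rdms[[1]]$kind,
      source = sprintf("mean of %d RDMs", length(rdms)))
}

#' Row-major upper triangle of a square matrix
#'
#' Extracts entries (i, j) with i < j in row-major order:
#' (1,2), (1,3), ..., (1,n), (2,3), ... This ordering is fixed across the
#' package so that permutation indices and regression rows always align.
#'
#' @param m square matrix
#' @return numeric vector of length n(n-1)/2
#' @export
upper_tri_vec <- function(m) {
  m <- as.matrix(m)
  t(m)[lower.tri(m)]
}

#' Vectorize and z-score an RDM
#'
#' Takes the row-major upper triangle (diagonal excluded) and standardises
#' it to mean 0 and unit sample standard deviation (n - 1 denominator).
#' These vectors are the dependent and independent variables of the RSA
#' regression.
#'
#' @param x an [rdm()] or a bare square matrix
#' @return numeric vector of length n(n-1)/2 with mean 0 and SD 1
#' @export
vectorize_z <- function(x) {
  m <- if (is_rdm(x)) x$values else as.matrix(x)
  if (nrow(m) < 3) stop("need an RDM of at least 3 stimuli to z-score")
  v <- upper_tri_vec(m)
  s <- stats::sd(v)
  if (s == 0) stop("zero-variance upper triangle: cannot z-score")
  (v - mean(v)) / s
}
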