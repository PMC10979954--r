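#' Fisher z transform and its inverse
#'
#' `fisher_z` maps correlations to z-space via arctanh; `inv_fisher_z` maps
#' back via tanh. Correlations of exactly +/-1 (possible with duplicated
#' ROIs) are clipped to +/-(1 - 1e-10) before the transform.
#'
#' @param r correlation value(s) in [-1, 1].
#' @param z z-space value(s).
#' @return Numeric vector/matrix of the same shape.
#' @examples
#' fisher_z(0.5)          # 0.5493
#' inv_fisher_z(fisher_z(-0.3))
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1")
  r <- pmin(pmax(r, -(1 - 1e-10)), 1 - 1e-10)
  atanh(r)
}

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Aggregate a connectivity matrix to anatomical systems
#'
#' Entry (A, B) is the z-space mean of all ROI-pair correlations between
#' systems A and B, back-transformed to r-space. Diagonal (intra-system)
#' blocks average over unordered distinct ROI pairs, excluding self-pairs.
#'
#' @param matrix a [conn_matrix()].
#' @param systems named list mapping system name to ROI names (see
#'   [system_definition()]); systems must be disjoint and all ROIs present.
#' @return A [conn_matrix()] over systems. Intra-system entries for
#'   singleton systems are undefined: set to NA with a warning.
#' @export
aggregate_system <- function(matrix, systems) {
  stopifnot(inherits(matrix, "conn_matrix"), is.list(systems))
  all_rois <- unlist(systems, use.names = FALSE)
  if (anyDuplicated(all_rois)) stop("systems must be disjoint")
  missing <- setdiff(all_rois, matrix$roi_names)
  if (length(missing))
    stop("ROIs not in matrix: ", paste(missing, collapse = ", "))
  ns <- length(systems)
  out <- diag(1, ns)
  nm <- names(systems)
  for (a in seq_len(ns)) for (b in a:ns) {
    ia <- match(systems[[a]], matrix$roi_names)
    ib <- match(systems[[b]], matrix$roi_names)
    if (a == b) {
      if (length(ia) < 2) {
        warning(sprintf("system '%s' has < 2 ROIs; intra-system value undefined",
                        nm[a]))
        out[a, a] <- NA_real_
        next
      }
      block <- matrix$r[ia, ia, drop = FALSE]
      vals <- block[upper.tri(block)]
    } else {
      vals <- as.vector(matrix$r[ia, ib, drop = FALSE])
    }
    m <- inv_fisher_z(mean(fisher_z(vals), na.rm = TRUE))
    out[a, b] <- out[b, a] <- m
  }
  conn_matrix(out, nm, metadata = c(matrix$metadata, list(level = "system")))
}

#' Group mean of connectivity matrices
#'
#' Entrywise Fisher-z mean across scans, back-transformed to r-space.
#'
#' @param matrices list of [conn_matrix()] sharing one ROI set.
#' @param group optional group label stored in metadata.
#' @return A [conn_matrix()] with metadata `group` and `n`.
#' @export
group_mean_matrix <- function(matrices, group = NA_character_) {
  if (length(matrices) == 0) stop("empty collection")
  rois <- matrices[[1]]$roi_names
  zs <- lapply(matrices, function(m) {
    if (!identical(m$roi_names, rois)) stop("matrices must share one ROI set")
    fisher_z(m$r)
  })
  zbar <- Reduce(`+`, zs) / length(zs)
  r <- inv_fisher_z(zbar)
  diag(r) <- 1
  conn_matrix(r, rois, metadata = list(group = group, n = length(matrices)))
}

#' Difference matrix in z units
#'
#' Entrywise `arctanh(A) - arctanh(B)` (e.g. 5xFAD minus WT group means),
#' reported in Fisher-z units.
#'
#' @param groupA_mean,groupB_mean [conn_matrix()] objects on one ROI set.
#' @return Signed numeric matrix (z units) with ROI dimnames.
#' @export
difference_matrix <- function(groupA_mean, groupB_mean) {
  stopifnot(inherits(groupA_mean, "conn_matrix"),
            inherits(groupB_mean, "conn_matrix"))
  if (!identical(groupA_mean$roi_names, groupB_mean$roi_names))
    stop("ROI sets differ")
  d <- fisher_z(groupA_mean$r) - fisher_z(groupB_mean$r)
  diag(d) <- 0
  d
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values for a vector of p-values (family: all edges or system
#' pairs within one timepoint's comparison).
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values, same length.
#' @export
fdr_correct <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Binary significance mask
#'
#' @param p numeric vector or symmetric matrix of p-values.
#' @param alpha significance threshold.
#' @return Logical mask, `p < alpha` (symmetric if `p` is a matrix).
#' @export
binarize <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p < alpha
}
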