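#' Connectivity matrix container
#'
#' A symmetric ROI x ROI Pearson correlation matrix with ROI names and scan
#' metadata. Degenerate (zero-variance) ROIs may carry NA in their rows and
#' columns; otherwise entries lie in [-1, 1] with unit diagonal.
#'
#' @param r symmetric numeric matrix.
#' @param roi_names ROI labels; default taken from dimnames.
#' @param metadata named list (subject, genotype, age_months, scan_id, ...).
#' @return A `conn_matrix` object.
#' @export
conn_matrix <- function(r, roi_names = rownames(r), metadata = list()) {
  r <- as.matrix(r)
  if (is.null(roi_names)) roi_names <- sprintf("ROI%02d", seq_len(nrow(r)))
  stopifnot(nrow(r) == ncol(r), length(roi_names) == nrow(r))
  if (anyDuplicated(roi_names)) stop("roi_names must be unique")
  ok <- !is.na(r)
  if (max(abs(r[ok])) > 1 + 1e-8) stop("correlations must lie in [-1, 1]")
  if (max(abs(r - t(r)), na.rm = TRUE) > 1e-8) stop("matrix must be symmetric")
  r <- (r + t(r)) / 2
  dimnames(r) <- list(roi_names, roi_names)
  structure(list(r = r, roi_names = as.character(roi_names),
                 metadata = metadata),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("Connectivity matrix: %d ROIs; off-diagonal r in [%.3f, %.3f]%s\n",
              nrow(x$r), suppressWarnings(min(off, na.rm = TRUE)),
              suppressWarnings(max(off, na.rm = TRUE)),
              if (anyNA(off)) sprintf(" (%d NA)", sum(is.na(off))) else ""))
  md <- x$metadata
  if (length(md))
    cat("  ", paste(names(md), unlist(lapply(md, format)), sep = "=",
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Small fixture graphs with known metric values
#'
#' Fixed connectivity matrices used as oracles for the graph-metric code:
#' `triangle_unit` (3 nodes, all off-diagonal 1), `star5` (hub connected to
#' 4 leaves with weight 0.5), `path4` (4-node path, unit weights), and
#' `random5_seeded` (5 x 5 symmetric weights in (0, 1), fixed seed).
#'
#' @param name one of "triangle_unit", "star5", "path4", "random5_seeded".
#' @return A [conn_matrix()].
#' @examples
#' gen_toy_graph("star5")
#' @export
gen_toy_graph <- function(name = c("triangle_unit", "star5", "path4",
                                   "random5_seeded")) {
  name <- match.arg(name)
  r <- switch(name,
    triangle_unit = {
      m <- matrix(1, 3, 3)
      m
    },
    star5 = {
      m <- diag(5)
      m[1, 2:5] <- m[2:5, 1] <- 0.5
      m
    },
    path4 = {
      m <- diag(4)
      for (i in 1:3) m[i, i + 1] <- m[i + 1, i] <- 1
      m
    },
    random5_seeded = with_seed(20240317L, {
      m <- diag(5)
      v <- runif(10, 0.05, 0.95)
      m[upper.tri(m)] <- v
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    })
  )
  diag(r) <- 1
  conn_matrix(r, sprintf("N%d", seq_len(nrow(r))),
              metadata = list(fixture = name))
}
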