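#' Read and write pipeline artifacts
#'
#' Plain-text interchange used by the pipeline and its command-line
#' wrapper: scans as TSV matrices (ROIs x time, header row of ROI names)
#' with a manifest CSV; connectivity matrices as TSV with an ROI-name
#' header plus a JSON metadata sidecar; system definitions as JSON
#' `{system: [roi, ...]}`; cytokine panels as long-format CSV.
#'
#' @param scans list of [scan_ts()] (with `manifest` attribute) as from
#'   [gen_scan_set()].
#' @param dir output directory (created if needed).
#' @name cytonet-io
NULL

#' @rdname cytonet-io
#' @export
write_scan_set <- function(scans, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- attr(scans, "manifest")
  for (s in scans) {
    f <- file.path(dir, paste0(s$scan_id, ".tsv"))
    m <- t(s$data)           # time x ROI, header = ROI names
    write.table(format(m, digits = 17, trim = TRUE), f, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = s$roi_names)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname cytonet-io
#' @export
read_scan_set <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  scans <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- as.matrix(read.delim(file.path(dir, paste0(manifest$scan_id[i],
                                                    ".tsv")),
                              check.names = FALSE))
    scan_ts(t(m), colnames(m), manifest$tr[i],
            subject_id = manifest$subject[i],
            genotype = manifest$genotype[i],
            age_months = manifest$age_months[i],
            scan_id = manifest$scan_id[i])
  })
  names(scans) <- manifest$scan_id
  attr(scans, "manifest") <- manifest
  scans
}

#' @rdname cytonet-io
#' @param matrix a [conn_matrix()].
#' @param path file path for the TSV (a `.json` sidecar is written next to
#'   it).
#' @export
write_conn_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "conn_matrix"))
  m <- matrix$r
  write.table(cbind(roi = rownames(m), format(m, digits = 17, trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(matrix$metadata, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cytonet-io
#' @export
read_conn_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  rois <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- rois
  side <- sub("\\.tsv$", ".json", path)
  md <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
        else list()
  conn_matrix(m, rois, metadata = as.list(md))
}

#' @rdname cytonet-io
#' @param systems named list (system -> ROI names).
#' @export
write_systems <- function(systems, path) {
  jsonlite::write_json(systems, path)
  invisible(path)
}

#' @rdname cytonet-io
#' @export
read_systems <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname cytonet-io
#' @param panel long-format cytokine data.frame.
#' @export
write_panel <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE)
  limits <- attr(panel, "limits")
  if (!is.null(limits))
    write.csv(limits, sub("\\.csv$", "_limits.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname cytonet-io
#' @export
read_panel <- function(path) {
  panel <- read.csv(path)
  lf <- sub("\\.csv$", "_limits.csv", path)
  if (file.exists(lf)) attr(panel, "limits") <- read.csv(lf)
  class(panel) <- c("cytokine_panel", "data.frame")
  panel
}
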