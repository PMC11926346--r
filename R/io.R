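#' Write a connectome as a labelled tab-separated matrix
#'
#' Emits the full symmetric matrix with region labels as first row and first
#' column, weights printed with 17 significant digits so a read/write round
#' trip is bit-stable.
#'
#' @param c a `connectome`
#' @param path output file path
#' @export
write_connectome <- function(c, path) {
  m <- format(c$weights, digits = 17, scientific = TRUE, trim = TRUE)
  df <- cbind(region = c$region_labels, as.data.frame(m, optional = TRUE))
  colnames(df) <- c("region", c$region_labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a connectome from delimited text
#'
#' Accepts either a labelled square matrix (first row and column are region
#' labels, as written by [write_connectome()]) or a 3-column edge list
#' (`label_i`, `label_j`, `weight`). Asymmetry within `tol` is symmetrized by
#' averaging; negative weights, NaN entries and conflicting duplicate edges
#' are errors.
#'
#' @param path file path
#' @param region_labels optional label set for edge-list input, so regions
#'   without any edge are representable; ignored for matrix input.
#' @param subject_id subject identifier for the result.
#' @param tol symmetrization tolerance.
#' @export
read_connectome_matrix <- function(path, region_labels = NULL,
                                   subject_id = NULL, tol = 1e-9) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- strsplit(readLines(path, n = 1), "[\t,; ]+")[[1]]
  tab <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                    skip = 0)
  is_edge_list <- ncol(tab) == 3 &&
    !(length(first) > 3) &&
    suppressWarnings(!anyNA(as.numeric(tab[[3]])))
  if (is_edge_list && is.character(tab[[1]])) {
    return(edge_list_to_connectome(tab, region_labels, subject_id, tol))
  }
  tab <- read.table(path, header = TRUE, sep = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
  labels <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stopf("matrix in %s is not square: %d rows, %d weight columns",
          path, nrow(m), ncol(m))
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("non-numeric or NaN entry at row '%s', column '%s'",
          labels[bad[1]], colnames(m)[bad[2]])
  }
  connectome(m, labels, subject_id, tol = tol)
}

edge_list_to_connectome <- function(tab, region_labels, subject_id, tol) {
  a <- as.character(tab[[1]]); b <- as.character(tab[[2]])
  w <- as.numeric(tab[[3]])
  if (is.null(region_labels)) region_labels <- sort(unique(c(a, b)))
  ia <- match(a, region_labels); ib <- match(b, region_labels)
  if (anyNA(ia) || anyNA(ib)) {
    stopf("edge list labels not in region_labels: %s",
          paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
  }
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      ws <- w[key == k]
      if (max(ws) - min(ws) > tol) {
        stopf("conflicting duplicate edge %s-%s: weights %s",
              a[key == k][1], b[key == k][1],
              paste(signif(ws, 6), collapse = ", "))
      }
    }
    keepi <- !dup
    ia <- ia[keepi]; ib <- ib[keepi]; w <- w[keepi]
  }
  n <- length(region_labels)
  m <- matrix(0, n, n, dimnames = list(region_labels, region_labels))
  m[cbind(ia, ib)] <- w
  m[cbind(ib, ia)] <- w
  connectome(m, region_labels, subject_id, tol = tol)
}

#' Write cohort metadata as a tab-separated table
#' @param meta data.frame with columns `subject_id`, `age`, `sex`,
#'   `education`, `group` and one column per cognitive score.
#' @param path output path
#' @export
write_cohort_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read cohort metadata written by [write_cohort_metadata()]
#' @param path file path
#' @export
read_cohort_metadata <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
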