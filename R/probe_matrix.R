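#' Probe-level intensity matrix with clutch metadata
#'
#' Light container for a probes x samples matrix of log2 intensities plus
#' the sample-to-mother (clutch) assignment. Row names are probe ids,
#' column names sample ids. In this design every clutch comes from one
#' mother, so "mother" and "clutch" are used interchangeably.
#'
#' @param values numeric matrix, probes x samples, log2 intensities,
#'   with row and column names set.
#' @param sample_meta named character vector mapping each sample id to a
#'   mother id; names must cover all columns of `values`.
#' @return An object of class `probe_matrix`: a list with elements
#'   `values` (the matrix) and `sample_meta` (the mother assignment,
#'   reordered to match the columns).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' pm <- probe_matrix(m, setNames(rep(c("A", "B"), each = 2), colnames(m)))
#' clutch_factor(pm)
#' @export
probe_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe ids as rownames and sample ids as colnames")
  if (anyNA(values))
    stop("missing values in intensity matrix")
  if (anyDuplicated(rownames(values)))
    stop("duplicated probe ids")
  missing_meta <- setdiff(colnames(values), names(sample_meta))
  if (length(missing_meta))
    stop("samples without a mother id: ", paste(missing_meta, collapse = ", "))
  sample_meta <- sample_meta[colnames(values)]
  tab <- table(sample_meta)
  if (any(tab < 2))
    stop("every mother needs >= 2 eggs for range statistics; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  structure(list(values = values, sample_meta = sample_meta),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("probe_matrix:", nrow(x$values), "probes x", ncol(x$values), "samples,",
      length(unique(x$sample_meta)), "clutches\n")
  invisible(x)
}

#' @export
dim.probe_matrix <- function(x) dim(x$values)

#' Clutch assignment as a factor in sample order
#' @param m a `probe_matrix`
#' @return factor of length `ncol(m$values)` with mother ids as levels
#'   (in first-appearance order, which fixes the digit order of profile codes).
#' @export
clutch_factor <- function(m) {
  factor(m$sample_meta, levels = unique(m$sample_meta))
}

#' Replace the intensity values of a probe_matrix
#' @keywords internal
set_values <- function(m, values) {
  m$values <- values
  m
}

#' Read / write the intensity matrix as TSV
#'
#' TSV layout: first column `probe_id`, remaining columns one per sample,
#' log2 values. The sample sheet is a two-column TSV (`sample_id`,
#' `mother_id`).
#'
#' @param path TSV file of intensities
#' @param sample_sheet_path TSV file mapping samples to mothers
#' @return a `probe_matrix`
#' @export
read_probe_matrix <- function(path, sample_sheet_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  ss <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  probe_matrix(values, stats::setNames(as.character(ss$mother_id), ss$sample_id))
}

#' @rdname read_probe_matrix
#' @param m a `probe_matrix`
#' @export
write_probe_matrix <- function(m, path, sample_sheet_path = NULL) {
  tab <- data.frame(probe_id = rownames(m$values), m$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path)) {
    ss <- data.frame(sample_id = names(m$sample_meta),
                     mother_id = unname(m$sample_meta))
    utils::write.table(ss, sample_sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
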