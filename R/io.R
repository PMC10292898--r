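# Readers and writers for the plain-text exchange formats the pipeline uses:
# edge-list TSV, one-ID-per-line node sets, GMT target sets, association TSV,
# expression TSV + sample sheet, and JSON reports.

#' Read an interactome edge list from TSV
#'
#' Expects columns \code{protein_a}, \code{protein_b} and optionally
#' \code{source}; lines starting with \code{#} are ignored.
#'
#' @param path path to the TSV file.
#' @return an \linkS4class{Interactome}.
#' @export
readEdgeList <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b")
  if (!all(need %in% names(df))) {
    stop("edge list must have columns protein_a and protein_b")
  }
  cols <- c(need, intersect("source", names(df)))
  buildInteractome(df[, cols, drop = FALSE])
}

#' Write an interactome edge list to TSV
#'
#' @param g an \linkS4class{Interactome}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(g, path) {
  utils::write.table(edgeTable(g), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a node set (one ID per line)
#'
#' @param path path to the file; \code{#} comment lines are ignored.
#' @param name label for the returned set (default: file base name).
#' @return a \linkS4class{TargetSet}.
#' @export
readNodeSet <- function(path, name = NULL) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  TargetSet(name, ln)
}

#' Read compound target sets from GMT or two-column TSV
#'
#' GMT rows are \code{name <tab> description <tab> member...}; the TSV form
#' has columns \code{set_name} and \code{member}. The format is chosen by the
#' file extension (".gmt" vs anything else).
#'
#' @param path path to the file.
#' @return named list of \linkS4class{TargetSet}s.
#' @export
readTargetSets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (!all(c("set_name", "member") %in% names(df))) {
      stop("target TSV must have columns set_name and member")
    }
    sets <- split(df$member, df$set_name)
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  out <- lapply(names(sets), function(nm) TargetSet(nm, sets[[nm]]))
  names(out) <- names(sets)
  out
}

#' Write target sets to GMT
#'
#' @param sets named list of \linkS4class{TargetSet}s.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(setName(s), "na", members(s)), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a compound--disease association table
#'
#' @param path TSV with columns \code{compound}, \code{disease},
#'   \code{label}; labels must be \code{therapeutic} or
#'   \code{non_therapeutic}.
#' @return data.frame with those columns; duplicate pairs are an error.
#' @export
readAssociations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("compound", "disease", "label")
  if (!all(need %in% names(df))) {
    stop("association table must have columns compound, disease, label")
  }
  if (anyDuplicated(df[, c("compound", "disease")])) {
    stop("duplicate (compound, disease) pairs")
  }
  ok <- df$label %in% c("therapeutic", "non_therapeutic")
  if (!all(ok)) stop("labels must be 'therapeutic' or 'non_therapeutic'")
  df[, need]
}

#' Read an expression matrix with its sample sheet
#'
#' @param exprPath TSV whose first column is the gene ID and whose remaining
#'   columns are per-sample log2 expression values.
#' @param sheetPath TSV with columns \code{sample} and \code{group}
#'   (\code{case}/\code{control}).
#' @return a \code{SummarizedExperiment} (see \code{\link{makeExpressionSet}}).
#' @export
readExpressionTSV <- function(exprPath, sheetPath) {
  df <- utils::read.delim(exprPath, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- genes
  sheet <- utils::read.delim(sheetPath, header = TRUE,
                             stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(sheet))) {
    stop("sample sheet must have columns sample and group")
  }
  groups <- stats::setNames(sheet$group, sheet$sample)
  makeExpressionSet(mat, groups)
}

# Internal: write a list as pretty JSON (deterministic key order as given).
.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the interactome load report as JSON
#'
#' @param g an \linkS4class{Interactome}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeLoadReport <- function(g, path) {
  .writeJSON(loadReport(g), path)
}
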