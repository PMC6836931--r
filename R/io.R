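## Plain-text readers/writers: counts TSV/MTX, sample metadata, GMT gene
## sets, category map, weighted edge lists, ground-truth JSON.

#' Read gene sets from a GMT file
#'
#' Lines are \code{term TAB description TAB gene...}.  Duplicate terms are
#' rejected with their line numbers.
#'
#' @param path GMT file
#' @return named list term -> character gene ids; descriptions kept in
#'   \code{attr(, "description")}
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (need term, description, >= 1 gene): ",
         paste(bad, collapse = ", "))
  terms <- vapply(parts, `[[`, "", 1L)
  dup <- which(duplicated(terms) | duplicated(terms, fromLast = TRUE))
  if (length(dup))
    stop("duplicate term '", terms[dup[1]], "' on lines ",
         paste(dup, collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- terms
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), terms)
  sets
}

#' @rdname readGeneSets
#' @param sets named list term -> genes
#' @param descriptions optional named character descriptions
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(tm)
    paste(c(tm, descriptions[[tm]], sets[[tm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted edge list TSV (node, node, confidence)
#'
#' Duplicate undirected edges are rejected naming both lines.
#'
#' @param path TSV file with a header
#' @return an \linkS4class{InteractionGraph}
#' @export
readEdgeList <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("edge list needs 3 columns: from, to, confidence")
  colnames(df)[1:3] <- c("from", "to", "confidence")
  if (!is.numeric(df$confidence)) stop("confidence column must be numeric")
  key <- paste(pmin(df$from, df$to), pmax(df$from, df$to))
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup))
    stop("duplicate edge '", key[dup[1]], "' on lines ",
         paste(dup + 1L, collapse = " and "))  # +1 for the header line
  InteractionGraph(df)
}

#' @rdname readEdgeList
#' @param graph an \linkS4class{InteractionGraph}
#' @export
writeEdgeList <- function(graph, path) {
  utils::write.table(graph@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count matrix with sample metadata
#'
#' \code{countsPath} may be a TSV (transcripts as rows, first column =
#' transcript id, header = sample ids) or a MatrixMarket \code{.mtx} file
#' accompanied by row-name and column-name files (one id per line).
#' Negative or non-integer values are rejected.
#'
#' @param countsPath counts TSV or MTX file
#' @param metaPath sample metadata TSV with columns sample, time and
#'   optionally surgeon, batch
#' @param rowNamesPath,colNamesPath id files, required for MTX input
#' @return a \linkS4class{TimecourseExperiment}
#' @export
readCounts <- function(countsPath, metaPath, rowNamesPath = NULL,
                       colNamesPath = NULL) {
  if (grepl("\\.mtx$", countsPath)) {
    if (is.null(rowNamesPath) || is.null(colNamesPath))
      stop("MTX input needs rowNamesPath and colNamesPath")
    m <- as.matrix(Matrix::readMM(countsPath))
    rn <- readLines(rowNamesPath)
    cn <- readLines(colNamesPath)
    if (nrow(m) != length(rn) || ncol(m) != length(cn))
      stop("MTX dimensions (", nrow(m), " x ", ncol(m),
           ") do not match the id files (", length(rn), " x ", length(cn), ")")
    dimnames(m) <- list(rn, cn)
  } else {
    df <- utils::read.table(countsPath, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  }
  if (any(m < 0)) stop("negative counts are not allowed")
  meta <- utils::read.table(metaPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("sample", "time") %in% colnames(meta)))
    stop("metadata needs 'sample' and 'time' columns")
  meta <- meta[match(colnames(m), meta$sample), , drop = FALSE]
  if (any(is.na(meta$sample)))
    stop("metadata is missing sample(s): ",
         paste(setdiff(colnames(m), meta$sample), collapse = ", "))
  TimecourseExperiment(m, meta[, setdiff(colnames(meta), "sample"),
                               drop = FALSE])
}

#' @rdname readCounts
#' @param x a \linkS4class{TimecourseExperiment}
#' @param dir output directory
#' @param prefix file-name prefix
#' @export
writeCounts <- function(x, dir, prefix = "counts") {
  cp <- file.path(dir, paste0(prefix, ".tsv"))
  m <- counts(x)
  df <- data.frame(transcript = rownames(m), m, check.names = FALSE)
  utils::write.table(df, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- file.path(dir, paste0(prefix, "_meta.tsv"))
  cd <- as.data.frame(colData(x))
  utils::write.table(data.frame(sample = rownames(cd), cd), mp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(counts = cp, meta = mp))
}

#' Read / write a term -> category map TSV
#' @param path two-column TSV (term, category) with header
#' @return named character term -> category
#' @export
readCategoryMap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate term(s) in category map: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname readCategoryMap
#' @param map named character term -> category
#' @export
writeCategoryMap <- function(map, path) {
  utils::write.table(data.frame(term = names(map), category = unname(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read ground truth as JSON
#' @param truth a \linkS4class{GroundTruth}
#' @param path JSON file
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(list(
    moduleLabels = as.list(truth@moduleLabels),
    deTranscripts = truth@deTranscripts,
    termMap = truth@termMap, categoryMap = as.list(truth@categoryMap),
    tfTargets = truth@tfTargets, drivenTfs = truth@drivenTfs,
    hubNode = truth@hubNode, cascade = truth@cascade),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GroundTruth",
      moduleLabels = unlist(j$moduleLabels),
      deTranscripts = as.character(j$deTranscripts),
      termMap = lapply(j$termMap, as.character),
      categoryMap = unlist(j$categoryMap),
      tfTargets = lapply(j$tfTargets, as.character),
      drivenTfs = as.character(j$drivenTfs),
      hubNode = as.character(j$hubNode),
      cascade = as.character(j$cascade))
}
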