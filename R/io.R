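#' Coerce input to a binary association matrix
#'
#' The canonical container for known lncRNA-disease associations is a binary
#' matrix with diseases on rows and lncRNAs on columns, labelled by
#' identifier. Analysis functions accept either this matrix or a long
#' edge-list data frame whose first two columns are `(disease, lncrna)` with
#' an optional third `{0,1}` weight column; identifier order is the order of
#' first appearance and duplicated edges collapse to a single 1.
#'
#' @param x A `{0,1}` matrix with row/column names, or an edge-list data
#'   frame.
#' @return A numeric `{0,1}` matrix with `dimnames = list(diseases, lncrnas)`.
#' @export
#' @examples
#' as_assoc_matrix(data.frame(disease = c("D1", "D2"),
#'                            lncrna  = c("L1", "L2")))
as_assoc_matrix <- function(x) {
  if (is.matrix(x)) {
    if (!all(x %in% c(0, 1))) {
      abort("association matrix entries must all be 0 or 1")
    }
    if (is.null(rownames(x))) rownames(x) <- paste0("D", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("L", seq_len(ncol(x)))
    if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
      abort("association matrix identifiers must be unique")
    }
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("associations must be a matrix or a data frame with >= 2 columns")
  }
  dis <- as.character(x[[1]])
  lnc <- as.character(x[[2]])
  w <- if (ncol(x) >= 3) as.numeric(x[[3]]) else rep(1, nrow(x))
  if (!all(w %in% c(0, 1))) abort("edge weights must be 0 or 1")
  d_ids <- unique(dis)
  l_ids <- unique(lnc)
  a <- matrix(0, length(d_ids), length(l_ids), dimnames = list(d_ids, l_ids))
  keep <- w == 1
  a[cbind(match(dis[keep], d_ids), match(lnc[keep], l_ids))] <- 1
  a
}

#' Tidy an association matrix into an edge list
#'
#' @param assoc An association matrix (see [as_assoc_matrix()]).
#' @param keep_zeros Keep the unobserved pairs (as weight-0 rows)?
#' @return A tibble with columns `disease`, `lncrna`, `known`.
#' @export
assoc_edges <- function(assoc, keep_zeros = FALSE) {
  a <- as_assoc_matrix(assoc)
  out <- tibble(disease = rep(rownames(a), times = ncol(a)),
                lncrna = rep(colnames(a), each = nrow(a)),
                known = as.integer(c(a)))
  if (!keep_zeros) out <- dplyr::filter(out, .data$known == 1L)
  out
}

#' Read a lncRNA-disease association table
#'
#' Two dialects are supported. `edge_list` (the canonical one, matching how
#' the association databases publish their data) is a header-less TSV whose
#' rows are `disease_id<TAB>lncrna_id` with an optional third `{0,1}` weight
#' field; identifiers are ordered by first appearance and duplicate edges
#' collapse. `dense` is a full matrix with a header row of lncRNA
#' identifiers and a first column of disease identifiers; every cell must be
#' 0 or 1.
#'
#' @param path Path to the TSV file.
#' @param format `"edge_list"` or `"dense"`.
#' @return A binary association matrix (diseases x lncRNAs).
#' @export
read_associations <- function(path, format = c("edge_list", "dense")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "dense") {
    df <- utils::read.delim(path, header = TRUE, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    a <- as.matrix(df)
    if (!is.numeric(a) || !all(a %in% c(0, 1))) {
      abort("dense association matrix contains values other than 0/1")
    }
    return(as_assoc_matrix(a))
  }
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) abort("association edge list is empty")
  fields <- strsplit(lines[nonempty], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2 | nf > 3)) {
    ln <- nonempty[which(nf < 2 | nf > 3)[1]]
    abort(paste0("parse error at line ", ln,
                 ": expected 2 or 3 tab-separated fields"))
  }
  w <- vapply(fields, function(f) if (length(f) == 3) f[3] else "1", "")
  if (!all(w %in% c("0", "1"))) {
    ln <- nonempty[which(!w %in% c("0", "1"))[1]]
    abort(paste0("validation error at line ", ln, ": weight must be 0 or 1"))
  }
  as_assoc_matrix(data.frame(
    disease = vapply(fields, `[`, "", 1),
    lncrna = vapply(fields, `[`, "", 2),
    weight = as.numeric(w)
  ))
}

#' Read an lncRNA expression matrix
#'
#' Expects a TSV with a header: the first column holds lncRNA identifiers
#' and the remaining columns hold numeric expression levels per tissue or
#' cell type. Rows whose identifier is absent from the association universe
#' are dropped with a warning (public expression panels cover far more
#' lncRNAs than any association snapshot). An empty file yields an empty
#' matrix: expression is optional throughout the pipeline.
#'
#' @param path Path to the TSV file.
#' @param assoc Association matrix defining the lncRNA universe.
#' @return A numeric matrix (lncRNAs x tissues) with rownames, possibly with
#'   zero rows.
#' @export
read_expression <- function(path, assoc) {
  assoc <- as_assoc_matrix(assoc)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    return(matrix(numeric(0), 0, 0))
  }
  df <- suppressWarnings(
    readr::read_tsv(path, na = character(), show_col_types = FALSE,
                    col_types = readr::cols(
                      readr::col_character(),
                      .default = readr::col_double())))
  prb <- readr::problems(df)
  if (nrow(prb) > 0) {
    abort(paste0("non-numeric expression value at row ", prb$row[1],
                 ", column ", prb$col[1]))
  }
  if (anyDuplicated(df[[1]])) abort("duplicated lncRNA identifier in expression table")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  known <- rownames(m) %in% colnames(assoc)
  if (any(!known)) {
    warn(paste0("dropping ", sum(!known),
                " expression profile(s) for lncRNAs absent from the association matrix"))
    m <- m[known, , drop = FALSE]
  }
  if (nrow(m) > 0 && ncol(m) < 2) {
    abort("expression matrix needs at least 2 tissue columns")
  }
  m
}

#' Write a prediction score table
#'
#' Emits a long-format TSV with columns
#' `disease_id, lncrna_id, score, known_flag`, sorted by disease identifier
#' and, within disease, by descending score. Scores are written with 17
#' significant digits so a read-back reproduces them bit-identically.
#'
#' @param scores A prediction tibble as returned by [lnc_predict()], with
#'   columns `disease`, `lncrna`, `score`, `known`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(is.data.frame(scores),
            all(c("disease", "lncrna", "score", "known") %in% names(scores)))
  if (!all(is.finite(scores$score))) {
    abort("scores contain non-finite values; refusing to write")
  }
  ord <- order(scores$disease, -scores$score, scores$lncrna, method = "radix")
  s <- scores[ord, ]
  out <- paste(s$disease, s$lncrna, sprintf("%.17g", s$score),
               as.integer(s$known), sep = "\t")
  writeLines(c("disease_id\tlncrna_id\tscore\tknown_flag", out), path)
  invisible(path)
}

#' Read back a prediction score table written by [write_scores()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `disease`, `lncrna`, `score`, `known`.
#' @export
read_scores <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = "ccdi")
  names(df) <- c("disease", "lncrna", "score", "known")
  df
}
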