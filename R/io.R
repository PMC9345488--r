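#' Read a per-sample label table
#'
#' CSV with columns `sample_id,label[,probability]` (header optional; detected
#' by a non-numeric third field or the literal column names). An empty label
#' field means the sample is unlabelled (missing), which downstream keeps its
#' raw pairwise distances.
#'
#' @param path path to the CSV.
#' @return data.frame with columns `sample_id`, `label` (`NA` = missing) and,
#'   when present in the file, `probability` in `[0, 1]`.
#' @export
read_labels <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         strip.white = TRUE, colClasses = "character")
  if (nrow(raw) > 0L &&
      tolower(raw[1L, 1L]) %in% c("sample_id", "sample", "id", "cell")) {
    raw <- raw[-1L, , drop = FALSE]
  }
  if (ncol(raw) < 2L) stop("labels file needs columns sample_id,label")
  out <- data.frame(sample_id = raw[[1L]], label = raw[[2L]],
                    stringsAsFactors = FALSE)
  out$label[out$label == ""] <- NA_character_
  if (ncol(raw) >= 3L) {
    p <- suppressWarnings(as.numeric(raw[[3L]]))
    if (any(is.na(p) & raw[[3L]] != "")) {
      stop("probability column must be numeric")
    }
    if (any(p < 0 | p > 1, na.rm = TRUE)) {
      stop("probabilities must lie in [0, 1]")
    }
    out$probability <- p
  }
  out
}

#' Write an embedding to CSV
#'
#' Emits `sample_id, dim1, dim2[, dim3...]` rows.
#'
#' @param embedding an [hdr_embed()] result or coordinate matrix.
#' @param path output path.
#' @export
write_embedding <- function(embedding, path) {
  coords <- .embedding_coords(embedding)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(coords)))
  df <- data.frame(sample_id = ids, coords, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a numeric sample x feature matrix
#'
#' Dense CSV/TSV (first column = sample ids when non-numeric, header
#' detected) or sparse MatrixMarket-style triplet text (`row col value` lines
#' after an optional `%%` comment header and a `nrow ncol nnz` line).
#'
#' @param path path to the matrix file.
#' @return a dense numeric matrix.
#' @export
read_matrix <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^%", lines)]
    hdr <- scan(text = lines[1L], quiet = TRUE)
    trip <- utils::read.table(text = lines[-1L])
    M <- matrix(0, hdr[1L], hdr[2L])
    M[cbind(trip[[1L]], trip[[2L]])] <- trip[[3L]]
    return(M)
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields[-1L])))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE)
  first_col_ids <- is.character(df[[1L]])
  ids <- if (first_col_ids) df[[1L]] else NULL
  if (first_col_ids) df <- df[, -1L, drop = FALSE]
  M <- as.matrix(df)
  storage.mode(M) <- "double"
  if (!is.null(ids)) rownames(M) <- ids
  M
}
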