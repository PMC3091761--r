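#' Read a genes-by-samples expression matrix from TSV
#'
#' The first column holds gene (row) identifiers; remaining columns are one
#' sample each. Identifiers must be unique in both dimensions and all cells
#' numeric.
#'
#' @param path TSV file path.
#' @param id_col Name for the identifier column when writing (ignored on
#'   read; the first column is always the identifier).
#' @param allow_missing If `FALSE` (default) any missing cell is an error;
#'   if `TRUE` rows containing missing values are dropped with a warning.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, allow_missing = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) fc_abort("expression TSV needs an id column plus samples")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    fc_abort(paste0(
      "duplicated gene id(s): ", paste(head(dup, 5), collapse = ", ")
    ))
  }
  sample_ids <- names(df)[-1]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    fc_abort(paste0("duplicated sample id(s): ", paste(dup_s, collapse = ", ")))
  }
  num <- df[-1]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    fc_abort(paste0(
      "non-numeric cells in column(s): ",
      paste(names(num)[bad], collapse = ", ")
    ))
  }
  mat <- as.matrix(num)
  rownames(mat) <- ids
  if (anyNA(mat)) {
    if (!allow_missing) fc_abort("missing cells in expression matrix")
    keep <- stats::complete.cases(mat)
    warn(sprintf("dropping %d row(s) with missing values", sum(!keep)))
    mat <- mat[keep, , drop = FALSE]
  }
  mat
}

#' Write an expression matrix as TSV (row ids in the first column)
#'
#' @param mat Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Header for the identifier column.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path, id_col = "gene") {
  df <- tibble::as_tibble(mat, rownames = id_col)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' @param path TSV with at least `sample` plus any of `case`, `tissue`,
#'   `storage`, `chip`, `batch`, `block_age`, `delta_ct`.
#' @return A tibble; `case`, `tissue`, `storage`, `chip`, `batch` become
#'   factors with stable level order.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample" %in% names(df)) fc_abort("sample sheet needs a 'sample' column")
  if (anyDuplicated(df$sample)) fc_abort("duplicated sample ids in sheet")
  for (col in intersect(c("case", "tissue", "storage", "chip", "batch"),
    names(df))) {
    df[[col]] <- factor(df[[col]], levels = unique(df[[col]]))
  }
  if ("tissue" %in% names(df)) {
    lv <- intersect(c("normal", "tumor"), levels(df$tissue))
    if (length(lv) == nlevels(df$tissue)) df$tissue <- factor(df$tissue, lv)
  }
  if ("storage" %in% names(df)) {
    lv <- intersect(c("FF", "FFPE"), levels(df$storage))
    if (length(lv) == nlevels(df$storage)) df$storage <- factor(df$storage, lv)
  }
  df
}

#' Gene-set collections
#'
#' A `gene_set_collection` is an ordered, named list of character vectors of
#' gene ids with an optional per-set description (GO category label etc.),
#' GMT-serializable via [write_gmt()].
#'
#' @param sets Named list of character vectors.
#' @param description Character vector of per-set descriptions (recycled).
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = "") {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    fc_abort("every gene set needs a name")
  }
  description <- rep_len(as.character(description), length(sets))
  structure(
    lapply(sets, as.character),
    description = setNames(description, names(sets)),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %d sets, sizes %d-%d\n",
    length(x),
    if (length(x)) min(lengths(x)) else 0L,
    if (length(x)) max(lengths(x)) else 0L
  ))
  invisible(x)
}

#' @rdname gene_set_collection
#' @param x A `gene_set_collection`.
#' @export
tidy.gene_set_collection <- function(x, ...) {
  tibble(
    set = names(x),
    description = unname(attr(x, "description")[names(x)]),
    size = lengths(x),
    genes = lapply(x, identity)
  )
}

#' Read gene sets in GMT format
#'
#' Standard dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members within
#' a set are dropped with a warning; a line with fewer than three fields is an
#' error.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()] preserving file order.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    fc_abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, function(s) sum(duplicated(s)), 0L))
  if (ndup > 0) {
    warn(sprintf("%d duplicated member(s) within sets were deduplicated", ndup))
    sets <- lapply(sets, unique)
  }
  gene_set_collection(setNames(sets, nm), description = desc)
}

#' Write gene sets in GMT format
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}
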