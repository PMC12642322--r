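#' Read a protein abundance matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of protein/gene
#' symbols. Empty cells are read as missing values (`NA`), never as zeros.
#'
#' @param path path to a tab-separated file.
#' @param scale_tag scale of the stored values; see [scale_tag()].
#' @return numeric matrix, features in rows, samples in columns, with a
#'   `scale_tag` attribute.
#' @export
read_abundance <- function(path, scale_tag = "log2") {
  scale_tag <- match.arg(scale_tag, .scale_levels)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged TSV: line ", bad, " has ", nf[bad], " fields, expected ", nf[1L])
  }
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         colClasses = c("character", rep("numeric", nf[1L] - 1L)),
                         na.strings = c("", "NA"))
  feats <- d[[1L]]
  if (anyDuplicated(feats))
    stop("duplicate feature symbols in ", path, ": ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- feats
  attr(m, "scale_tag") <- scale_tag
  .check_abundance(m)
  m
}

#' Write an abundance matrix to TSV
#'
#' Missing entries are written as empty cells so the file round-trips through
#' [read_abundance()] with the missingness pattern intact.
#'
#' @param m abundance matrix.
#' @param path output path.
#' @param feature_col name of the first (feature symbol) column.
#' @export
write_abundance <- function(m, path, feature_col = "feature") {
  .check_abundance(m)
  d <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(d)[1L] <- feature_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write the per-islet sample metadata table
#'
#' Columns: `sample_id`, `donor_id`, `group` (stage1/nd), `block` (tissue-block
#' batch), `cd3` (0/1, may be missing), `is_reference` (0/1 reference-pool
#' flag).
#'
#' @param path TSV path.
#' @return data.frame with the columns above.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            na.strings = c("", "NA"),
                            colClasses = "character")
  meta$cd3 <- as.integer(meta$cd3)
  meta$is_reference <- as.integer(meta$is_reference)
  .check_metadata(meta)
  meta
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  .check_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Each line is tab-separated: set name, description, then member symbols.
#' Members are deduplicated (with a warning); duplicate set names are an
#' error.
#'
#' @param path GMT path.
#' @return named list of character vectors with a `description` attribute and
#'   `provenance` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- structure(list(), description = character(0), provenance = path)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 2L)
  if (length(short)) stop("GMT line ", short[1L], " has fewer than 2 fields")
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) {
    mem <- p[-(1:2)]
    mem <- mem[nzchar(mem)]
    if (anyDuplicated(mem)) {
      warning("duplicate members in set '", p[[1L]], "' deduplicated")
      mem <- unique(mem)
    }
    mem
  })
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, description = desc, provenance = path)
}

#' @rdname read_gmt
#' @param sets named list of character vectors (a gene-set collection).
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  stopifnot(length(descriptions) == length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
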