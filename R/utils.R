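#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale tag of an abundance matrix
#'
#' Abundance matrices are plain numeric matrices (features in rows, samples in
#' columns) carrying a `scale_tag` attribute that records where in the
#' preprocessing chain they sit: `"linear"` raw intensities, `"log2"`
#' log2-transformed, `"log2_centered"` log2 and feature-centered. The tag only
#' moves forward along that chain.
#'
#' @param m numeric matrix with features in rows and samples in columns.
#' @return character scalar, one of `"linear"`, `"log2"`, `"log2_centered"`.
#' @export
scale_tag <- function(m) attr(m, "scale_tag") %||% "log2"

.scale_levels <- c("linear", "log2", "log2_centered")

#' @rdname scale_tag
#' @param value new tag; must not move backwards (e.g. log2 -> linear).
#' @export
`scale_tag<-` <- function(m, value) {
  value <- match.arg(value, .scale_levels)
  old <- scale_tag(m)
  if (match(value, .scale_levels) < match(old, .scale_levels))
    stop("scale_tag may only move forward (", old, " -> ", value, " is not allowed)")
  attr(m, "scale_tag") <- value
  m
}

.check_abundance <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("abundance matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  invisible(m)
}

.check_metadata <- function(meta, m = NULL) {
  need <- c("sample_id", "donor_id", "group", "block", "cd3", "is_reference")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!is.null(m)) {
    if (!setequal(colnames(m), meta$sample_id))
      stop("abundance samples and metadata sample_id differ")
  }
  invisible(meta)
}

# Align a metadata table to the column order of an abundance matrix.
.meta_align <- function(meta, m) {
  .check_metadata(meta, m)
  meta[match(colnames(m), meta$sample_id), , drop = FALSE]
}

# Restore the caller's RNG state on exit and seed a local stream.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Derive child seeds from a parent seed without disturbing the caller's stream.
.child_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Rank-based AUROC of scores for the positive class (ties share ranks).
.auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  pos <- as.logical(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
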