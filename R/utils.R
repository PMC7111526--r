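#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate coef cor cutree dist hclust lm logLik optim
#'   optimize p.adjust pchisq prcomp pt qt quantile rbinom rnorm runif sd var
#'   as.dist setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

# Atomic file write: write to a temp file in the same directory, then rename.
write_tsv_atomic <- function(x, path, row_names = FALSE) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.table(x, tmp, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

write_text_atomic <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided P from a t statistic.
t_pvalue <- function(tstat, df) 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
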