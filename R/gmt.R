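#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then one or more gene ids.
#'
#' @param path GMT file path.
#' @return list of sets, each `list(name, description, genes)`. A line with
#'   fewer than three fields raises a parse error naming the line.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(f)))
    out[[i]] <- list(name = f[1], description = f[2], genes = f[-(1:2)])
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets list of sets, each `list(name, description, genes)`.
#' @param path output path.
#' @return Invisibly, `path`. Round trips with [read_gmt()] preserving set
#'   names, descriptions and gene order.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    desc <- if (is.null(s$description)) "" else s$description
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
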