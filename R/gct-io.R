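# Readers and writers for the three classic expression-analysis formats:
# GCT (expression matrix, version line "#1.2"), CLS (three-line two-class
# phenotype labels) and GMT (one gene set per line).

#' Read / write a GCT expression matrix
#'
#' GCT version 1.2: a `#1.2` header line, a `n_genes<TAB>n_samples`
#' dimension line, then a table with `Name` and `Description` columns
#' followed by one column per sample.
#'
#' @param path file path.
#' @return `read_gct`: a numeric matrix (genes x samples) with gene ids as
#'   row names and a `description` attribute.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  abort_if(length(lines) < 3 || trimws(lines[1]) != "#1.2",
           "not a GCT 1.2 file (missing '#1.2' header)",
           class = "mirhub_parse_error")
  dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]])
  tab <- read.table(text = lines[-(1:2)], header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  abort_if(nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2],
           "GCT dimension line disagrees with the table",
           class = "mirhub_parse_error")
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(m) <- tab[[1]]
  attr(m, "description") <- tab[[2]]
  m
}

#' @param expr numeric matrix (genes x samples), row names = gene ids.
#' @rdname read_gct
#' @export
write_gct <- function(expr, path) {
  desc <- attr(expr, "description")
  if (is.null(desc)) desc <- rep("na", nrow(expr))
  header <- c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t"))
  tab <- cbind(Name = rownames(expr), Description = desc,
               as.data.frame(expr, check.names = FALSE))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write CLS phenotype labels
#'
#' Categorical CLS: line 1 is `n_samples n_classes 1`, line 2 names the
#' classes (`# classA classB`), line 3 assigns each sample a label (class
#' names or 0-based indices).
#'
#' @param path file path.
#' @return `read_cls`: a factor of per-sample class labels whose level
#'   order follows the header.
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  abort_if(length(lines) < 3, "CLS file needs three lines",
           class = "mirhub_parse_error")
  hd <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  classes <- strsplit(trimws(lines[2]), "[[:space:]]+")[[1]]
  abort_if(classes[1] != "#", "CLS class line must start with '#'",
           class = "mirhub_parse_error")
  classes <- classes[-1]
  lab <- strsplit(trimws(lines[3]), "[[:space:]]+")[[1]]
  abort_if(length(lab) != hd[1], "CLS label count disagrees with header",
           class = "mirhub_parse_error")
  if (all(lab %in% as.character(seq_along(classes) - 1L))) {
    lab <- classes[as.integer(lab) + 1L]
  }
  factor(lab, levels = classes)
}

#' @param labels factor (or character) of per-sample class labels.
#' @rdname read_cls
#' @export
write_cls <- function(labels, path) {
  labels <- as.factor(labels)
  lines <- c(paste(length(labels), nlevels(labels), "1"),
             paste(c("#", levels(labels)), collapse = " "),
             paste(as.character(labels), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' One set per line: set name, description, then tab-separated members.
#'
#' @param path file path.
#' @return `read_gmt`: a named list of character vectors with a
#'   `description` attribute on each element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    abort_if(length(fields) < 3,
             sprintf("GMT line %d: need name, description and >=1 member", i),
             class = "mirhub_parse_error")
    members <- fields[-(1:2)]
    attr(members, "description") <- fields[2]
    out[[fields[1]]] <- members
  }
  out
}

#' @param sets named list of character vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
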