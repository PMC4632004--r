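#' Construct a validated expression matrix
#'
#' The central container of the pipeline: a numeric genes-by-samples matrix of
#' log2-scale expression with unique gene and sample identifiers and a cohort
#' label. Every downstream stage (subtyping, enrichment scoring, network
#' inference, prognosis) consumes this object.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Rownames
#'   are gene symbols, colnames are sample identifiers.
#' @param dataset_id Free-text cohort label (used for per-dataset score
#'   normalization).
#' @return An object of class `expression_matrix`: the matrix with a
#'   `dataset_id` attribute.
#' @export
expression_matrix <- function(values, dataset_id = "cohort") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values")
  structure(values, dataset_id = dataset_id, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, dataset '%s'\n",
              nrow(x), ncol(x), attr(x, "dataset_id")))
  invisible(x)
}

dataset_id <- function(x) attr(x, "dataset_id") %||% "cohort"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a gene set
#'
#' @param name Set name.
#' @param members Character vector of gene symbols; duplicates are dropped
#'   with a warning, order of first occurrence kept.
#' @param description Free-text description.
#' @return A `gene_set` list with fields `name`, `description`, `members`.
#' @export
gene_set <- function(name, members, description = "") {
  members <- trimws(as.character(members))
  members <- members[nzchar(members)]
  if (length(members) == 0L) stop("gene set '", name, "' has no members")
  if (anyDuplicated(members)) {
    warning("gene set '", name, "' contains duplicate members; de-duplicated")
    members <- members[!duplicated(members)]
  }
  structure(list(name = name, description = description, members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%d genes)\n", x$name, length(x$members)))
  invisible(x)
}

#' Read an expression matrix from TSV or GCT
#'
#' Tab-delimited input: first column gene symbol, remaining columns one per
#' sample, header row of sample ids. GCT v1.2: `#1.2` line, dimension line,
#' then `Name`/`Description` columns before the samples. Duplicate gene rows
#' are collapsed by keeping the row with maximum variance (most variable
#' probe per symbol).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`.
#' @param dataset_id Cohort label; defaults to the file stem.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "gct"),
                            dataset_id = sub("\\.[^.]*$", "", basename(path))) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "gct") {
    if (length(lines) < 3L || !startsWith(lines[[1L]], "#1.2"))
      stop("malformed GCT header in ", path, ": expected '#1.2' on line 1")
    header_at <- 3L
    id_cols <- 2L
  } else {
    if (length(lines) < 2L) stop("malformed TSV in ", path, ": need header plus data")
    header_at <- 1L
    id_cols <- 1L
  }
  header <- strsplit(lines[[header_at]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- trimws(header[-seq_len(id_cols)])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header (line ", header_at, "): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- lines[-seq_len(header_at)]
  body <- body[nzchar(body)]
  gene <- character(length(body))
  vals <- matrix(NA_real_, length(body), length(sample_ids))
  for (i in seq_along(body)) {
    line_no <- header_at + i
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != id_cols + length(sample_ids))
      stop("line ", line_no, ": expected ", id_cols + length(sample_ids),
           " fields, found ", length(f))
    gene[i] <- trimws(f[[1L]])
    v <- suppressWarnings(as.numeric(f[-seq_len(id_cols)]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("line ", line_no, ", sample '", sample_ids[bad],
           "': non-numeric cell '", f[id_cols + bad], "'")
    }
    vals[i, ] <- v
  }
  rownames(vals) <- make.unique(gene)
  colnames(vals) <- sample_ids
  if (anyDuplicated(gene)) {
    keep <- vapply(split(seq_along(gene), gene), function(idx) {
      if (length(idx) == 1L) return(idx)
      idx[which.max(apply(vals[idx, , drop = FALSE], 1L, stats::var))]
    }, integer(1L))
    keep <- sort(unname(keep))
    vals <- vals[keep, , drop = FALSE]
    rownames(vals) <- gene[keep]
  }
  expression_matrix(vals, dataset_id = dataset_id)
}

#' Write an expression matrix as TSV (or GCT v1.2)
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "gct") {
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
    header <- paste(c("Name", "Description", colnames(x)), collapse = "\t")
    body <- paste(rownames(x), "na",
                  apply(x, 1L, function(r) paste(format(r, digits = 15), collapse = "\t")),
                  sep = "\t")
  } else {
    header <- paste(c("gene_id", colnames(x)), collapse = "\t")
    body <- paste(rownames(x),
                  apply(x, 1L, function(r) paste(format(r, digits = 15), collapse = "\t")),
                  sep = "\t")
  }
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then members, tab-separated.
#'
#' @param path File path.
#' @return A named list of [gene_set()] objects, file order preserved.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("line ", i, ": GMT lines need at least 3 tab-separated fields")
    sets[[i]] <- gene_set(trimws(f[[1L]]), f[-(1:2)], description = trimws(f[[2L]]))
  }
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of [gene_set()] objects (or a single one).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, if (nzchar(s$description)) s$description else "na", s$members),
          collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table
#'
#' Tab-delimited with header; requires columns `sample_id`, `time` (months,
#' non-negative) and `event` (0 = censored, 1 = death observed). An optional
#' `cohort_id` column defaults to the file stem.
#'
#' @param path File path.
#' @param cohort_id Default cohort label when the column is absent.
#' @return A `survival_table` data.frame with columns sample_id, time, event,
#'   cohort_id.
#' @export
read_survival <- function(path, cohort_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("sample_id", "time", "event"))
    if (!col %in% names(df)) stop("missing required column '", col, "' in ", path)
  if (!"cohort_id" %in% names(df)) df$cohort_id <- cohort_id
  survival_table(df$sample_id, df$time, df$event, df$cohort_id)
}

#' Construct a validated survival table
#'
#' @param sample_id,time,event,cohort_id Vectors of equal length; `time` in
#'   months, `event` coded 0/1 with 1 = death observed.
#' @return A data.frame of class `survival_table`.
#' @export
survival_table <- function(sample_id, time, event, cohort_id = "cohort") {
  df <- data.frame(sample_id = as.character(sample_id),
                   time = as.numeric(time),
                   event = as.numeric(event),
                   cohort_id = as.character(cohort_id),
                   stringsAsFactors = FALSE)
  if (anyNA(df$time) || any(df$time < 0))
    stop("survival times must be non-negative")
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (observed)")
  dup <- duplicated(df[c("cohort_id", "sample_id")])
  if (any(dup))
    stop("duplicate sample ids within cohort: ",
         paste(unique(df$sample_id[dup]), collapse = ", "))
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Write a survival table as TSV
#' @param x A `survival_table`.
#' @param path Output path.
#' @export
write_survival <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a transcriptional network as a tab-delimited edge list
#'
#' Columns: tf, target, mi (nats), mode (+1/-1), bootstrap_support. Round
#' trips losslessly with [read_network()].
#'
#' @param network A `transcriptional_network` (see [infer_regulons()]).
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "transcriptional_network"))
  edges <- network_edges(network)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines("tf\ttarget\tmi\tmode\tbootstrap_support", con)
  if (nrow(edges))
    writeLines(sprintf("%s\t%s\t%.17g\t%d\t%.17g", edges$tf, edges$target,
                       edges$mi, edges$mode, edges$bootstrap_support), con)
  invisible(path)
}

#' Read a transcriptional network written by [write_network()]
#'
#' @param path File path.
#' @param universe Optional target universe; defaults to all genes appearing
#'   in the file.
#' @return A `transcriptional_network`.
#' @export
read_network <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "target", "mi", "mode", "bootstrap_support")
  if (!all(need %in% names(df)))
    stop("network file must have columns: ", paste(need, collapse = ", "))
  if (is.null(universe)) universe <- sort(unique(c(df$tf, df$target)))
  tfs <- unique(df$tf)
  regulons <- lapply(tfs, function(tf) {
    sub <- df[df$tf == tf, , drop = FALSE]
    list(tf = tf,
         targets = sub$target,
         mi = stats::setNames(sub$mi, sub$target),
         mode = stats::setNames(as.integer(sub$mode), sub$target),
         bootstrap_support = stats::setNames(sub$bootstrap_support, sub$target))
  })
  names(regulons) <- tfs
  new_network(regulons, universe = universe, params = list())
}
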