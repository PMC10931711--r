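#' @useDynLib irapass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test pnorm qnorm qbeta rbeta rnorm runif rexp
#'   rgamma rbinom quantile sd setNames complete.cases p.adjust pt coef
#'   predict glm binomial as.formula median
#' @importFrom utils head read.delim write.table modifyList packageVersion
NULL

comment_header <- function(what, params = list()) {
  p <- if (length(params))
    paste(names(params), vapply(params, function(x) paste(format(x), collapse = ","), ""),
          sep = "=", collapse = "; ") else ""
  sprintf("# irapass %s | %s%s",
          as.character(utils::packageVersion("irapass")), what,
          if (nzchar(p)) paste0(" | ", p) else "")
}

write_tsv_commented <- function(df, path, what, params = list(), row_names = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment_header(what, params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = row_names,
              col.names = TRUE, na = "")
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  read.delim(path, comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = "", ...)
}

#' Construct a validated PDUI table
#'
#' A PDUI table is an events x samples numeric matrix of Percentage of Distal
#' polyA site Usage Index values in \[0,1\] (NA allowed), with canonical
#' `"GENE|chrom|site"` row names and unique sample column names.
#'
#' @param values numeric matrix (events x samples); rownames are event ids,
#'   colnames are sample ids.
#' @return the matrix with class `c("pdui_table","matrix","array")`.
#' @export
pdui_table <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("pdui_table requires event-id rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate event ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  parse_event_id(rownames(values))  # validates format
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("PDUI values must lie in [0,1]")
  class(values) <- c("pdui_table", class(matrix()))
  values
}

#' Construct a validated expression table
#'
#' @param values non-negative numeric matrix (genes x samples, TPM scale).
#' @return the matrix with class `c("expression_table","matrix","array")`.
#' @export
expression_table <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression_table requires gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  class(values) <- c("expression_table", class(matrix()))
  values
}

RESPONSE_LEVELS <- c("PRCR", "PDSD")

#' Construct a validated clinical table
#'
#' @param df data.frame with columns `sample_id`, `response` (one of
#'   `"PRCR"` responders, `"PDSD"` non-responders, or NA), `os_time`
#'   (overall survival, days, > 0), `os_event` (logical/0-1 death indicator),
#'   plus optional numeric covariate columns (e.g. `ImmuneScore`).
#' @return the validated data.frame with class `clinical_table`.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("sample_id", "response", "os_time", "os_event")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  bad <- !is.na(df$response) & !(df$response %in% RESPONSE_LEVELS)
  if (any(bad))
    stop("unknown response label(s): ", paste(unique(df$response[bad]), collapse = ", "),
         " (allowed: PRCR, PDSD, NA)")
  if (any(!is.na(df$os_time) & df$os_time <= 0)) stop("os_time must be > 0")
  df$os_event <- as.logical(df$os_event)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (pathway name -> gene symbols).
#' @param provenance free-text origin string (e.g. GMT file name).
#' @return list with class `gene_set_collection` and attribute `provenance`.
#' @export
gene_set_collection <- function(sets, provenance = "unspecified") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stop("pathway names required")
  if (anyDuplicated(names(sets))) stop("duplicate pathway names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(vapply(sets, length, 1L) == 0L)) stop("empty gene set")
  structure(sets, class = "gene_set_collection", provenance = provenance)
}

#' Construct a validated protein-interaction table
#'
#' Self-loops are dropped; duplicate undirected pairs are collapsed keeping
#' the maximum combined score.
#'
#' @param df data.frame with columns `gene_a`, `gene_b`, `combined_score`
#'   (integers on the STRING 0-1000 scale).
#' @return data.frame of unique undirected edges, class `interaction_table`.
#' @export
interaction_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("gene_a", "gene_b", "combined_score")
  if (!all(req %in% names(df))) stop("interaction table needs columns ", paste(req, collapse = ", "))
  s <- df$combined_score
  if (any(is.na(s)) || any(s != trunc(s)))
    stop("combined_score must be integer-valued")
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  if (nrow(df)) {
    a <- pmin(df$gene_a, df$gene_b)
    b <- pmax(df$gene_a, df$gene_b)
    key <- paste(a, b, sep = "\r")
    o <- order(key, -df$combined_score)
    df <- data.frame(gene_a = a[o], gene_b = b[o],
                     combined_score = as.integer(df$combined_score[o]),
                     stringsAsFactors = FALSE)
    df <- df[!duplicated(paste(df$gene_a, df$gene_b, sep = "\r")), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Read a PDUI table
#'
#' The `canonical` dialect expects a TSV whose first column (`event_id`)
#' holds `"GENE|chrom|site"` identifiers and whose remaining columns are
#' per-sample PDUI values. The `dapars2` dialect expects DaPars2-style rows:
#' a first column with four-field transcript ids
#' (`"transcript|GENE|chrom|strand"`), a `Predicted_Proximal_APA` coordinate
#' column, and per-sample PDUI columns; transcripts are collapsed to one row
#' per gene, keeping the transcript with the fewest missing PDUI values
#' (ties broken by file order), and ids are rewritten to the canonical form.
#' Empty fields are preserved as missing.
#'
#' @param path TSV file path.
#' @param dialect `"canonical"` or `"dapars2"`.
#' @return a [pdui_table()].
#' @export
read_pdui_table <- function(path, dialect = c("canonical", "dapars2")) {
  dialect <- match.arg(dialect)
  df <- read_tsv_commented(path)
  if (ncol(df) < 2) stop("PDUI file needs an id column and >= 1 sample column")
  if (dialect == "canonical") {
    ids <- as.character(df[[1]])
    parsed <- tryCatch(parse_event_id(ids), error = function(e)
      stop("while parsing event ids in ", path, ": ", conditionMessage(e)))
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- parsed$event_id
    return(pdui_table(m))
  }
  # dapars2
  if (!"Predicted_Proximal_APA" %in% names(df))
    stop("dapars2 dialect requires a Predicted_Proximal_APA column")
  raw_ids <- strsplit(as.character(df[[1]]), "|", fixed = TRUE)
  bad <- which(vapply(raw_ids, length, 1L) != 4L)
  if (length(bad))
    stop("malformed DaPars2 id at data row ", bad[1], ": ", df[[1]][bad[1]])
  gene <- vapply(raw_ids, `[[`, "", 2L)
  chrom <- vapply(raw_ids, `[[`, "", 3L)
  site <- as.numeric(df$Predicted_Proximal_APA)
  drop_cols <- c(names(df)[1], "Predicted_Proximal_APA", "fit_value", "Loci")
  m <- as.matrix(df[, setdiff(names(df), drop_cols), drop = FALSE])
  storage.mode(m) <- "double"
  # one row per gene: keep the transcript with the fewest missing PDUIs
  n_miss <- rowSums(is.na(m))
  keep <- order(gene, n_miss)
  keep <- keep[!duplicated(gene[keep])]
  keep <- sort(keep)  # restore file order among survivors
  m <- m[keep, , drop = FALSE]
  rownames(m) <- event_id(gene[keep], chrom[keep], site[keep])
  pdui_table(m)
}

#' @rdname read_pdui_table
#' @param pdui a [pdui_table()].
#' @export
write_pdui_table <- function(pdui, path) {
  df <- data.frame(event_id = rownames(pdui), as.data.frame(unclass(pdui)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(df, path, "pdui_table")
}

#' Read / write an expression table (genes x samples TPM)
#'
#' @param path TSV path; first column gene ids, remaining columns samples.
#' @return an [expression_table()].
#' @export
read_expression <- function(path) {
  df <- read_tsv_commented(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  expression_table(m)
}

#' @rdname read_expression
#' @param expr an [expression_table()].
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(df, path, "expression_table")
}

#' Read / write a clinical table
#'
#' @param path TSV with columns sample_id, response, os_time, os_event and
#'   optional numeric covariates.
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- read_tsv_commented(path)
  clinical_table(df)
}

#' @rdname read_clinical
#' @param clinical a [clinical_table()].
#' @export
write_clinical <- function(clinical, path) {
  write_tsv_commented(as.data.frame(clinical), path, "clinical_table")
}

#' Read a GMT gene-set file
#'
#' Standard MSigDB format: one pathway per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`; the description field is
#' discarded and duplicate genes within a line are de-duplicated.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 3))
    stop("GMT parse error at line ", which(nf < 3)[1], ": fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  gene_set_collection(sets, provenance = path)
}

#' @rdname read_gmt
#' @param sets a [gene_set_collection()].
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-style interaction TSV
#'
#' Expects two node columns and an integer combined-score column (0-1000).
#' Edges with `combined_score <= min_score` are dropped (strict inequality:
#' the default keeps scores greater than 700), self-loops removed, and
#' duplicate undirected pairs collapsed keeping the maximum score.
#'
#' @param path TSV path with a header row.
#' @param min_score integer threshold; strict `>` filter. Default 700.
#' @return an [interaction_table()].
#' @export
read_interactions <- function(path, min_score = 700) {
  df <- read_tsv_commented(path)
  if (nrow(df) == 0)
    return(interaction_table(data.frame(gene_a = character(), gene_b = character(),
                                        combined_score = integer())))
  if (ncol(df) < 3) stop("interaction file needs node, node, score columns")
  sc <- df[[3]]
  if (!is.numeric(sc) || any(is.na(sc)) || any(sc != trunc(sc)))
    stop("combined score column must be integer-valued")
  out <- data.frame(gene_a = as.character(df[[1]]), gene_b = as.character(df[[2]]),
                    combined_score = as.integer(sc), stringsAsFactors = FALSE)
  out <- out[out$combined_score > min_score, , drop = FALSE]
  interaction_table(out)
}

#' @rdname read_interactions
#' @param edges an [interaction_table()].
#' @export
write_interactions <- function(edges, path) {
  write_tsv_commented(as.data.frame(edges), path, "interaction_table")
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path file path; blank lines and `#` comments ignored.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Write / read a differential-APA result table
#'
#' @param res a `diff_apa_result` data.frame (see [call_differential()]).
#' @param path TSV path.
#' @export
write_diff_apa <- function(res, path) {
  write_tsv_commented(as.data.frame(res), path, "diff_apa_result",
                      params = attributes(res)[c("delta_threshold", "p_threshold")])
}

#' @rdname write_diff_apa
#' @export
read_diff_apa <- function(path) {
  df <- read_tsv_commented(path)
  class(df) <- c("diff_apa_result", "data.frame")
  df
}

#' Intersect and align the samples of two tables
#'
#' Any operation consuming two tables first intersects their sample ids,
#' preserving the order of the first argument; the intersection size is
#' reported via `message()`.
#'
#' @param a,b character vectors of sample ids.
#' @return character vector of shared sample ids, in `a`'s order.
#' @export
align_samples <- function(a, b) {
  shared <- a[a %in% b]
  message("aligned samples: ", length(shared), " shared of ",
          length(a), " x ", length(b))
  shared
}
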