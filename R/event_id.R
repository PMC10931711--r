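#' APA event identifiers
#'
#' An APA event is identified by its parental gene symbol, chromosome and the
#' genomic coordinate of the predicted proximal polyadenylation site, and is
#' serialized as \code{"GENE|chrom|site"} (e.g. \code{"AIM2|chr1|159062567"}).
#' Gene symbols may themselves contain hyphens (\code{"GTF3C2-AS1"}) but never
#' pipes, so the three-field form round-trips losslessly.
#'
#' @param gene_symbol character vector of gene symbols.
#' @param chrom character vector of chromosome names (non-empty).
#' @param proximal_site integer-valued vector of non-negative 1-based genomic
#'   coordinates of the proximal polyA site.
#' @return `event_id()` returns a character vector of canonical ids;
#'   `parse_event_id()` returns a data.frame with columns `event_id`,
#'   `gene_symbol`, `chrom`, `proximal_site`.
#' @examples
#' event_id("AIM2", "chr1", 159062567)
#' parse_event_id("AIM2|chr1|159062567")
#' @export
event_id <- function(gene_symbol, chrom, proximal_site) {
  gene_symbol <- as.character(gene_symbol)
  chrom <- as.character(chrom)
  site <- proximal_site
  if (any(!nzchar(gene_symbol))) stop("gene_symbol must be non-empty")
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  if (any(grepl("|", c(gene_symbol, chrom), fixed = TRUE)))
    stop("gene_symbol/chrom must not contain '|'")
  if (any(is.na(site)) || any(site < 0) || any(site != trunc(site)))
    stop("proximal_site must be a non-negative integer coordinate")
  sprintf("%s|%s|%s", gene_symbol, chrom, format(site, scientific = FALSE, trim = TRUE))
}

#' @param id character vector of serialized event ids.
#' @rdname event_id
#' @export
parse_event_id <- function(id) {
  parts <- strsplit(as.character(id), "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop("malformed event id (expected 'GENE|chrom|site'): ",
         paste(utils::head(id[bad], 3), collapse = ", "))
  gene <- vapply(parts, `[[`, "", 1L)
  chrom <- vapply(parts, `[[`, "", 2L)
  site_chr <- vapply(parts, `[[`, "", 3L)
  site <- suppressWarnings(as.numeric(site_chr))
  if (any(is.na(site) | site < 0 | site != trunc(site)))
    stop("malformed event id (proximal site not a non-negative integer): ",
         paste(utils::head(id[is.na(site) | site < 0], 3), collapse = ", "))
  if (any(!nzchar(gene)) || any(!nzchar(chrom)))
    stop("malformed event id (empty gene or chromosome field)")
  data.frame(event_id = event_id(gene, chrom, site),
             gene_symbol = gene, chrom = chrom, proximal_site = site,
             stringsAsFactors = FALSE)
}

#' Parental gene symbols of event ids
#'
#' @param id character vector of `"GENE|chrom|site"` ids.
#' @return character vector of gene symbols.
#' @export
event_gene <- function(id) parse_event_id(id)$gene_symbol
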