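#' Taxonomy table: OTU lineages
#'
#' Maps each OTU to a ranked lineage (kingdom through genus). Only the
#' phylum is required for the composition summaries; deeper ranks default
#' to `"unclassified"`.
#'
#' @param x a data frame with column `otu_id` and one or more of the rank
#'   columns `kingdom`, `phylum`, `class`, `order`, `family`, `genus`.
#' @return a `taxonomy_table` (data frame with `otu_id` and all six rank
#'   columns).
#' @export
taxonomy_table <- function(x) {
  if (!is.data.frame(x) || !"otu_id" %in% names(x)) {
    stop("taxonomy needs a data frame with an otu_id column", call. = FALSE)
  }
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  d <- data.frame(otu_id = as.character(x$otu_id), stringsAsFactors = FALSE)
  for (r in ranks) {
    v <- if (r %in% names(x)) as.character(x[[r]]) else rep("unclassified", nrow(d))
    v[is.na(v) | v == ""] <- "unclassified"
    d[[r]] <- v
  }
  if (anyDuplicated(d$otu_id)) {
    stop("duplicate otu_id in taxonomy: ",
         paste(unique(d$otu_id[duplicated(d$otu_id)]), collapse = ", "),
         call. = FALSE)
  }
  class(d) <- c("taxonomy_table", "data.frame")
  d
}

#' Look up a taxonomic rank for a set of OTUs
#'
#' @param taxonomy a `taxonomy_table`.
#' @param otu_ids character vector of OTU identifiers.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return character vector of rank labels, in the order of `otu_ids`.
#'   OTUs absent from the taxonomy are an error.
#' @export
taxon_of <- function(taxonomy, otu_ids, rank = "phylum") {
  rank <- match.arg(rank,
                    c("kingdom", "phylum", "class", "order", "family", "genus"))
  if (!inherits(taxonomy, "taxonomy_table")) taxonomy <- taxonomy_table(taxonomy)
  idx <- match(otu_ids, taxonomy$otu_id)
  if (anyNA(idx)) {
    stop("OTUs without a taxonomy entry: ",
         paste(utils::head(otu_ids[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  taxonomy[[rank]][idx]
}

# Parse one greengenes-style lineage string "k__Bacteria;p__Firmicutes;..."
# into the six canonical ranks; bare labels without the "x__" prefix are
# accepted positionally.
parse_lineage <- function(s) {
  ranks <- c(k = "kingdom", p = "phylum", c = "class",
             o = "order", f = "family", g = "genus")
  out <- stats::setNames(rep("unclassified", 6L), unname(ranks))
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  pos <- 0L
  for (p in parts) {
    if (p == "") next
    if (grepl("^[kpcofgs]__", p)) {
      key <- substr(p, 1L, 1L)
      val <- sub("^[kpcofgs]__", "", p)
      if (key %in% names(ranks) && nzchar(val)) out[ranks[[key]]] <- val
      pos <- match(key, names(ranks), nomatch = pos)
    } else {
      pos <- pos + 1L
      if (pos <= 6L && nzchar(p)) out[pos] <- p
    }
  }
  out
}
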