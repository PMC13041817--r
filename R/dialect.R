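# Column dialect for tabular interaction lists.
#
# Interaction tables in the wild use either "Regulator*/Regulated*" or
# "Source*/Target*" paired headers; the canonical internal names are fixed
# here and the alias map is user-extensible.

#' Canonical interaction-table columns
#'
#' The fixed internal column set every reader maps onto. All columns are
#' character except `score`, which is numeric. `src_identifier` /
#' `tgt_identifier` are derived at read time from the identity columns with
#' precedence database ID > symbol > name; `src_id_source` records which one
#' was used. `src_key` / `tgt_key` are the element identity keys
#' (identifier + type) that define node identity in the baseline graph.
#'
#' @return Character vector of canonical column names.
#' @export
canonical_columns <- function() {
  c(
    "src_name", "src_db_id", "src_symbol", "src_identifier", "src_id_source",
    "src_type", "src_compartment", "src_compartment_id",
    "tgt_name", "tgt_db_id", "tgt_symbol", "tgt_identifier", "tgt_id_source",
    "tgt_type", "tgt_compartment", "tgt_compartment_id",
    "sign", "connection", "mechanism",
    "cell_line", "cell_type", "tissue", "organism", "context_other",
    "paper_ids", "evidence", "score",
    "src_key", "tgt_key"
  )
}

#' Default header-alias map for the tabular interaction dialect
#'
#' Maps canonical internal columns to the header spellings accepted on
#' input. Header comparison is case-insensitive after collapsing
#' whitespace and the punctuation characters `._-` to single spaces. Extend
#' or override entries to support converter-specific headers:
#' `read_interactions(path, dialect = modifyList(biorecipe_dialect(),
#' list(cell_line = c("cell line", "cellline"))))`.
#'
#' @return Named list: canonical column -> character vector of aliases.
#' @export
biorecipe_dialect <- function() {
  list(
    src_name           = c("regulator name", "source name", "regulator", "source"),
    src_db_id          = c("regulator id", "source id", "regulator database id",
                           "source database id"),
    src_symbol         = c("regulator hgnc symbol", "regulator symbol",
                           "source hgnc symbol", "source symbol"),
    src_type           = c("regulator type", "source type"),
    src_compartment    = c("regulator compartment", "source compartment",
                           "regulator location", "source location"),
    src_compartment_id = c("regulator compartment id", "source compartment id"),
    tgt_name           = c("regulated name", "target name", "regulated", "target"),
    tgt_db_id          = c("regulated id", "target id", "regulated database id",
                           "target database id"),
    tgt_symbol         = c("regulated hgnc symbol", "regulated symbol",
                           "target hgnc symbol", "target symbol"),
    tgt_type           = c("regulated type", "target type"),
    tgt_compartment    = c("regulated compartment", "target compartment",
                           "regulated location", "target location"),
    tgt_compartment_id = c("regulated compartment id", "target compartment id"),
    sign               = c("sign", "interaction sign", "regulation sign", "effect"),
    connection         = c("connection type", "connection", "direct"),
    mechanism          = c("mechanism", "interaction mechanism"),
    cell_line          = c("cell line"),
    cell_type          = c("cell type"),
    tissue             = c("tissue type", "tissue"),
    organism           = c("organism", "species"),
    context_other      = c("context", "other context", "context other"),
    paper_ids          = c("paper ids", "paper id", "pmid", "pmcid"),
    evidence           = c("evidence", "statements", "evidence text"),
    score              = c("score", "reader score", "belief score")
  )
}

normalize_header <- function(x) {
  stringr::str_squish(stringr::str_replace_all(stringr::str_to_lower(x), "[._-]", " "))
}

# Map raw headers to canonical names; first alias hit wins, first matching
# raw column wins for a given canonical name.
map_headers <- function(headers, dialect) {
  norm <- normalize_header(headers)
  out <- setNames(rep(NA_character_, length(dialect)), names(dialect))
  for (canon in names(dialect)) {
    hit <- which(norm %in% dialect[[canon]])
    if (length(hit) > 0) out[[canon]] <- headers[hit[1L]]
  }
  out
}
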