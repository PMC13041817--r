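# Reading and writing tabular interaction lists.

#' Read a tabular interaction list
#'
#' Reads a delimited table (tab or comma) or a spreadsheet with one directed,
#' signed interaction per row, maps its headers onto the canonical column set
#' through the dialect alias map, and normalizes element identity and
#' attribute values. Rows missing a source or target identity are rejected
#' and reported (row-indexed) via a warning and the `"rejected"` attribute,
#' never silently dropped.
#'
#' Element identifiers follow the precedence database ID > symbol > name
#' when several identity columns are populated; the column actually used is
#' recorded in `src_id_source` / `tgt_id_source`. Sign values are mapped
#' through an explicit vocabulary (`default_sign_map()`); unknown values are
#' an error, never guessed. A missing connection type defaults to
#' `"indirect"`.
#'
#' @param path Path to a `.tsv`/`.txt`, `.csv`, or `.xlsx`/`.xls` file with a
#'   header row.
#' @param role `"new_list"` or `"baseline"`; stored as the `source_label`
#'   attribute and echoed in downstream reports.
#' @param dialect Header alias map, see [biorecipe_dialect()].
#' @param sign_map Sign vocabulary table, see [default_sign_map()].
#' @return A tibble with the columns of [canonical_columns()], one row per
#'   accepted input row, input order preserved (duplicates retained).
#'   Attributes: `source_label`, `role`, and `rejected` (tibble of dropped
#'   rows with `row` and `reason`).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(paste(
#'   c("Regulator Name\tRegulated Name\tSign\tConnection Type",
#'     "LKB1\tAMPK\tpositive\tdirect"), collapse = "\n"), f)
#' read_interactions(f, role = "baseline")
read_interactions <- function(path,
                              role = c("new_list", "baseline"),
                              dialect = biorecipe_dialect(),
                              sign_map = default_sign_map()) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    abort(paste0("cannot read interaction file: '", path, "' does not exist"),
          class = "netreconcile_io_error")
  }
  raw <- read_raw_table(path)
  build_interaction_tbl(raw, role = role, dialect = dialect,
                        sign_map = sign_map,
                        source_label = basename(path))
}

read_raw_table <- function(path) {
  ext <- stringr::str_to_lower(tools::file_ext(path))
  raw <- tryCatch(
    {
      if (ext %in% c("xlsx", "xls")) {
        readxl::read_excel(path, col_types = "text")
      } else {
        first <- readLines(path, n = 1L, warn = FALSE)
        delim <- if (stringr::str_count(first, "\t") >=
                     stringr::str_count(first, ",")) "\t" else ","
        readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
      }
    },
    error = function(e) {
      abort(paste0("cannot read interaction file '", path, "': ",
                   conditionMessage(e)),
            class = "netreconcile_io_error")
    }
  )
  as_tibble(raw)
}

#' Convert a raw data frame of interactions to the canonical table
#'
#' The workhorse behind [read_interactions()], exposed so in-memory data
#' frames (e.g. from converters or the fixture generator) can be normalized
#' without a file round-trip.
#'
#' @param raw Data frame with dialect headers, one interaction per row.
#' @inheritParams read_interactions
#' @param source_label Label recorded on the result.
#' @return Canonical interaction tibble; see [read_interactions()].
#' @export
build_interaction_tbl <- function(raw,
                                  role = c("new_list", "baseline"),
                                  dialect = biorecipe_dialect(),
                                  sign_map = default_sign_map(),
                                  source_label = "memory") {
  role <- match.arg(role)
  cmap <- map_headers(names(raw), dialect)

  get_col <- function(canon) {
    src <- cmap[[canon]]
    if (is.na(src)) rep(NA_character_, nrow(raw)) else as.character(raw[[src]])
  }

  if (all(is.na(cmap[c("src_name", "src_db_id", "src_symbol")]))) {
    abort("no recognized regulator/source identity column (need one of: regulator name, regulator id, regulator hgnc symbol, or a source-prefixed equivalent)",
          class = "netreconcile_format_error")
  }
  if (all(is.na(cmap[c("tgt_name", "tgt_db_id", "tgt_symbol")]))) {
    abort("no recognized regulated/target identity column (need one of: regulated name, regulated id, regulated hgnc symbol, or a target-prefixed equivalent)",
          class = "netreconcile_format_error")
  }
  if (is.na(cmap[["sign"]])) {
    abort("no recognized sign column (expected one of: sign, interaction sign, regulation sign, effect)",
          class = "netreconcile_format_error")
  }

  n <- nrow(raw)
  tbl <- tibble(
    src_name           = normalize_identity(get_col("src_name")),
    src_db_id          = normalize_identity(get_col("src_db_id")),
    src_symbol         = normalize_identity(get_col("src_symbol")),
    src_type           = normalize_element_type(get_col("src_type")),
    src_compartment    = normalize_identity(get_col("src_compartment")),
    src_compartment_id = normalize_identity(get_col("src_compartment_id")),
    tgt_name           = normalize_identity(get_col("tgt_name")),
    tgt_db_id          = normalize_identity(get_col("tgt_db_id")),
    tgt_symbol         = normalize_identity(get_col("tgt_symbol")),
    tgt_type           = normalize_element_type(get_col("tgt_type")),
    tgt_compartment    = normalize_identity(get_col("tgt_compartment")),
    tgt_compartment_id = normalize_identity(get_col("tgt_compartment_id")),
    sign_raw           = normalize_identity(get_col("sign")),
    connection         = normalize_connection(get_col("connection")),
    mechanism          = normalize_identity(get_col("mechanism")),
    cell_line          = normalize_identity(get_col("cell_line")),
    cell_type          = normalize_identity(get_col("cell_type")),
    tissue             = normalize_identity(get_col("tissue")),
    organism           = normalize_identity(get_col("organism")),
    context_other      = normalize_identity(get_col("context_other")),
    paper_ids          = normalize_identity(get_col("paper_ids")),
    evidence           = get_col("evidence"),
    score              = suppressWarnings(as.numeric(get_col("score")))
  )
  tbl$evidence[is.na(tbl$evidence)] <- ""

  pick <- function(db, sym, nm) {
    src <- dplyr::case_when(
      !is_blank(db)  ~ "database_id",
      !is_blank(sym) ~ "symbol",
      !is_blank(nm)  ~ "name",
      TRUE           ~ NA_character_
    )
    id <- dplyr::case_when(
      src == "database_id" ~ db,
      src == "symbol"      ~ sym,
      src == "name"        ~ nm,
      TRUE                 ~ ""
    )
    list(id = id, src = src)
  }
  s <- pick(tbl$src_db_id, tbl$src_symbol, tbl$src_name)
  t <- pick(tbl$tgt_db_id, tbl$tgt_symbol, tbl$tgt_name)
  tbl$src_identifier <- s$id
  tbl$src_id_source  <- s$src
  tbl$tgt_identifier <- t$id
  tbl$tgt_id_source  <- t$src

  bad_identity <- is.na(tbl$src_id_source) | is.na(tbl$tgt_id_source)
  rejected <- tibble(
    row = which(bad_identity),
    reason = ifelse(is.na(tbl$src_id_source[bad_identity]) &
                      is.na(tbl$tgt_id_source[bad_identity]),
                    "missing source and target identity",
                    ifelse(is.na(tbl$src_id_source[bad_identity]),
                           "missing source identity", "missing target identity"))
  )
  if (nrow(rejected) > 0) {
    warn(paste0(nrow(rejected), " row(s) rejected for missing identity: row ",
                paste(rejected$row, collapse = ", ")))
  }
  tbl <- tbl[!bad_identity, , drop = FALSE]

  sign_lookup <- setNames(sign_map$sign, sign_map$value)
  mapped <- unname(sign_lookup[tbl$sign_raw])
  bad_sign <- is.na(mapped)
  if (any(bad_sign)) {
    offending <- unique(tbl$sign_raw[bad_sign])
    abort(paste0("unmappable sign value(s): ",
                 paste0("'", offending, "'", collapse = ", "),
                 " (rows ", paste(which(bad_sign), collapse = ", "),
                 "); extend sign_map to accept them"),
          class = "netreconcile_row_error")
  }
  tbl$sign <- mapped
  tbl$sign_raw <- NULL

  tbl$src_key <- element_key(tbl$src_identifier, tbl$src_type)
  tbl$tgt_key <- element_key(tbl$tgt_identifier, tbl$tgt_type)
  tbl <- tbl[, canonical_columns()]

  attr(tbl, "source_label") <- source_label
  attr(tbl, "role") <- role
  attr(tbl, "rejected") <- rejected
  tbl
}

# Output headers for write_classified(); chosen so that the default dialect
# maps them straight back onto the canonical columns on re-read.
output_headers <- c(
  src_name = "Regulator Name", src_db_id = "Regulator ID",
  src_symbol = "Regulator HGNC Symbol", src_type = "Regulator Type",
  src_compartment = "Regulator Compartment",
  src_compartment_id = "Regulator Compartment ID",
  tgt_name = "Regulated Name", tgt_db_id = "Regulated ID",
  tgt_symbol = "Regulated HGNC Symbol", tgt_type = "Regulated Type",
  tgt_compartment = "Regulated Compartment",
  tgt_compartment_id = "Regulated Compartment ID",
  sign = "Sign", connection = "Connection Type", mechanism = "Mechanism",
  cell_line = "Cell Line", cell_type = "Cell Type", tissue = "Tissue Type",
  organism = "Organism", context_other = "Context",
  paper_ids = "Paper IDs", evidence = "Evidence", score = "Score"
)

#' Write a classified interaction list
#'
#' Writes a tab-delimited table with the interaction columns plus
#' `Category`, `Subcategory`, `MatchedBaseline` and `Mismatches`, in input
#' row order. The output re-reads cleanly with [read_interactions()].
#'
#' @param classified Result of [classify_interactions()] (or any canonical
#'   interaction tibble carrying `category`, `subcategory`, `matched_desc`,
#'   `mismatch_desc` columns; blanks are written for any that are absent).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_classified <- function(classified, path) {
  out <- tibble::tibble(.rows = nrow(classified))
  for (canon in names(output_headers)) {
    vals <- if (canon %in% names(classified)) classified[[canon]] else ""
    out[[output_headers[[canon]]]] <- vals
  }
  grab <- function(col) {
    if (col %in% names(classified)) as.character(classified[[col]]) else ""
  }
  out[["Category"]] <- grab("category")
  out[["Subcategory"]] <- grab("subcategory")
  out[["MatchedBaseline"]] <- grab("matched_desc")
  out[["Mismatches"]] <- grab("mismatch_desc")
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) {
      abort(paste0("cannot write classified list to '", path, "': ",
                   conditionMessage(e)),
            class = "netreconcile_io_error")
    }
  )
  invisible(path)
}

#' Deduplicate an interaction list
#'
#' Uniqueness is over the tuple (source identity key, target identity key,
#' sign, connection); the first occurrence of each tuple is retained, so the
#' unique count is order-insensitive but the representative rows follow
#' input order.
#'
#' @param tbl Canonical interaction tibble.
#' @return Deduplicated tibble; the original row count is kept in the
#'   `n_total` attribute.
#' @export
distinct_interactions <- function(tbl) {
  out <- dplyr::distinct(tbl, .data$src_key, .data$tgt_key, .data$sign,
                         .data$connection, .keep_all = TRUE)
  attr(out, "n_total") <- nrow(tbl)
  out
}
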