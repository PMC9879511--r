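# Drug table and DDI tuple table reading/writing (CSV or TSV by extension).

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "")
}

.write_table <- function(df, path) {
  sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a drug table
#'
#' Expects a CSV/TSV file with header columns `id` and `smiles`.
#'
#' @param path file path (`.tsv`/`.tab` read as tab-separated, otherwise
#'   comma-separated).
#' @return data frame with character columns `id` and `smiles`.
#' @export
read_drug_table <- function(path) {
  df <- .read_table(path)
  miss <- setdiff(c("id", "smiles"), names(df))
  if (length(miss) > 0)
    stop("drug table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$id <- as.character(df$id)
  df$smiles <- as.character(df$smiles)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0)
    stop("duplicate drug id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  df[, c("id", "smiles")]
}

#' @rdname read_drug_table
#' @param drugs data frame as returned by [read_drug_table()].
#' @export
write_drug_table <- function(drugs, path) {
  .write_table(drugs[, c("id", "smiles")], path)
  invisible(path)
}

#' Read a DDI tuple table
#'
#' Expects a CSV/TSV file with header columns `drug_x`, `drug_y`, `type`
#' and optionally `label` (defaults to 1, i.e. observed positives). Every
#' drug id must resolve in `drugs`. Interaction type ids are densified to
#' `0..K-1` if needed; the mapping is attached as attribute
#' `relation_map` (a data frame with columns `original`, `relabeled`).
#'
#' @param path file path.
#' @param drugs drug table used to resolve ids.
#' @return data frame with columns `drug_x`, `drug_y`, `type` (integer,
#'   dense from 0) and `label` (0/1).
#' @export
read_ddi_table <- function(path, drugs) {
  df <- .read_table(path)
  miss <- setdiff(c("drug_x", "drug_y", "type"), names(df))
  if (length(miss) > 0)
    stop("DDI table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$drug_x <- as.character(df$drug_x)
  df$drug_y <- as.character(df$drug_y)
  bad <- !(df$drug_x %in% drugs$id) | !(df$drug_y %in% drugs$id)
  if (any(bad)) {
    rows <- which(bad)
    ids <- setdiff(unique(c(df$drug_x[rows], df$drug_y[rows])), drugs$id)
    stop("unknown drug id(s) ", paste(ids, collapse = ", "),
         " in DDI table row(s) ", paste(utils::head(rows, 10), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$label)) df$label <- 1L
  if (!all(df$label %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  df$type <- as.integer(df$type)
  types <- sort(unique(df$type))
  out <- df[, c("drug_x", "drug_y", "type", "label")]
  if (!identical(types, seq_along(types) - 1L)) {
    map <- data.frame(original = types, relabeled = seq_along(types) - 1L)
    out$type <- map$relabeled[match(out$type, map$original)]
    attr(out, "relation_map") <- map
    message("relation ids were not dense; relabeled ",
            length(types), " type(s) to 0..", length(types) - 1L)
  }
  out
}

#' @rdname read_ddi_table
#' @param tuples data frame of DDI tuples.
#' @export
write_ddi_table <- function(tuples, path) {
  .write_table(tuples[, intersect(c("drug_x", "drug_y", "type", "label"),
                                  names(tuples))], path)
  invisible(path)
}

#' Parse all drugs of a drug table into molecular graphs
#'
#' @param drugs drug table (`id`, `smiles`).
#' @return named list of `molecular_graph` objects, one per drug id.
#' @export
parse_drug_table <- function(drugs) {
  gs <- lapply(drugs$smiles, parse_smiles)
  names(gs) <- drugs$id
  gs
}
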