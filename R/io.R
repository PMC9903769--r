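#' @name magscape-io
#' @title Tabular input/output
#'
#' @description
#' Every intermediate in the pipeline is a tab-separated table with a
#' mandatory header, decimal points and no thousands separators. Each table
#' obeys a named schema (column names, types and primary key) registered in
#' the package; \code{read_table()} validates on the way in and
#' \code{write_table()} writes a canonical form that round-trips losslessly.
NULL

# Schema registry: columns (name -> type among chr/num/int/lgl), primary key.
# Keys of length 2 on pair tables are order-insensitive.
.schemas <- list(
  genomes = list(
    cols = c(genome_id = "chr", length = "num", completion = "num",
             redundancy = "num", lineage = "chr", source = "chr",
             is_phytoplankton = "lgl"),
    key = "genome_id"),
  pairs = list(
    cols = c(genome_a = "chr", genome_b = "chr", ani = "num",
             aligned_fraction_smaller = "num"),
    key = c("genome_a", "genome_b"), unordered_key = TRUE),
  metagenomes = list(
    cols = c(metagenome_id = "chr", station_id = "chr", depth_layer = "chr",
             size_fraction = "chr", total_reads = "num", subset_labels = "chr"),
    key = "metagenome_id"),
  recruitment = list(
    cols = c(genome_id = "chr", metagenome_id = "chr", recruited_reads = "num",
             breadth = "num", mean_coverage = "num"),
    key = c("genome_id", "metagenome_id")),
  markers = list(
    cols = c(genome_id = "chr", marker_id = "chr", best_hit_identity = "num"),
    key = NULL),
  annotations = list(
    cols = c(gene_id = "chr", genome_id = "chr", og_id = "chr",
             og_known = "lgl", agnostos_cluster = "chr"),
    key = "gene_id"),
  function_meta = list(
    cols = c(og_id = "chr", is_retrotransposon = "lgl"),
    key = "og_id"),
  station_env = list(
    cols = c(station_id = "chr", sst = "num", salinity = "num",
             silicate = "num", nitrate = "num", phosphate = "num",
             iron = "num", si_no3 = "num"),
    key = "station_id"),
  grid = list(
    cols = c(lat = "num", lon = "num", ocean = "lgl", sst = "num",
             salinity = "num", silicate = "num", nitrate = "num",
             phosphate = "num", iron = "num", si_no3 = "num"),
    key = c("lat", "lon"))
)

#' List the registered table schemas
#' @return character vector of schema names.
#' @export
list_schemas <- function() names(.schemas)

.get_schema <- function(schema) {
  if (!schema %in% names(.schemas)) {
    stop("unknown schema '", schema, "'; known: ",
         paste(names(.schemas), collapse = ", "), call. = FALSE)
  }
  .schemas[[schema]]
}

#' Read and validate a tab-separated pipeline table
#'
#' Reads a TSV with a mandatory header, checks the columns required by the
#' named schema, coerces types, and enforces primary-key uniqueness.
#' Rows whose values fail type coercion are reported with their file line
#' numbers; under \code{permissive = TRUE} such rows are dropped with a
#' warning instead of raising an error.
#'
#' @param path file path.
#' @param schema one of \code{\link{list_schemas}()}.
#' @param permissive downgrade row-level errors to warnings (default FALSE).
#' @return a data.frame with the schema's columns in canonical order.
#' @export
read_table <- function(path, schema, permissive = FALSE) {
  sc <- .get_schema(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA", quote = "")
  missing <- setdiff(names(sc$cols), names(df))
  if (length(missing)) {
    stop("schema error in '", path, "' (", schema, "): missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[names(sc$cols)]
  bad_rows <- integer(0)
  for (cn in names(sc$cols)) {
    raw <- df[[cn]]
    val <- switch(sc$cols[[cn]],
      chr = raw,
      num = suppressWarnings(as.numeric(raw)),
      int = suppressWarnings(as.integer(raw)),
      lgl = .parse_logical(raw))
    if (sc$cols[[cn]] != "chr") {
      bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
      bad_rows <- union(bad_rows, bad)
    }
    df[[cn]] <- val
  }
  if (length(bad_rows)) {
    # +1 for header: report 1-based file line numbers
    msg <- paste0("unparseable row(s) in '", path, "' (", schema,
                  ") at file line(s) ",
                  paste(sort(bad_rows) + 1L, collapse = ", "))
    if (permissive) {
      warning(msg, call. = FALSE)
      df <- df[-bad_rows, , drop = FALSE]
    } else {
      stop(msg, call. = FALSE)
    }
  }
  if (!is.null(sc$key) && nrow(df)) {
    keyvals <- df[sc$key]
    if (isTRUE(sc$unordered_key)) {
      a <- pmin(keyvals[[1]], keyvals[[2]])
      b <- pmax(keyvals[[1]], keyvals[[2]])
      keystr <- paste(a, b, sep = "\r")
    } else {
      keystr <- do.call(paste, c(keyvals, sep = "\r"))
    }
    dup <- duplicated(keystr)
    if (any(dup)) {
      msg <- paste0("integrity error in '", path, "' (", schema,
                    "): duplicate key(s): ",
                    paste(unique(gsub("\r", "/", keystr[dup])), collapse = ", "))
      if (permissive) {
        warning(msg, call. = FALSE)
        df <- df[!dup, , drop = FALSE]
      } else {
        stop(msg, call. = FALSE)
      }
    }
  }
  rownames(df) <- NULL
  df
}

.parse_logical <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "true", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "false", "F", "0")] <- FALSE
  out
}

#' Write a pipeline table as canonical TSV
#'
#' @param df data.frame matching the schema.
#' @param path output path.
#' @param schema one of \code{\link{list_schemas}()}.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(df, path, schema) {
  sc <- .get_schema(schema)
  missing <- setdiff(names(sc$cols), names(df))
  if (length(missing)) {
    stop("cannot write ", schema, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- df[names(sc$cols)]
  for (cn in names(sc$cols)) {
    if (sc$cols[[cn]] == "num") {
      out[[cn]] <- format(out[[cn]], scientific = FALSE, trim = TRUE,
                          digits = 15, nsmall = 0)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
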