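# Table readers/writers for the pipeline's TSV dialects. Tables are UTF-8,
# tab-delimited, one header row, decimal point, no thousands separators.

table_schema_registry <- function() {
  ch <- "character"; num <- "numeric"; cnt <- "count"
  list(
    plate_counts = c(mouse_id = ch, host = ch, day = num, category = ch,
                     count = cnt, depth = cnt),
    markers = c(mouse_id = ch, host = ch, day = num, yfp = cnt, cfp = cnt),
    competition = c(mouse_id = ch, host = ch, housing = ch, time_h = num,
                    mutant = cnt, reference = cnt),
    resistance = c(mouse_id = ch, host = ch, day = num, antibiotic = ch,
                   resistant = cnt, total = cnt, dilution_r = num,
                   dilution_t = num),
    growth_curve = c(medium = ch, time_h = num, od = num),
    calibration = c(sample = ch, replicate = num,
                    median_fluorescence = num, rate_per_hour = num),
    hybridization = c(mouse_id = ch, day = num, replicate = num,
                      median_fluorescence = num),
    phenotype = c(mouse_id = ch, host = ch, day = num, gat_neg = cnt,
                  total = cnt),
    clone_typing = c(mouse_id = ch, clone = num, locus = ch, state = ch),
    variants = c(population = ch, host = ch, target = ch, class = ch,
                 frequency = num)
  )
}

#' Names of the supported table schemas
#' @return Character vector of schema names.
#' @export
table_schemas <- function() names(table_schema_registry())

#' Read and validate a pipeline table
#'
#' Reads a tab-delimited table and validates it against one of the named
#' schemas: all schema columns must be present, numeric columns must parse,
#' and count columns must be non-negative. Validation errors name the
#' offending row and column.
#'
#' @param path Path to a TSV file.
#' @param schema Schema name; see [table_schemas()].
#' @return A data.frame of validated records (extra columns are kept).
#'   An empty table (header only) is returned with a warning.
#' @export
read_table <- function(path, schema) {
  reg <- table_schema_registry()
  if (!schema %in% names(reg))
    stop_invalid("unknown schema '", schema, "'; available: ",
                 paste(names(reg), collapse = ", "))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- reg[[schema]]
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(spec), names(d))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s for schema '%s'", path,
                 paste(missing, collapse = ", "), schema), call. = FALSE)
  if (!nrow(d)) {
    warning(path, ": empty table (header only)", call. = FALSE)
  }
  for (col in names(spec)) {
    type <- spec[[col]]
    if (type %in% c("numeric", "count")) {
      v <- suppressWarnings(as.numeric(d[[col]]))
      bad <- which(is.na(v) & !(is.na(d[[col]]) | d[[col]] == "NA"))
      if (length(bad))
        stop(sprintf("%s: non-numeric value '%s' in column '%s' at row %d",
                     path, d[[col]][bad[1]], col, bad[1]), call. = FALSE)
      if (type == "count") {
        neg <- which(v < 0)
        if (length(neg))
          stop(sprintf("%s: negative count %s in column '%s' at row %d",
                       path, format(v[neg[1]]), col, neg[1]), call. = FALSE)
      }
      d[[col]] <- v
    }
  }
  d
}

#' Write a pipeline table
#'
#' Tab-delimited UTF-8 writer matching [read_table()]; `read_table(
#' write_table(x, path), schema)` round-trips every schema.
#'
#' @param x Data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a simulation configuration from a JSON document
#'
#' The JSON mirrors [sim_config()]: scalar fields by name, plus
#' `beneficial_loci` and `resistance_loci` as arrays of objects. A
#' `preset` field may name a shipped preset instead, with any further
#' fields overriding it where the preset is itself a configuration.
#'
#' @param path Path to a JSON file.
#' @return A [sim_config()] (or the preset's parameter list for
#'   non-configuration presets).
#' @export
sim_config_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(doc$preset)) {
    p <- sim_preset(doc$preset)
    return(p)
  }
  ben <- lapply(doc$beneficial_loci, function(b)
    do.call(beneficial_locus, b))
  res <- lapply(doc$resistance_loci, function(r)
    do.call(resistance_locus, r))
  args <- doc[setdiff(names(doc), c("beneficial_loci", "resistance_loci"))]
  do.call(sim_config, c(args, list(beneficial_loci = ben,
                                   resistance_loci = res)))
}
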