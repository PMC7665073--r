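# Schema-validated CSV readers. Comma-separated, UTF-8, "." decimal, header
# mandatory; unknown columns are preserved.

#' Read and validate a CSV table against a column schema
#'
#' @param path File path.
#' @param schema Named character vector: required column -> type
#'   (`"numeric"`, `"integer"`, or `"character"`).
#' @return A tibble with required columns coerced to their declared types and
#'   any extra columns preserved. An empty file with a valid header returns
#'   an empty tibble with a warning. A missing required column, or a cell
#'   that fails numeric coercion, is an error naming the column (and row).
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop_invalid("`", basename(path), "` is missing required column(s): ",
                 paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("`", basename(path), "` has a header but no rows")
    return(tibble::as_tibble(df))
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("numeric", "integer")) {
      raw <- df[[col]]
      coerced <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(coerced) & !is.na(raw) & trimws(raw) != "")
      if (length(bad)) {
        stop_invalid("`", basename(path), "`: malformed numeric cell at row ",
                     bad[1], ", column `", col, "` (value: '",
                     raw[bad[1]], "')")
      }
      df[[col]] <- if (type == "integer") as.integer(coerced) else coerced
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  tibble::as_tibble(df)
}

#' @rdname read_table
#' @export
schema_tanks <- function() {
  c(tank_id = "character", diet = "character", n_initial = "integer",
    n_final = "integer", w_initial_g = "numeric", w_final_g = "numeric",
    feed_intake_g = "numeric", protein_fed_g = "numeric",
    duration_days = "numeric")
}

#' @rdname read_table
#' @export
schema_titration <- function() {
  c(diet = "character", replicate = "integer", phase = "character",
    volume_ml = "numeric", normality = "numeric", protein_mass_g = "numeric")
}

#' @rdname read_table
#' @export
schema_formulation <- function() {
  c(diet = "character", ingredient = "character", g_per_100g = "numeric")
}

#' @rdname read_table
#' @export
schema_prices <- function() {
  c(commodity = "character", year = "integer",
    price_usd_per_tonne = "numeric")
}

#' Read tank records from CSV
#' @param path CSV with the [schema_tanks()] columns.
#' @return Tibble of tank records.
#' @export
read_tanks <- function(path) read_table(path, schema_tanks())

#' Read titration records from CSV
#' @param path CSV with the [schema_titration()] columns.
#' @return Tibble of titration records.
#' @export
read_titration <- function(path) read_table(path, schema_titration())

#' Read diet formulations from CSV
#' @param path CSV with the [schema_formulation()] columns.
#' @return Tibble: diet, ingredient, g_per_100g.
#' @export
read_formulation <- function(path) read_table(path, schema_formulation())
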