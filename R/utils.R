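`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert fasting blood sugar between mmol/L and mg/dL
#'
#' Glucose in mg/dL equals mmol/L times 18.016 (the molar mass of glucose
#' per decilitre scaling). Reports that mix the two unit systems need this
#' constant; risk-score analyses of glucose are often run on the mg/dL scale.
#'
#' @param x numeric vector of glucose values.
#' @return `x` converted to the other unit system.
#' @export
fbs_mmol_to_mgdl <- function(x) x * 18.016

#' @rdname fbs_mmol_to_mgdl
#' @export
fbs_mgdl_to_mmol <- function(x) x / 18.016

# deterministic 32-bit sub-seed for stage `k` of a run seeded with `seed`
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647L)
}

# write a data frame as TSV with enough digits that doubles round-trip exactly
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# read a TSV written by write_tsv(); `numeric_cols` are coerced and any
# unparseable entry is reported with its file and line number
read_tsv_checked <- function(path, numeric_cols = character()) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & raw != "")
    if (length(bad)) {
      stop(sprintf("parse error in %s, line %d: column '%s' value '%s' is not numeric",
                   path, bad[1] + 1L, col, raw[bad[1]]), call. = FALSE)
    }
    df[[col]] <- num
  }
  df
}

log_stage <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}
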