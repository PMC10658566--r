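# Canonical permeation-record schema. One row = one Franz-cell observation:
# a drug permeating microneedle-treated skin, with the seven device/drug
# features plus the measured cumulative amount (ug/cm^2) and percentage.
perm_schema <- c("drug", "skin_type", "mn_type", "mn_length",
                 "mn_surface_area", "drug_loading", "permeation_time",
                 "mw", "permeation_amount", "permeation_percentage")

perm_numeric_cols <- c("mn_length", "mn_surface_area", "drug_loading",
                       "permeation_time", "mw", "permeation_amount",
                       "permeation_percentage")

# header synonyms accepted at read time (after lowercasing and squashing
# punctuation to "_")
perm_synonyms <- list(
  drug = c("drug", "drug_name", "compound"),
  skin_type = c("skin_type", "skin"),
  mn_type = c("mn_type", "needle_type", "type_of_mn", "type_of_the_mn"),
  mn_length = c("mn_length", "mn_length_um", "needle_length", "mn_length_m"),
  mn_surface_area = c("mn_surface_area", "surface_area", "surface_area_of_mn",
                      "mn_surface_area_mm2", "mn_surface_area_mm_2"),
  drug_loading = c("drug_loading", "loading", "drug_loading_ug",
                   "drug_loading_in_mn", "drug_loading_g"),
  permeation_time = c("permeation_time", "time", "time_hr", "time_h",
                      "permeation_time_hr", "permeation_time_h"),
  mw = c("mw", "mw_da", "molecular_weight"),
  permeation_amount = c("permeation_amount", "amount", "cumulative_amount",
                        "cumulative_permeation_amount",
                        "permeation_amount_ug_per_cm2"),
  permeation_percentage = c("permeation_percentage", "percentage",
                            "cumulative_percentage",
                            "cumulative_permeation_percentage")
)

canon_header <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Read a permeation dataset
#'
#' Reads a CSV of Franz-cell permeation observations into the canonical
#' ten-column schema: `drug`, `skin_type` (R/H), `mn_type`
#' (hydrogel/plastic), `mn_length` (um), `mn_surface_area` (mm^2, patch
#' total), `drug_loading` (ug), `permeation_time` (h), `mw` (Da),
#' `permeation_amount` (ug/cm^2) and `permeation_percentage` (%). Common
#' header synonyms are mapped automatically, and the value "solid" for the
#' needle type is read as "plastic" (the literature uses both names for the
#' same pre-treatment needles). Either response column may contain blanks.
#'
#' Rows with a permeation time outside 0.0833-48 h or a loading outside
#' 50-70,940 ug (the ranges the model family was built for) trigger a
#' warning; rows with a percentage above 100 are retained but flagged in
#' the `flagged_rows` attribute rather than silently dropped.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A `permeation_data` data frame, row order preserved.
#' @export
read_permeation_data <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(raw) == 0) stop("empty dataset: ", path, call. = FALSE)
  hdr <- canon_header(names(raw))
  mapped <- rep(NA_character_, length(hdr))
  for (canon in names(perm_synonyms)) {
    hit <- which(hdr %in% perm_synonyms[[canon]])
    if (length(hit)) mapped[hit[1]] <- canon
  }
  missing <- setdiff(perm_schema, mapped)
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- raw[, !is.na(mapped), drop = FALSE]
  names(df) <- mapped[!is.na(mapped)]
  df <- df[, perm_schema]
  for (col in perm_numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad)) {
        stop(sprintf("column '%s': unparseable numeric value in row %s",
                     col, paste(bad, collapse = ", ")), call. = FALSE)
      }
      v <- parsed
    }
    df[[col]] <- v
  }
  as_permeation_data(df)
}

#' Coerce a data frame to the permeation-record schema
#'
#' Validates column presence, normalizes categorical vocabularies
#' (`skin_type` to R/H, `mn_type` to hydrogel/plastic with "solid" mapped
#' to "plastic") and attaches range warnings/flags. Used by
#' [read_permeation_data()] and by the synthetic generator.
#'
#' @param df A data frame with the ten canonical columns.
#' @return A `permeation_data` data frame.
#' @export
as_permeation_data <- function(df) {
  missing <- setdiff(perm_schema, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, perm_schema]
  st <- tolower(trimws(as.character(df$skin_type)))
  st_map <- c(r = "R", rat = "R", h = "H", human = "H")
  if (any(!st %in% names(st_map))) {
    bad <- which(!st %in% names(st_map))
    stop("unknown skin_type in row ", paste(bad, collapse = ", "),
         " (expected R/rat or H/human)", call. = FALSE)
  }
  df$skin_type <- unname(st_map[st])
  mt <- tolower(trimws(as.character(df$mn_type)))
  mt_map <- c(hydrogel = "hydrogel", plastic = "plastic", solid = "plastic")
  if (any(!mt %in% names(mt_map))) {
    bad <- which(!mt %in% names(mt_map))
    stop("unknown mn_type in row ", paste(bad, collapse = ", "),
         " (expected hydrogel, plastic or solid)", call. = FALSE)
  }
  df$mn_type <- unname(mt_map[mt])

  tm <- df$permeation_time
  if (any(!is.na(tm) & (tm < 0.08333 - 1e-9 | tm > 48))) {
    warning("permeation_time outside the modelled range [0.0833, 48] h",
            call. = FALSE)
  }
  ld <- df$drug_loading
  if (any(!is.na(ld) & (ld < 50 | ld > 70940))) {
    warning("drug_loading outside the modelled range [50, 70940] ug",
            call. = FALSE)
  }
  amt <- df$permeation_amount
  if (any(!is.na(amt) & amt < 0)) {
    stop("negative permeation_amount", call. = FALSE)
  }
  pct <- df$permeation_percentage
  if (any(!is.na(pct) & pct < 0)) {
    stop("negative permeation_percentage", call. = FALSE)
  }
  flagged <- which(!is.na(pct) & pct > 100)
  rownames(df) <- NULL
  structure(df, class = c("permeation_data", "data.frame"),
            flagged_rows = flagged)
}

#' Write a permeation dataset to CSV
#'
#' Numeric values are written with enough digits (up to 17 significant) for
#' a read-write-read round trip to be lossless.
#'
#' @param records A `permeation_data` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_permeation_data <- function(records, path) {
  df <- as.data.frame(records)[, perm_schema]
  for (col in perm_numeric_cols) {
    v <- df[[col]]
    out <- vapply(v, function(x) {
      if (is.na(x)) "" else format(x, digits = 17, trim = TRUE)
    }, character(1))
    df[[col]] <- out
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Normalize a cumulative amount to a 1 cm^2 diffusion window
#'
#' Vertical Franz devices expose a 1.00 cm^2 window, horizontal devices
#' 1.13 cm^2; measured amounts are divided by the window area so that all
#' records are expressed per 1 cm^2.
#'
#' @param amount Cumulative amount(s), >= 0.
#' @param device `"vertical"` or `"horizontal"`.
#' @return Amount per 1 cm^2 (vectorized).
#' @export
normalize_amount <- function(amount, device = c("vertical", "horizontal")) {
  device <- match.arg(device)
  if (any(amount < 0, na.rm = TRUE)) {
    stop("amount must be non-negative", call. = FALSE)
  }
  amount / window_area_cm2(device)
}

#' Split records into training and test sets
#'
#' Uniform random partition without replacement at the given ratio
#' (default 7:3). The training size is `ratio * N` rounded half up, so 191
#' records split 134/57. Reproducible for a given seed; the caller's RNG
#' state is left untouched.
#'
#' @param records A data frame of records (N >= 2 rows).
#' @param ratio Training fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return A `split_result` list with `train`, `test`, `seed`, `ratio` and
#'   the training row indices `train_idx`.
#' @export
split_train_test <- function(records, ratio = 0.7, seed) {
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records to split", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) {
    stop("ratio must be strictly between 0 and 1", call. = FALSE)
  }
  n_train <- as.integer(floor(ratio * n + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- local_seed(seed, sample(n, n_train))
  idx <- sort(idx)
  structure(
    list(train = records[idx, , drop = FALSE],
         test = records[-idx, , drop = FALSE],
         seed = seed, ratio = ratio, train_idx = idx),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("train/test split: %d/%d rows (ratio %g, seed %d)\n",
              nrow(x$train), nrow(x$test), x$ratio, x$seed))
  invisible(x)
}

#' Per-drug record counts and shares
#'
#' @param records A data frame with a `drug` column, non-empty.
#' @return Data frame with `drug`, `n` and `share_pct` (integer percent of
#'   all records), sorted by decreasing count. Counts sum to `nrow(records)`.
#' @export
summarize_dataset <- function(records) {
  if (nrow(records) == 0) stop("empty dataset", call. = FALSE)
  tab <- table(records$drug)
  out <- data.frame(drug = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$drug), ]
  out$share_pct <- as.integer(round(100 * out$n / sum(out$n)))
  rownames(out) <- NULL
  out
}

# evaluate `code` under a fixed seed without disturbing the caller's RNG
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
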