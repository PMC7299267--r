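# shared I/O helpers: delimiter auto-detection limited to comma and tab;
# anything else is an error, not a guess

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_comma <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab == 0 && n_comma == 0)
    stop("cannot detect delimiter (neither tab nor comma) in ", path, call. = FALSE)
  if (n_tab >= n_comma) "\t" else ","
}

delim_for_write <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

check_overwrite <- function(path, overwrite) {
  if (file.exists(path) && !overwrite)
    stop("output file exists: ", path, " (use overwrite = TRUE)", call. = FALSE)
}

# external (file) phenology column names <-> internal names
PHENO_EXTERNAL <- c(germination = "germination_date", bolting = "bolting_date",
                    flowering_init = "flowering_init_date",
                    flowering_term = "flowering_term_date",
                    senescence = "senescence_date")

parse_event_dates <- function(df, path) {
  ev_cols <- unname(PHENO_EXTERNAL)
  vals <- unlist(lapply(ev_cols, function(cn) df[[cn]]))
  vals <- vals[!is.na(vals) & vals != ""]
  if (all(grepl("^-?[0-9]+$", vals))) {
    message("phenology dates in ", basename(path), " read as integer day offsets")
    for (cn in ev_cols) df[[cn]] <- suppressWarnings(as.integer(df[[cn]]))
    return(list(df = df, reference = NA))
  }
  dates <- suppressWarnings(as.Date(vals, format = "%Y-%m-%d"))
  if (anyNA(dates))
    stop("unparseable event dates (need ISO-8601 or integer offsets): ",
         paste(utils::head(unique(vals[is.na(dates)]), 3), collapse = ", "),
         call. = FALSE)
  ref <- min(suppressWarnings(as.Date(df[[PHENO_EXTERNAL["germination"]]])), na.rm = TRUE)
  message("phenology dates in ", basename(path),
          " read as ISO-8601; reference date (day 0) = ", format(ref))
  for (cn in ev_cols) {
    d <- suppressWarnings(as.Date(df[[cn]], format = "%Y-%m-%d"))
    df[[cn]] <- as.integer(d - ref)
  }
  list(df = df, reference = ref)
}

#' Read a phenology table
#'
#' One row per plant with cohort index, the five life-event dates
#' (germination, bolting, flowering initiation, flowering termination,
#' whole-plant senescence) and the morphology measurements. Dates may be
#' ISO-8601 calendar dates or integer day offsets (auto-detected and
#' logged); internally everything is an integer offset from the reference
#' date. Rows violating the life-cycle ordering
#' `g <= bolting <= fi <= ft <= senescence` are rejected with their row
#' numbers, as are duplicate plant ids.
#'
#' @param path Delimited text file (comma or tab), with header columns
#'   `plant_id`, `accession`, `regime`, `cohort`, `germination_date`,
#'   `bolting_date`, `flowering_init_date`, `flowering_term_date`,
#'   `senescence_date`, and optionally `leaves_at_bolting`,
#'   `rosette_diameter_mm`, `fruit_count`, `censored`.
#' @return A plant-record data frame with internal column names
#'   (`germination`, `bolting`, `flowering_init`, `flowering_term`,
#'   `senescence`); the reference date, if any, is in
#'   `attr(, "reference_date")`.
#' @export
read_phenology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("plant_id", "accession", "regime", "cohort", unname(PHENO_EXTERNAL))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenology file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dup <- df$plant_id[duplicated(df$plant_id)]
  if (length(dup)) stop("duplicate plant id(s): ",
                        paste(unique(dup), collapse = ", "), call. = FALSE)
  parsed <- parse_event_dates(df, path)
  df <- parsed$df
  names(df)[match(unname(PHENO_EXTERNAL), names(df))] <- names(PHENO_EXTERNAL)
  ev <- df[, names(PHENO_EXTERNAL)]
  bad <- vapply(seq_len(nrow(ev)), function(i) {
    v <- as.numeric(ev[i, ])
    is.unsorted(v[!is.na(v)])
  }, logical(1))
  if (any(bad))
    stop("life-cycle ordering violated (g <= bolting <= fi <= ft <= senescence) in row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  df$cohort <- as.integer(df$cohort)
  attr(df, "reference_date") <- parsed$reference
  df
}

#' Write a phenology table
#'
#' Inverse of [read_phenology()]: writes the external column layout with
#' integer day offsets, comma-separated for `.csv`, otherwise
#' tab-separated. Refuses to overwrite unless asked.
#'
#' @param records Plant-record data frame (internal column names).
#' @param path Output path.
#' @param overwrite Overwrite an existing file? Default `FALSE`.
#' @return The path, invisibly.
#' @export
write_phenology <- function(records, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  out <- records
  names(out)[match(names(PHENO_EXTERNAL), names(out))] <- unname(PHENO_EXTERNAL)
  utils::write.table(out, path, sep = delim_for_write(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an environment series
#'
#' Daily mode expects columns `day`, `temp_daylight`, `photoperiod` and
#' validates day contiguity (gaps are an error listing the missing days).
#' Logger mode expects sub-daily rows `day`, `hour`, `temp` plus a separate
#' photoperiod table (`day`, `sunrise`, `sunset`) and routes through
#' [daylight_mean_from_log()].
#'
#' @param path Delimited text file.
#' @param mode `"daily"` or `"logger"`.
#' @param photoperiod_path Photoperiod table path (logger mode only).
#' @return An [env_series()].
#' @export
read_environment <- function(path, mode = c("daily", "logger"),
                             photoperiod_path = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (mode == "daily") {
    need <- c("day", "temp_daylight", "photoperiod")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("daily environment file missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    df <- df[order(df$day), , drop = FALSE]
    gaps <- setdiff(seq(min(df$day), max(df$day)), df$day)
    if (length(gaps))
      stop("environment series not contiguous; missing day(s): ",
           paste(gaps, collapse = ", "), call. = FALSE)
    env_series(df$day, df$temp_daylight, df$photoperiod)
  } else {
    if (is.null(photoperiod_path))
      stop("logger mode needs `photoperiod_path`", call. = FALSE)
    pp <- utils::read.table(photoperiod_path, header = TRUE,
                            sep = detect_delim(photoperiod_path),
                            stringsAsFactors = FALSE)
    daylight_mean_from_log(df, pp)
  }
}

#' Write a daily environment series
#'
#' @param env An [env_series()].
#' @inheritParams write_phenology
#' @return The path, invisibly.
#' @export
write_environment <- function(env, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  utils::write.table(as.data.frame(env), path, sep = delim_for_write(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genetic map and RIL genotype matrix
#'
#' Two layouts are accepted. Rotated (single file): rows are markers with
#' columns `marker`, `chr`, `pos`, followed by one column per line holding
#' allele codes. Two-file: `path` is a line x marker genotype matrix with a
#' `line` id column, and `map_path` holds `marker`, `chr`, `pos`. Allele
#' codes `A`/`B` are kept; `-`, `NA` and empty cells become missing; any
#' other code is rejected naming the code and cell. Unsorted marker
#' positions are sorted with a warning.
#'
#' @param path Genotype file.
#' @param map_path Optional separate map file (two-file layout).
#' @return A list with elements `map` (a `genetic_map` data frame) and
#'   `geno` (lines x markers character matrix of `"A"`/`"B"`/`NA`).
#' @export
read_genotypes <- function(path, map_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE)
  if (is.null(map_path)) {
    need <- c("marker", "chr", "pos")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("rotated genotype file missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    message("genotype file ", basename(path), " read in rotated layout (",
            ncol(df) - 3L, " lines x ", nrow(df), " markers)")
    map <- df[, need]
    geno <- t(as.matrix(df[, setdiff(names(df), need), drop = FALSE]))
    colnames(geno) <- map$marker
  } else {
    mp <- utils::read.table(map_path, header = TRUE, sep = detect_delim(map_path),
                            stringsAsFactors = FALSE)
    need <- c("marker", "chr", "pos")
    miss <- setdiff(need, names(mp))
    if (length(miss)) stop("map file missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (!"line" %in% names(df))
      stop("two-file layout genotype matrix needs a `line` column", call. = FALSE)
    message("genotype data read in two-file layout (", nrow(df), " lines x ",
            nrow(mp), " markers)")
    map <- mp[, need]
    geno <- as.matrix(df[, setdiff(names(df), "line"), drop = FALSE])
    rownames(geno) <- df$line
    miss_mk <- setdiff(map$marker, colnames(geno))
    if (length(miss_mk)) stop("genotype matrix missing marker column(s): ",
                              paste(utils::head(miss_mk, 5), collapse = ", "),
                              call. = FALSE)
    geno <- geno[, map$marker, drop = FALSE]
  }
  geno[geno %in% c("-", "")] <- NA
  bad <- which(!is.na(geno) & !(geno %in% c("A", "B")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unknown allele code '%s' at line %s, marker %s",
                 geno[bad[1, 1], bad[1, 2]],
                 rownames(geno)[bad[1, 1]] %||% bad[1, 1],
                 colnames(geno)[bad[1, 2]]), call. = FALSE)
  if (is.unsorted(order(map$chr, map$pos))) map <- map # no-op guard
  ord <- order(map$chr, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    warning("marker positions not sorted; sorting by chromosome and cM",
            call. = FALSE)
    map <- map[ord, , drop = FALSE]
    geno <- geno[, map$marker, drop = FALSE]
  }
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  list(map = map, geno = geno)
}

#' Write a genetic map + genotype matrix in rotated layout
#'
#' @param map `genetic_map` data frame.
#' @param geno Lines x markers character matrix.
#' @inheritParams write_phenology
#' @return The path, invisibly.
#' @export
write_genotypes <- function(map, geno, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  g <- geno[, map$marker, drop = FALSE]
  g[is.na(g)] <- "-"
  out <- cbind(map[, c("marker", "chr", "pos")],
               as.data.frame(t(g), check.names = FALSE))
  utils::write.table(out, path, sep = delim_for_write(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a phenotype table (line id + one column per trait)
#'
#' @param phenotypes Data frame with a `line` column and trait columns, or a
#'   named vector (written as trait `value`).
#' @inheritParams write_phenology
#' @return The path, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  if (!is.data.frame(phenotypes))
    phenotypes <- data.frame(line = names(phenotypes), value = as.numeric(phenotypes))
  utils::write.table(phenotypes, path, sep = delim_for_write(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path Delimited file with a `line` column and one column per trait.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                          stringsAsFactors = FALSE)
  if (!"line" %in% names(df))
    stop("phenotype file needs a `line` column", call. = FALSE)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
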