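#' @importFrom utils read.csv write.csv
NULL

# ---- parsing helpers --------------------------------------------------------

# Parse a numeric cell: "." decimal mark, "," thousands separator, "NA"/"" as
# missing. Locale-independent by construction.
.parseNumber <- function(x, what = "value") {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "na", ".")] <- NA_character_
  stripped <- gsub(",", "", x, fixed = TRUE)
  out <- suppressWarnings(as.numeric(stripped))
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop(sprintf("cannot parse %s cell(s): %s", what,
                 paste(sQuote(x[bad]), collapse = ", ")), call. = FALSE)
  out
}

# Parse "X.XX (L-U)" (hyphen or en-dash range separator) into c(or, lower, upper).
.parseOrCell <- function(cell, row_label) {
  cell <- trimws(cell)
  m <- regmatches(cell,
    regexec("^([0-9.,]+)\\s*\\(\\s*([0-9.,]+)\\s*[-–]\\s*([0-9.,]+)\\s*\\)$",
            cell))[[1]]
  if (length(m) != 4L)
    stop(sprintf("malformed OR cell %s in row %s (expected \"X.XX (L-U)\")",
                 sQuote(cell), sQuote(row_label)), call. = FALSE)
  .parseNumber(m[2:4], what = "odds-ratio")
}

.checkDirection <- function(direction) {
  direction <- as.character(direction)
  bad <- !direction %in% .DIRECTIONS
  if (any(bad))
    stop("direction must be one of ", paste(.DIRECTIONS, collapse = ", "),
         "; got ", paste(sQuote(unique(direction[bad])), collapse = ", "),
         call. = FALSE)
  direction
}

# ---- record validators ------------------------------------------------------

.validateAssociations <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("disease_name", "or_per_sd", "ci_lower", "ci_upper",
            "direction", "source", "significant")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("association table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(df)
  .checkDirection(df$direction)
  if (any(is.na(df$or_per_sd) | df$or_per_sd <= 0))
    stop("odds ratios must be strictly positive", call. = FALSE)
  has_ci <- !is.na(df$ci_lower) & !is.na(df$ci_upper)
  if (any(has_ci & (df$ci_lower <= 0 | df$ci_upper <= 0)))
    stop("CI bounds must be strictly positive", call. = FALSE)
  bad <- has_ci & (df$ci_lower > df$or_per_sd | df$or_per_sd > df$ci_upper)
  if (any(bad))
    stop("inverted CI (lower > OR or OR > upper) in row(s): ",
         paste(df$disease_name[bad], collapse = ", "), call. = FALSE)
  if (any(is.na(df$ci_lower) != is.na(df$ci_upper)))
    stop("one-sided missing CI bound", call. = FALSE)
  df$significant <- as.logical(df$significant)
  df
}

.validateBurdens <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("cause_name", "measure", "value", "ci_lower", "ci_upper",
            "population", "year")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("burden table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(df)
  bad_m <- !df$measure %in% .MEASURES
  if (any(bad_m))
    stop("unknown measure: ", paste(sQuote(unique(df$measure[bad_m])),
                                    collapse = ", "), call. = FALSE)
  if (any(!is.na(df$value) & df$value < 0))
    stop("negative burden rate", call. = FALSE)
  # a MISSING value implies MISSING bounds
  if (any(is.na(df$value) & (!is.na(df$ci_lower) | !is.na(df$ci_upper))))
    stop("CI bounds present for a MISSING burden value", call. = FALSE)
  ok <- !is.na(df$value) & !is.na(df$ci_lower) & !is.na(df$ci_upper)
  if (any(ok & (df$ci_lower > df$value | df$value > df$ci_upper)))
    stop("burden CI does not contain the rate", call. = FALSE)
  df
}

.validateSnps <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("rsid", "chromosome", "position", "short_allele", "long_allele",
            "short_allele_freq", "telomere_maintenance", "n_participants",
            "gwas", "population")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("SNP table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(df)
  dup <- unique(df$rsid[duplicated(df$rsid)])
  if (length(dup))
    stop("duplicate rsid(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (any(is.na(df$position) | df$position <= 0))
    stop("positions must be positive", call. = FALSE)
  f <- df$short_allele_freq
  if (any(!is.na(f) & (f < 0 | f > 1)))
    stop("allele frequency outside [0, 1]", call. = FALSE)
  bad_tm <- !df$telomere_maintenance %in% c("yes", "no", "unknown")
  if (any(bad_tm))
    stop("telomere_maintenance must be yes/no/unknown", call. = FALSE)
  df
}

# ---- disease-association tables --------------------------------------------

#' Read a table of per-SD disease odds ratios
#'
#' Accepts either separate numeric columns \code{or_per_sd}, \code{ci_lower},
#' \code{ci_upper}, or a single text column \code{or_ci} holding cells such
#' as \code{"5.27 (3.15-8.81)"} (hyphen or en-dash). Non-significant rows are
#' retained and flagged; filtering is a visible downstream step
#' (see [dropNonsignificant()]).
#'
#' @param path CSV file with a header.
#' @return data.frame of disease associations with columns
#'   \code{disease_name}, \code{or_per_sd}, \code{ci_lower}, \code{ci_upper},
#'   \code{direction} (\code{per_sd_longer}/\code{per_sd_shorter}),
#'   \code{source}, \code{significant}.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("disease_name,or_ci,direction,source,significant",
#'   "Glioma,\"5.27 (3.15-8.81)\",per_sd_longer,meta,TRUE"), tf)
#' readOrTable(tf)
#' @export
readOrTable <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) {
    return(.validateAssociations(data.frame(
      disease_name = character(), or_per_sd = numeric(),
      ci_lower = numeric(), ci_upper = numeric(), direction = character(),
      source = character(), significant = logical())))
  }
  if ("or_ci" %in% names(raw)) {
    parsed <- t(vapply(seq_len(nrow(raw)),
      function(i) .parseOrCell(raw$or_ci[i], raw$disease_name[i]),
      numeric(3)))
    or <- parsed[, 1]; lo <- parsed[, 2]; hi <- parsed[, 3]
  } else {
    or <- .parseNumber(raw$or_per_sd, "odds-ratio")
    lo <- .parseNumber(raw$ci_lower, "CI")
    hi <- .parseNumber(raw$ci_upper, "CI")
  }
  df <- data.frame(
    disease_name = raw$disease_name,
    or_per_sd = or, ci_lower = lo, ci_upper = hi,
    direction = raw$direction,
    source = if ("source" %in% names(raw)) raw$source else "",
    significant = if ("significant" %in% names(raw))
      toupper(raw$significant) %in% c("TRUE", "T", "1", "YES") else TRUE,
    stringsAsFactors = FALSE)
  .validateAssociations(df)
}

#' Write a disease-association table
#'
#' @param assocs data.frame as returned by [readOrTable()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeOrTable <- function(assocs, path) {
  assocs <- .validateAssociations(assocs)
  cols <- c("disease_name", "or_per_sd", "ci_lower", "ci_upper",
            "direction", "source", "significant")
  write.csv(assocs[, cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---- burden tables ----------------------------------------------------------

#' Read an age-standardized burden table (incidence / DALY rates)
#'
#' Two dialects are supported. \code{"simple"} expects columns
#' \code{cause_name, measure, value, ci_lower, ci_upper, population, year}.
#' \code{"gbd_results"} mimics the GBD Results Tool export layout
#' (\code{measure, location, sex, age, cause, metric, year, val, upper,
#' lower}) where the measure strings are \code{"Incidence"} and
#' \code{"DALYs (Disability-Adjusted Life Years)"} and the metric is
#' \code{"Rate"} (per 100,000). Thousands separators are accepted
#' (\code{"2,106.22"}); \code{"NA"} cells become missing values with missing
#' bounds.
#'
#' @param path CSV file.
#' @param dialect \code{"simple"} or \code{"gbd_results"}.
#' @return data.frame of burden estimates (rates per 100,000 persons,
#'   age-standardized).
#' @export
readBurdenTable <- function(path, dialect = c("simple", "gbd_results")) {
  dialect <- match.arg(dialect)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (dialect == "gbd_results") {
    measure_map <- c(
      "Incidence" = "incidence",
      "DALYs (Disability-Adjusted Life Years)" = "daly",
      "incidence" = "incidence", "daly" = "daly")
    m <- measure_map[raw$measure]
    if (any(is.na(m) & !is.na(raw$measure)))
      stop("unknown measure string: ",
           paste(sQuote(unique(raw$measure[is.na(m)])), collapse = ", "),
           call. = FALSE)
    if ("metric" %in% names(raw) && any(raw$metric != "Rate"))
      stop("gbd_results dialect expects metric == 'Rate'", call. = FALSE)
    df <- data.frame(
      cause_name = raw$cause, measure = unname(m),
      value = .parseNumber(raw$val, "rate"),
      ci_lower = .parseNumber(raw$lower, "rate"),
      ci_upper = .parseNumber(raw$upper, "rate"),
      population = raw$location,
      year = as.integer(raw$year), stringsAsFactors = FALSE)
  } else {
    if (nrow(raw) == 0L)
      return(.validateBurdens(data.frame(
        cause_name = character(), measure = character(), value = numeric(),
        ci_lower = numeric(), ci_upper = numeric(),
        population = character(), year = integer())))
    df <- data.frame(
      cause_name = raw$cause_name, measure = raw$measure,
      value = .parseNumber(raw$value, "rate"),
      ci_lower = .parseNumber(raw$ci_lower, "rate"),
      ci_upper = .parseNumber(raw$ci_upper, "rate"),
      population = if ("population" %in% names(raw)) raw$population else "",
      year = if ("year" %in% names(raw)) as.integer(raw$year) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  # MISSING value => MISSING bounds, never silently zero
  df$ci_lower[is.na(df$value)] <- NA_real_
  df$ci_upper[is.na(df$value)] <- NA_real_
  .validateBurdens(df)
}

#' Write a burden table (simple dialect)
#'
#' @param burdens data.frame as returned by [readBurdenTable()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeBurdenTable <- function(burdens, path) {
  burdens <- .validateBurdens(burdens)
  cols <- c("cause_name", "measure", "value", "ci_lower", "ci_upper",
            "population", "year")
  write.csv(burdens[, cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---- LD matrices ------------------------------------------------------------

#' Read a square R-squared LD matrix
#'
#' The file holds a header row of rsids and a leading rsid column.
#' Whitespace- or comma-delimited. Lower- or upper-triangular input is
#' mirrored to a full symmetric matrix; \code{"NA"} cells become missing.
#'
#' @param path delimited file.
#' @param chromosome chromosome label (defaults to the file name stem).
#' @return an [LDMatrix-class].
#' @export
readLdMatrix <- function(path, chromosome = NULL) {
  if (is.null(chromosome))
    chromosome <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  raw <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                    check.names = FALSE, colClasses = "character",
                    na.strings = c("NA", ""))
  if (nrow(raw) != ncol(raw))
    stop(sprintf("LD matrix in %s is not square (%d rows, %d columns)",
                 basename(path), nrow(raw), ncol(raw)), call. = FALSE)
  if (!identical(rownames(raw), colnames(raw)))
    stop("row and column rsids disagree in ", basename(path), call. = FALSE)
  m <- matrix(.parseNumber(as.matrix(raw), "R-squared"),
              nrow = nrow(raw), dimnames = dimnames(raw))
  # both triangles given: check agreement before mirroring
  both <- !is.na(m) & !is.na(t(m))
  d <- (m - t(m))[both]
  if (any(abs(d) > 1e-9))
    stop("asymmetric R-squared values beyond tolerance in ", basename(path),
         call. = FALSE)
  LDMatrix(m, rsids = rownames(m), chromosome = chromosome)
}

#' Read all LD matrices in a directory
#'
#' @param dir directory of per-chromosome matrix files (\code{.csv}/
#'   \code{.txt}); chromosome labels are taken from the \code{chr<label>}
#'   file-name stems.
#' @return list of [LDMatrix-class] objects.
#' @export
readLdMatrixDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(csv|txt|tsv)$", full.names = TRUE)
  if (!length(files)) stop("no matrix files under ", dir, call. = FALSE)
  labs <- sub("^chr", "", sub("\\.[^.]*$", "", basename(files)))
  # numeric chromosome order where possible
  ord <- order(suppressWarnings(as.numeric(labs)), labs)
  mapply(readLdMatrix, files[ord], labs[ord], SIMPLIFY = FALSE,
         USE.NAMES = FALSE)
}

# ---- SNP tables -------------------------------------------------------------

#' Read a SNP annotation table
#'
#' @param path CSV with columns \code{rsid, chromosome, position,
#'   short_allele, long_allele, short_allele_freq, telomere_maintenance
#'   (yes/no/unknown), n_participants, gwas, population}. Positions are
#'   GRCh38 coordinates.
#' @return validated data.frame (unique rsids, positive positions,
#'   frequencies in [0, 1]).
#' @export
readSnpTable <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  df <- data.frame(
    rsid = raw$rsid, chromosome = raw$chromosome,
    position = as.integer(.parseNumber(raw$position, "position")),
    short_allele = ifelse(raw$short_allele %in% c("", "NA"), NA_character_,
                          raw$short_allele),
    long_allele = ifelse(raw$long_allele %in% c("", "NA"), NA_character_,
                         raw$long_allele),
    short_allele_freq = .parseNumber(raw$short_allele_freq, "frequency"),
    telomere_maintenance = raw$telomere_maintenance,
    n_participants = suppressWarnings(
      as.integer(.parseNumber(raw$n_participants, "N"))),
    gwas = toupper(raw$gwas) %in% c("TRUE", "T", "Y", "YES", "1"),
    population = raw$population, stringsAsFactors = FALSE)
  .validateSnps(df)
}

#' Write a SNP annotation table
#'
#' @param snps data.frame as returned by [readSnpTable()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSnpTable <- function(snps, path) {
  snps <- .validateSnps(snps)
  write.csv(snps, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---- excess-burden output ---------------------------------------------------

#' Write an excess-burden table
#'
#' Emits a fixed column order with full-precision values plus 2-decimal
#' display columns; rounding happens only in the display columns
#' (half-even, at report time).
#'
#' @param records data.frame of excess-burden rows (see [excessBurden()]).
#' @param path output CSV path.
#' @param digits decimals for the display columns.
#' @return \code{path}, invisibly.
#' @export
writeExcessTable <- function(records, path, digits = 2L) {
  cols <- c("cause_name", "measure", "direction", "value",
            "ci_lower", "ci_upper", "components")
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stop("excess table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- records[, cols]
  out$display <- vapply(seq_len(nrow(out)), function(i)
    formatExcessValue(out$value[i], out$ci_lower[i], out$ci_upper[i],
                      digits = digits), character(1))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back an excess-burden table written by [writeExcessTable()]
#'
#' @param path CSV path.
#' @return data.frame of excess-burden rows (full-precision columns; the
#'   display column is dropped).
#' @export
readExcessTable <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  data.frame(
    cause_name = raw$cause_name, measure = raw$measure,
    direction = raw$direction,
    value = .parseNumber(raw$value, "excess"),
    ci_lower = .parseNumber(raw$ci_lower, "excess"),
    ci_upper = .parseNumber(raw$ci_upper, "excess"),
    components = raw$components, stringsAsFactors = FALSE)
}
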