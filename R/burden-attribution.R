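# The core statistic. Excess burden per SD of gTL for one disease is
# (OR - 1) x rate, where the rate is the age-standardized incidence or DALY
# rate per 100,000 persons and the OR is harmonized to the disease group's
# risk-increasing direction. The excess CI applies the same formula to the
# OR's CI bounds; the burden CI is not used. Group totals sum values and
# like bounds (the source convention: perfect dependence across diseases).

.excessRow <- function(cause_name, measure, direction, value, ci_lower,
                       ci_upper, components) {
  data.frame(cause_name = cause_name, measure = measure,
             direction = direction, value = value, ci_lower = ci_lower,
             ci_upper = ci_upper,
             components = paste(components, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Excess incidence or DALYs for one disease
#'
#' \code{value = (OR - 1) * rate}, with
#' \code{ci = ((OR_lower - 1) * rate, (OR_upper - 1) * rate)}. Interpreted as
#' cases (or DALYs) per 100,000 persons per SD of gTL in excess of baseline.
#' The burden estimate's own CI bounds are not propagated. Note the
#' approximation inherited from the source method: the OR stands in for a
#' rate ratio even for common diseases.
#'
#' @param assoc one-row association data.frame, harmonized to the disease's
#'   risk-increasing direction.
#' @param burden one-row burden data.frame for the same cause, with a
#'   non-missing rate.
#' @return one-row excess-burden data.frame with columns \code{cause_name,
#'   measure, direction, value, ci_lower, ci_upper, components}.
#' @examples
#' a <- data.frame(disease_name = "Glioma", or_per_sd = 5.27,
#'   ci_lower = 3.15, ci_upper = 8.81, direction = "per_sd_longer",
#'   source = "meta", significant = TRUE)
#' b <- data.frame(cause_name = "Glioma", measure = "incidence",
#'   value = 8.39, ci_lower = 7.29, ci_upper = 9.30,
#'   population = "Europe", year = 2017L)
#' round(excessBurden(a, b)$value, 2)  # 35.83
#' @export
excessBurden <- function(assoc, burden) {
  assoc <- .validateAssociations(assoc)
  burden <- .validateBurdens(burden)
  stopifnot(nrow(assoc) == 1L, nrow(burden) == 1L)
  if (is.na(burden$value))
    stop("burden value is MISSING; route this pair to the exclusion list",
         call. = FALSE)
  .excessRow(
    cause_name = burden$cause_name, measure = burden$measure,
    direction = assoc$direction,
    value = (assoc$or_per_sd - 1) * burden$value,
    ci_lower = (assoc$ci_lower - 1) * burden$value,
    ci_upper = (assoc$ci_upper - 1) * burden$value,
    components = burden$cause_name)
}

#' Total excess burden over a disease group
#'
#' Sums the values and sums the like CI bounds of rows sharing one measure
#' and one direction. Summing bounds assumes perfect dependence between the
#' per-disease estimates; it is the source convention (the group lower bound
#' equals the sum of per-disease lower bounds). A root-sum-square
#' alternative, which instead assumes independence, is available via
#' \code{bounds = "rss"}.
#'
#' @param rows excess-burden data.frame (see [excessBurden()]).
#' @param bounds \code{"sum"} (default, source convention) or \code{"rss"}.
#' @param cause_name label for the total row.
#' @return one-row excess-burden data.frame listing all component causes.
#' @export
totalExcess <- function(rows, bounds = c("sum", "rss"),
                        cause_name = "total") {
  bounds <- match.arg(bounds)
  if (nrow(rows) == 0L)
    return(.excessRow(cause_name, NA_character_, NA_character_,
                      0, 0, 0, character(0)))
  if (length(unique(rows$measure)) != 1L)
    stop("cannot total across measures", call. = FALSE)
  if (length(unique(rows$direction)) != 1L)
    stop("cannot total across effect directions", call. = FALSE)
  if (bounds == "sum") {
    lo <- sum(rows$ci_lower); hi <- sum(rows$ci_upper)
  } else {
    v <- sum(rows$value)
    lo <- v - sqrt(sum((rows$value - rows$ci_lower)^2))
    hi <- v + sqrt(sum((rows$ci_upper - rows$value)^2))
  }
  .excessRow(cause_name, rows$measure[1], rows$direction[1],
             sum(rows$value), lo, hi, rows$cause_name)
}

#' Attribute excess burden across a study's diseases
#'
#' Pairs each harmonized association with the burden rows for its cause
#' (exact name match after the optional alias map) and computes per-disease
#' excess rows plus per-measure, per-direction totals. A disease with burden
#' available for only one measure contributes only to that measure's total;
#' every excluded disease/measure pair carries a machine-readable reason
#' (\code{"no burden record"} or \code{"burden value missing"}).
#'
#' @param assocs association data.frame, already significance-filtered and
#'   harmonized (each row in its risk-increasing direction).
#' @param burdens burden data.frame.
#' @param aliases optional named character vector mapping
#'   \code{disease_name} to the burden \code{cause_name}.
#' @param bounds CI convention for totals, see [totalExcess()].
#' @return an [AttributionReport-class].
#' @export
attributeBurden <- function(assocs, burdens, aliases = NULL,
                            bounds = c("sum", "rss")) {
  bounds <- match.arg(bounds)
  assocs <- .validateAssociations(assocs)
  burdens <- .validateBurdens(burdens)
  dup <- unique(assocs$disease_name[duplicated(assocs$disease_name)])
  if (length(dup))
    stop("duplicate disease in associations: ",
         paste(dup, collapse = ", "), call. = FALSE)
  key <- paste(burdens$cause_name, burdens$measure)
  if (anyDuplicated(key))
    stop("duplicate cause x measure in burden table: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)

  rows <- list(); included <- list(); excluded <- list()
  for (i in seq_len(nrow(assocs))) {
    a <- assocs[i, , drop = FALSE]
    cause <- a$disease_name
    if (!is.null(aliases) && cause %in% names(aliases))
      cause <- unname(aliases[[cause]])
    for (meas in .MEASURES) {
      b <- burdens[burdens$cause_name == cause & burdens$measure == meas, ,
                   drop = FALSE]
      if (nrow(b) == 0L) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          disease = a$disease_name, measure = meas,
          reason = "no burden record", stringsAsFactors = FALSE)
      } else if (is.na(b$value)) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          disease = a$disease_name, measure = meas,
          reason = "burden value missing", stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- excessBurden(a, b)
        included[[length(included) + 1L]] <- data.frame(
          disease = a$disease_name, cause = cause, measure = meas,
          or_per_sd = a$or_per_sd, rate = b$value,
          direction = a$direction, stringsAsFactors = FALSE)
      }
    }
  }
  empty_excess <- data.frame(
    cause_name = character(), measure = character(), direction = character(),
    value = numeric(), ci_lower = numeric(), ci_upper = numeric(),
    components = character(), stringsAsFactors = FALSE)
  rows <- if (length(rows)) do.call(rbind, rows) else empty_excess
  included <- if (length(included)) do.call(rbind, included) else
    data.frame(disease = character(), cause = character(),
               measure = character(), or_per_sd = numeric(),
               rate = numeric(), direction = character())
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(disease = character(), measure = character(),
               reason = character())

  totals <- empty_excess
  if (nrow(rows)) {
    grp <- unique(rows[, c("measure", "direction")])
    totals <- do.call(rbind, lapply(seq_len(nrow(grp)), function(g) {
      sel <- rows$measure == grp$measure[g] &
        rows$direction == grp$direction[g]
      totalExcess(rows[sel, , drop = FALSE], bounds = bounds,
                  cause_name = sprintf("total %s (%s)", grp$measure[g],
                                       grp$direction[g]))
    }))
  }
  new("AttributionReport", included = included, excluded = excluded,
      rows = rows, totals = totals)
}
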