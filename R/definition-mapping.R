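# Disease-definition reconciliation: registry burden categories are often
# broader than the case definitions behind an MR odds ratio. Broad burden is
# allocated to narrow definitions in proportion to case counts (SEER-style),
# and sub-conditions can be subtracted for sensitivity analyses.

#' Case-count fraction of a narrow definition within a broad category
#'
#' @param narrow_name,broad_name disease labels.
#' @param narrow_count,broad_count non-negative case counts,
#'   \code{narrow_count <= broad_count}, \code{broad_count > 0}. May be
#'   omitted when \code{fraction} is given directly.
#' @param fraction allocation fraction in [0, 1]; computed from the counts
#'   when they are supplied.
#' @param source free-text provenance of the counts.
#' @return one-row data.frame with columns \code{narrow_name, broad_name,
#'   narrow_count, broad_count, fraction, source}; the fraction is kept at
#'   full precision.
#' @examples
#' caseFraction("IPF", "Interstitial lung disease", 268, 1000)$fraction
#' @export
caseFraction <- function(narrow_name, broad_name, narrow_count = NA,
                         broad_count = NA, fraction = NULL, source = "") {
  if (!is.na(narrow_count) && !is.na(broad_count)) {
    if (broad_count <= 0)
      stop("broad_count must be positive", call. = FALSE)
    if (narrow_count < 0 || narrow_count > broad_count)
      stop("need 0 <= narrow_count <= broad_count", call. = FALSE)
    f <- narrow_count / broad_count
    if (!is.null(fraction) && !is.na(fraction) &&
        abs(fraction - f) > 1e-9)
      stop("supplied fraction disagrees with counts", call. = FALSE)
    fraction <- f
  }
  if (is.null(fraction) || is.na(fraction))
    stop("either counts or a fraction must be supplied", call. = FALSE)
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  data.frame(narrow_name = narrow_name, broad_name = broad_name,
             narrow_count = as.numeric(narrow_count),
             broad_count = as.numeric(broad_count),
             fraction = fraction, source = source, stringsAsFactors = FALSE)
}

#' Read a case-fraction table
#'
#' Columns: \code{narrow_name, broad_name}, then either
#' \code{narrow_count, broad_count} or a precomputed \code{fraction}
#' (plus optional \code{source}).
#'
#' @param path CSV file.
#' @return data.frame of case fractions (one row per narrow definition).
#' @export
readFractionTable <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    caseFraction(
      narrow_name = raw$narrow_name[i], broad_name = raw$broad_name[i],
      narrow_count = if ("narrow_count" %in% names(raw))
        .parseNumber(raw$narrow_count[i], "count") else NA,
      broad_count = if ("broad_count" %in% names(raw))
        .parseNumber(raw$broad_count[i], "count") else NA,
      fraction = if ("fraction" %in% names(raw))
        .parseNumber(raw$fraction[i], "fraction") else NULL,
      source = if ("source" %in% names(raw)) raw$source[i] else "")
  })
  do.call(rbind, rows)
}

#' Allocate broad registry burden to a narrow case definition
#'
#' Multiplies the rate and both CI bounds by the case-count fraction and
#' renames the cause to the narrow definition. Linear: fractions that
#' partition a broad cause (summing to 1) conserve its burden exactly.
#'
#' @param broad burden data.frame rows for one broad cause (any measures).
#' @param frac one-row case-fraction data.frame whose \code{broad_name}
#'   matches the burden's \code{cause_name}.
#' @return burden rows for the narrow definition.
#' @export
allocateBurden <- function(broad, frac) {
  broad <- .validateBurdens(broad)
  stopifnot(nrow(frac) == 1L)
  if (!all(broad$cause_name == frac$broad_name))
    stop(sprintf("fraction is for %s but burden rows are for %s",
                 sQuote(frac$broad_name),
                 paste(sQuote(unique(broad$cause_name)), collapse = ", ")),
         call. = FALSE)
  if (any(is.na(broad$value)))
    stop("cannot allocate a MISSING burden value", call. = FALSE)
  out <- broad
  out$cause_name <- frac$narrow_name
  out$value <- broad$value * frac$fraction
  out$ci_lower <- broad$ci_lower * frac$fraction
  out$ci_upper <- broad$ci_upper * frac$fraction
  .appendProvenance(out, sprintf("allocated %.6g of %s", frac$fraction,
                                 frac$broad_name))
}

#' Subtract a sub-condition's share from an excess-burden estimate
#'
#' Sensitivity analysis: removes \code{fraction} of a component's excess from
#' a total, applying the same rule to the CI bounds. Exact complement:
#' \code{result + fraction * component == total} in value and bounds.
#'
#' @param total,component one-row excess-burden data.frames sharing measure
#'   and direction (see [excessBurden()], [totalExcess()]).
#' @param fraction share of the component attributable to the sub-condition,
#'   in [0, 1].
#' @param label cause name for the adjusted estimate.
#' @return one-row excess-burden data.frame.
#' @export
subtractSubcondition <- function(total, component, fraction,
                                 label = sprintf("%s minus %.1f%% of %s",
                                                 total$cause_name,
                                                 100 * fraction,
                                                 component$cause_name)) {
  stopifnot(nrow(total) == 1L, nrow(component) == 1L)
  if (total$measure != component$measure)
    stop("measure mismatch between total and component", call. = FALSE)
  if (total$direction != component$direction)
    stop("direction mismatch between total and component", call. = FALSE)
  if (is.na(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  value <- total$value - fraction * component$value
  if (!is.na(value) && value < 0)
    stop("subtraction yields a negative excess; inputs are inconsistent",
         call. = FALSE)
  data.frame(
    cause_name = label, measure = total$measure,
    direction = total$direction, value = value,
    ci_lower = total$ci_lower - fraction * component$ci_lower,
    ci_upper = total$ci_upper - fraction * component$ci_upper,
    components = paste0(total$components, " - ", fraction, "*",
                        component$cause_name),
    stringsAsFactors = FALSE)
}
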