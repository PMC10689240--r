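#' @name circuit
#' @title Anatomical circuit quantification
#' @description Rabies input fractions with starter-cell QC, normalized
#'   axonal projection intensities and ratios, double-label overlap
#'   fractions, and point-to-line distance distributions.
NULL

# Region abbreviations encountered in MeA tracing work; unknown regions pass
# through with a warning rather than an error (the list is editable).
KNOWN_REGIONS <- c(
  "MeA", "MeApd", "MeApv", "MeAa", "PA", "CoA", "CeA", "BLA", "AAA",
  "BNST", "BNSTp", "BNSTpr", "BNSTif", "MPOA", "AVPV", "VMHvl", "PMv",
  "LH", "ZI", "AOB", "MOB", "Pir", "AHN", "PVN", "DG", "CA1", "CA3",
  "LS", "MS", "NAc", "CP", "GP", "SI", "PAG", "VTA", "SN", "Thal")

#' Per-region quantification table
#'
#' Holds either retrograde cell counts or projection intensities per brain
#' region for one animal, with starter-cell QC metadata.
#'
#' @param df Data frame with a `region` column plus either `count` (cells)
#'   or `i_raw` and `i_background` (mean pixel intensity). Region names must
#'   be unique; unknown abbreviations raise a warning.
#' @param tracer `"rabies"` or `"anterograde"`.
#' @param animal Animal identifier.
#' @param starter_in,starter_out Starter cells inside/outside the target
#'   structure.
#' @return The data frame with class `region_quant_table` and metadata
#'   attributes.
#' @export
region_quant_table <- function(df, tracer = c("rabies", "anterograde"),
                               animal = NA_character_,
                               starter_in = NA_real_, starter_out = NA_real_) {
  tracer <- match.arg(tracer)
  df <- as.data.frame(df)
  if (is.null(df$region)) stop("missing `region` column")
  if (anyDuplicated(df$region)) stop("region names must be unique per animal")
  has_counts <- !is.null(df$count)
  has_int <- !is.null(df$i_raw) && !is.null(df$i_background)
  if (!has_counts && !has_int) {
    stop("need a `count` column or `i_raw` + `i_background` columns")
  }
  if (has_counts && any(df$count < 0)) stop("counts must be non-negative")
  if (has_int && (any(df$i_raw < 0) || any(df$i_background < 0))) {
    stop("intensities must be non-negative")
  }
  unknown <- setdiff(df$region, KNOWN_REGIONS)
  if (length(unknown)) {
    warning("unknown region(s), passed through: ",
            paste(unknown, collapse = ", "))
  }
  structure(df, tracer = tracer, animal = animal,
            starter_in = starter_in, starter_out = starter_out,
            class = c("region_quant_table", "data.frame"))
}

#' Quality-control rule for tracing experiments
#'
#' @param starter_threshold Minimum fraction of starter cells inside the
#'   target structure; brains at or below it fail (strict inequality).
#'   0.70 for rabies, 0.65 for anterograde tracing.
#' @param excluded_regions Regions dropped before normalization owing to
#'   proximity to the injection site: LH, anterior MeA and AAA for rabies;
#'   LH and anterior MeA for anterograde.
#' @param report_floor Reporting floor: input fractions must exceed 0.02, or
#'   normalized intensities reach at least 0.2, to enter the reported subset.
#' @param always_include Regions always reported regardless of the floor
#'   (VMHvl for projections, given its established role in aggression).
#' @return A list of class `qc_rule`.
#' @export
qc_rule <- function(starter_threshold = 0.70,
                    excluded_regions = c("LH", "MeAa", "AAA"),
                    report_floor = 0.02,
                    always_include = character(0)) {
  if (!(starter_threshold > 0 && starter_threshold <= 1)) {
    stop("`starter_threshold` must be in (0, 1]")
  }
  structure(list(starter_threshold = starter_threshold,
                 excluded_regions = excluded_regions,
                 report_floor = report_floor,
                 always_include = always_include),
            class = "qc_rule")
}

#' Default QC rules for rabies input and anterograde projection mapping
#' @rdname qc_rule
#' @export
qc_rule_rabies <- function() {
  qc_rule(starter_threshold = 0.70,
          excluded_regions = c("LH", "MeAa", "AAA"),
          report_floor = 0.02)
}

#' @rdname qc_rule
#' @export
qc_rule_anterograde <- function() {
  qc_rule(starter_threshold = 0.65,
          excluded_regions = c("LH", "MeAa"),
          report_floor = 0.2,
          always_include = "VMHvl")
}

#' Starter-cell quality control
#'
#' A brain passes when strictly more than the threshold fraction of starter
#' cells lies inside the target structure.
#'
#' @param table A [region_quant_table()] with starter metadata, or `NULL` if
#'   `starter_in`/`starter_out` are given directly.
#' @param rule A [qc_rule()].
#' @param starter_in,starter_out Optional direct counts, overriding the
#'   table metadata.
#' @return List with `fraction` (in / (in + out)) and `pass`.
#' @export
starter_qc <- function(table = NULL, rule = qc_rule_rabies(),
                       starter_in = NULL, starter_out = NULL) {
  if (is.null(starter_in)) starter_in <- attr(table, "starter_in")
  if (is.null(starter_out)) starter_out <- attr(table, "starter_out")
  if (is.null(starter_in) || is.null(starter_out) ||
      is.na(starter_in) || is.na(starter_out)) {
    stop("starter cell counts are missing")
  }
  total <- starter_in + starter_out
  if (total == 0) stop("no starter cells counted")
  frac <- starter_in / total
  list(fraction = frac, pass = frac > rule$starter_threshold)
}

#' Per-region input fractions from retrograde counts
#'
#' Drops the excluded regions, then normalizes the remaining counts to
#' fractions of total inputs. The reported subset keeps regions whose
#' fraction exceeds the reporting floor (default 2% of total inputs).
#'
#' @param table A [region_quant_table()] of counts.
#' @param rule A [qc_rule()] (default rabies rule).
#' @return List with `fractions` (named, summing to 1 over the retained
#'   regions), `reported` (subset above the floor) and `excluded` (regions
#'   dropped before normalization).
#' @export
input_fractions <- function(table, rule = qc_rule_rabies()) {
  df <- as.data.frame(table)
  if (is.null(df$count)) stop("`table` must carry counts")
  drop <- df$region %in% rule$excluded_regions
  df2 <- df[!drop, , drop = FALSE]
  total <- sum(df2$count)
  if (total == 0) stop("all counts are zero after exclusions")
  fr <- stats::setNames(df2$count / total, df2$region)
  list(fractions = fr,
       reported = fr[fr > rule$report_floor],
       excluded = df$region[drop])
}

#' Normalized projection intensity per region
#'
#' Subtracts the contralateral background from the raw mean pixel intensity
#' (`I_signal = max(I_raw - I_background, 0)`) and normalizes to the maximum
#' signal across regions (`I_norm = I_signal / max(I_signal)`), after
#' dropping the excluded regions. The reported subset keeps regions with
#' `I_norm` at or above the floor (default 0.2) plus the always-include set.
#'
#' @param table A [region_quant_table()] with `i_raw` and `i_background`.
#' @param rule A [qc_rule()] (default anterograde rule).
#' @return List with `i_signal`, `i_norm` (named; max exactly 1), `reported`
#'   and `excluded`.
#' @export
projection_intensity <- function(table, rule = qc_rule_anterograde()) {
  df <- as.data.frame(table)
  if (is.null(df$i_raw) || is.null(df$i_background)) {
    stop("`table` must carry i_raw and i_background")
  }
  drop <- df$region %in% rule$excluded_regions
  df2 <- df[!drop, , drop = FALSE]
  sig <- pmax(df2$i_raw - df2$i_background, 0)
  if (max(sig) == 0) stop("all signal intensities are zero after exclusions")
  inorm <- stats::setNames(sig / max(sig), df2$region)
  keep <- inorm >= rule$report_floor | names(inorm) %in% rule$always_include
  list(i_signal = stats::setNames(sig, df2$region),
       i_norm = inorm,
       reported = inorm[keep],
       excluded = df$region[drop])
}

#' Ratio of summed normalized intensities between two region sets
#'
#' e.g. the overall fiber density in MPOA + AVPV over that in VMHvl + PMv,
#' or BNSTpr over BNSTif.
#'
#' @param i_norm Named numeric vector of normalized intensities.
#' @param numerator,denominator Character vectors of region names.
#' @return The ratio `sum(i_norm[numerator]) / sum(i_norm[denominator])`;
#'   `NA` with attribute `undefined = TRUE` when the denominator sum is 0.
#' @export
projection_ratio <- function(i_norm, numerator, denominator) {
  miss <- setdiff(c(numerator, denominator), names(i_norm))
  if (length(miss)) stop("region(s) absent from i_norm: ",
                         paste(miss, collapse = ", "))
  den <- sum(i_norm[denominator])
  if (den == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  sum(i_norm[numerator]) / den
}

#' Overlap percentages from double-label counts
#'
#' From counts of cells positive only for marker A, only for marker B, and
#' for both, computes the percentage of A cells that are also B, of B cells
#' that are also A, and the double-positive share of all labeled cells.
#'
#' @param only_a,only_b,both Non-negative counts.
#' @return List with `pct_a_also_b`, `pct_b_also_a`, `pct_double` (each
#'   0-100; `NA` when its denominator is 0).
#' @export
overlap_fractions <- function(only_a, only_b, both) {
  if (any(c(only_a, only_b, both) < 0)) stop("counts must be non-negative")
  total <- only_a + only_b + both
  if (total == 0) stop("no labeled cells")
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(pct_a_also_b = safe(both, only_a + both),
       pct_b_also_a = safe(both, only_b + both),
       pct_double = safe(both, total))
}

#' Perpendicular distances from points to a line
#'
#' Euclidean distance from each point to the infinite line through two
#' reference points (e.g. cell positions relative to the optic tract or the
#' dorsal edge of the MeA).
#'
#' @param points Two-column matrix (x, y) of point coordinates, pixels.
#' @param line Two-row, two-column matrix giving two distinct points on the
#'   line.
#' @return Numeric vector of distances.
#' @export
point_to_line_distances <- function(points, line) {
  points <- matrix(as.numeric(points), ncol = 2L)
  line <- matrix(as.numeric(line), ncol = 2L)
  if (nrow(line) != 2L) stop("`line` must contain exactly two points")
  d <- line[2L, ] - line[1L, ]
  len <- sqrt(sum(d^2))
  if (len == 0) stop("line endpoints coincide")
  # |cross product| / |direction|
  abs((points[, 1L] - line[1L, 1L]) * d[2L] -
        (points[, 2L] - line[1L, 2L]) * d[1L]) / len
}
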