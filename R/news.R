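#' NEWS 2 scoring band table
#'
#' Returns the banding chart for the five numeric NEWS 2 components
#' (respiratory rate, oxygen saturation on scale 1, systolic blood pressure,
#' pulse rate and temperature) as shipped with the package in
#' `inst/extdata/news2_chart.csv`. Bands are closed intervals on the
#' measurement scale; temperature bands are expressed to one decimal place,
#' matching the published chart (e.g. 38.1--39.0 scores 1 point).
#'
#' The two remaining components are categorical and are handled directly by
#' [score_component()]: consciousness on the ACVPU scale (Alert scores 0, any
#' of Confusion/Voice/Pain/Unresponsive scores 3) and supplemental oxygen
#' (2 points when on oxygen, 0 on air).
#'
#' @return A data frame with columns `component`, `lower`, `upper`, `points`.
#' @export
news2_chart <- function() {
  if (is.null(.news_cache$chart)) {
    path <- system.file("extdata", "news2_chart.csv", package = "rcstrial")
    .news_cache$chart <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .news_cache$chart
}

.news_cache <- new.env(parent = emptyenv())

# physiological plausibility limits used for input validation
.news_ranges <- list(
  respiratory_rate = c(0, 60),
  spo2             = c(50, 100),
  systolic_bp      = c(40, 300),
  pulse            = c(20, 220),
  temperature      = c(30, 43)
)

.acvpu_levels <- c("Alert", "Confusion", "Voice", "Pain", "Unresponsive")

#' Score a single NEWS 2 component
#'
#' Maps a measurement to its 0--3 point band. Numeric components are looked
#' up in [news2_chart()]; `consciousness` follows the ACVPU rule (Alert = 0,
#' otherwise 3, with new confusion scoring 3); `on_oxygen` scores 2 when
#' `TRUE` and 0 when `FALSE`.
#'
#' Temperature is banded to one decimal place: values are rounded to 0.1
#' before lookup so that e.g. 38.05 falls in the 36.1--38.0 band.
#'
#' @param name Component name: one of `"respiratory_rate"`, `"spo2"`,
#'   `"on_oxygen"`, `"systolic_bp"`, `"pulse"`, `"consciousness"`,
#'   `"temperature"`.
#' @param value Measurement(s): numeric for the numeric components, logical
#'   for `on_oxygen`, character/factor ACVPU level for `consciousness`.
#' @return Integer vector of points in `{0, 1, 2, 3}`; `NA` where the input
#'   is `NA`.
#' @export
#' @examples
#' score_component("respiratory_rate", 18)  # 0
#' score_component("spo2", 93)              # 2
#' score_component("consciousness", "Alert")
score_component <- function(name, value) {
  if (length(name) != 1L) stop("'name' must be a single component label")
  if (name == "consciousness") {
    value <- as.character(value)
    bad <- !is.na(value) & !value %in% .acvpu_levels
    if (any(bad)) {
      stop("unknown ACVPU level(s): ", paste(unique(value[bad]), collapse = ", "))
    }
    return(ifelse(is.na(value), NA_integer_, ifelse(value == "Alert", 0L, 3L)))
  }
  if (name == "on_oxygen") {
    if (!is.logical(value)) {
      stop("'on_oxygen' must be logical")
    }
    return(ifelse(is.na(value), NA_integer_, ifelse(value, 2L, 0L)))
  }
  rng <- .news_ranges[[name]]
  if (is.null(rng)) stop("unknown NEWS 2 component: ", name)
  value <- as.numeric(value)
  out_of_range <- !is.na(value) & (value < rng[1] | value > rng[2])
  if (any(out_of_range)) {
    stop(sprintf("%s value(s) outside physiological range [%g, %g]: %s",
                 name, rng[1], rng[2],
                 paste(utils::head(value[out_of_range], 3), collapse = ", ")))
  }
  chart <- news2_chart()
  bands <- chart[chart$component == name, , drop = FALSE]
  v <- if (name == "temperature") round(value, 1) else value
  pts <- rep(NA_integer_, length(v))
  for (i in seq_len(nrow(bands))) {
    hit <- !is.na(v) & v >= bands$lower[i] & v <= bands$upper[i]
    pts[hit] <- bands$points[i]
  }
  unmatched <- is.na(pts) & !is.na(v)
  if (any(unmatched)) {
    stop(sprintf("%s value(s) fall in no chart band: %s", name,
                 paste(utils::head(v[unmatched], 3), collapse = ", ")))
  }
  pts
}

.news_components <- c("respiratory_rate", "spo2", "on_oxygen", "systolic_bp",
                      "pulse", "consciousness", "temperature")

#' Compute NEWS 2 totals from a table of vital-sign components
#'
#' Sums the seven component scores. All components must be present: rows with
#' any missing component are refused (impute first; totals are always
#' calculated from completed components, never imputed directly).
#'
#' @param vitals A data frame with columns `respiratory_rate`, `spo2`,
#'   `on_oxygen` (logical), `systolic_bp`, `pulse`, `consciousness` (ACVPU)
#'   and `temperature`.
#' @param component_points If `TRUE`, also return the per-component points.
#' @return Integer vector of totals in 0--20, or (with
#'   `component_points = TRUE`) a data frame of the seven component scores
#'   plus a `news_total` column.
#' @export
#' @examples
#' v <- data.frame(respiratory_rate = 22, spo2 = 95, on_oxygen = FALSE,
#'                 systolic_bp = 100, pulse = 92, consciousness = "Alert",
#'                 temperature = 38.2)
#' compute_news(v)  # 7
compute_news <- function(vitals, component_points = FALSE) {
  miss <- setdiff(.news_components, names(vitals))
  if (length(miss)) stop("missing vitals column(s): ", paste(miss, collapse = ", "))
  pts <- lapply(.news_components, function(nm) score_component(nm, vitals[[nm]]))
  names(pts) <- .news_components
  pts <- as.data.frame(pts)
  if (anyNA(pts)) {
    stop("cannot score rows with missing components; run imputation first")
  }
  total <- as.integer(rowSums(pts))
  if (!component_points) return(total)
  pts$news_total <- total
  pts
}

#' Members achieving the maximum NEWS within an RCS
#'
#' Given the scores of the members of one resource constrained situation,
#' returns the ids of all members attaining the maximum (the "winner set").
#' A prioritization is counted correct when the prioritized patient belongs
#' to this set, so ties are correct by construction.
#'
#' @param scores Named numeric vector of member scores (names are member ids),
#'   or an unnamed vector (positional ids are used).
#' @return Character vector of ids achieving the maximum.
#' @export
#' @examples
#' rcs_winner_set(c(A = 5, B = 3))        # "A"
#' rcs_winner_set(c(A = 4, B = 4))        # "A" "B"
rcs_winner_set <- function(scores) {
  if (length(scores) == 0L) stop("empty score set")
  if (anyNA(scores)) stop("all members must be scored")
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  ids[scores == max(scores)]
}
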